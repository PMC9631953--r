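#' Simulation configuration
#'
#' Parameters of the synthetic genome used to exercise the pipeline against
#' known truth: a 2n = 14-style karyotype (6 autosomes + X + Y by default)
#' fragmented into lognormally sized scaffolds, sexed per-scaffold mean
#' depths, noisy alignment evidence to a chromosome-level reference, and
#' Y-marker-gene homology hits.
#'
#' Depth noise is Gamma (strictly positive, right-skewed like real coverage)
#' and is decomposed into a per-scaffold bias shared between the two samples
#' (mappability/GC-type bias) and a sex-independent residual with CV
#' `depth_cv_resid`; the marginal per-sample CV equals `depth_cv`. The shared
#' component cancels in the female:male ratio, which is what makes depth
#' ratios so much tighter than per-sample depths on real data.
#'
#' @param seed integer seed; every stage derives its own substream via
#'   [stage_seed()], so outputs are byte-identical for a fixed config.
#' @param n_autosomes number of autosomes (default 6, the dasyurid 2n = 14
#'   complement).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   Default: autosomes proportional to `n_autosomes:1` summing to 97.1 Mb,
#'   plus chrX 2.6 Mb and chrY 0.3 Mb (a 100 Mb toy genome with the X and Y
#'   fractions of a typical marsupial male assembly).
#' @param scaffold_len_logmean,scaffold_len_logsd lognormal scaffold-size
#'   parameters (bp scale; defaults `log(1e5)` and `0.8`, ~700 scaffolds on
#'   the default genome).
#' @param min_scaffold_len minimum scaffold size in bp (default 1000).
#' @param depth_male,depth_female mean autosomal depth of each sample
#'   (x coverage, default 55).
#' @param depth_cv marginal coefficient of variation of per-scaffold depth
#'   (default 0.10).
#' @param depth_cv_resid CV of the sex-independent residual component
#'   (default 0.04; capped at `depth_cv`).
#' @param female_y_background fraction of the female autosomal depth leaking
#'   onto Y scaffolds through X/Y-homologous-region mismapping (default 0.02).
#' @param aln_miss_prob probability a scaffold gets no alignment block on its
#'   true chromosome (default 0.05).
#' @param aln_chimera_prob probability a scaffold gets a spurious block on a
#'   wrong chromosome (default 0.05; drawn independently of the miss event).
#' @param n_y_genes number of Y marker genes (default 20).
#' @param y_gene_ambiguous_frac fraction of Y genes emitting several partial,
#'   near-equal hits on distinct scaffolds instead of one clean placement
#'   (default 0.05, i.e. one gene in 20 in expectation — the ATRY-like case).
#' @return a `sexscaff_sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$chrom_lengths
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 6L,
                       chrom_lengths = NULL,
                       scaffold_len_logmean = log(1e5),
                       scaffold_len_logsd = 0.8,
                       min_scaffold_len = 1000,
                       depth_male = 55,
                       depth_female = 55,
                       depth_cv = 0.10,
                       depth_cv_resid = 0.04,
                       female_y_background = 0.02,
                       aln_miss_prob = 0.05,
                       aln_chimera_prob = 0.05,
                       n_y_genes = 20L,
                       y_gene_ambiguous_frac = 0.05) {
  if (is.null(chrom_lengths)) {
    w <- rev(seq_len(n_autosomes))
    auto <- round(97.1e6 * w / sum(w))
    chrom_lengths <- c(
      setNames(auto, paste0("chr", seq_len(n_autosomes))),
      chrX = 2.6e6, chrY = 0.3e6
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    n_autosomes = as.integer(n_autosomes),
    chrom_lengths = chrom_lengths,
    scaffold_len_logmean = scaffold_len_logmean,
    scaffold_len_logsd = scaffold_len_logsd,
    min_scaffold_len = min_scaffold_len,
    depth_male = depth_male,
    depth_female = depth_female,
    depth_cv = depth_cv,
    depth_cv_resid = min(depth_cv_resid, depth_cv),
    female_y_background = female_y_background,
    aln_miss_prob = aln_miss_prob,
    aln_chimera_prob = aln_chimera_prob,
    n_y_genes = as.integer(n_y_genes),
    y_gene_ambiguous_frac = y_gene_ambiguous_frac
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sexscaff_sim_config")
}

validate_sim_config <- function(cfg) {
  cl <- cfg$chrom_lengths
  if (is.null(names(cl)) || anyDuplicated(names(cl)) || any(cl <= 0)) {
    stop_validation("chrom_lengths must be uniquely named and all > 0")
  }
  if (sum(cl) <= 0) stop_validation("total genome length must be > 0")
  probs <- c(cfg$female_y_background, cfg$aln_miss_prob,
             cfg$aln_chimera_prob, cfg$y_gene_ambiguous_frac)
  if (any(probs < 0 | probs > 1)) {
    stop_validation("probabilities must lie in [0, 1]")
  }
  if (cfg$depth_cv <= 0) stop_validation("depth_cv must be > 0")
  if (cfg$depth_male <= 0 || cfg$depth_female <= 0) {
    stop_validation("mean depths must be > 0")
  }
  if (cfg$min_scaffold_len <= 0) stop_validation("min_scaffold_len must be > 0")
  if (any(cl < cfg$min_scaffold_len)) {
    stop_validation(
      "chromosome(s) shorter than min_scaffold_len (%d bp): %s",
      as.integer(cfg$min_scaffold_len),
      paste(names(cl)[cl < cfg$min_scaffold_len], collapse = ", ")
    )
  }
  if (cfg$n_y_genes < 0) stop_validation("n_y_genes must be >= 0")
  invisible(cfg)
}

#' @export
print.sexscaff_sim_config <- function(x, ...) {
  cat("<sexscaff simulation config>\n")
  cat(sprintf("  seed: %d | genome: %s chromosomes, %.1f Mb total\n",
              x$seed, length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6))
  cat(sprintf("  depth: male %gx / female %gx, CV %.2f (resid %.2f), female Y background %.3f\n",
              x$depth_male, x$depth_female, x$depth_cv, x$depth_cv_resid,
              x$female_y_background))
  cat(sprintf("  alignments: miss %.2f, chimera %.2f | markers: %d Y genes, ambiguous frac %.2f\n",
              x$aln_miss_prob, x$aln_chimera_prob, x$n_y_genes,
              x$y_gene_ambiguous_frac))
  invisible(x)
}
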