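# Synthetic inputs with known truth: karyotype fragmentation, sexed depths,
# alignment evidence, Y-marker hits. All randomness flows through per-stage
# substreams of cfg$seed (see stage_seed), so a config reproduces byte-
# identical outputs regardless of which stages are run or in what order.

#' Fragment a karyotype into scaffolds
#'
#' Partitions every chromosome into one or more scaffolds with lognormally
#' distributed lengths. Scaffold lengths on a chromosome sum exactly to the
#' chromosome length and offsets are non-overlapping, so the table doubles as
#' ground truth for the downstream classification and anchoring stages.
#'
#' @param config a [sim_config()].
#' @return tibble with columns `scaffold_id`, `true_chromosome`, `length`,
#'   `offset` (0-based start of the scaffold on its chromosome).
#' @examples
#' truth <- simulate_karyotype(sim_config(seed = 42))
#' tapply(truth$length, truth$true_chromosome, sum)
#' @export
simulate_karyotype <- function(config) {
  validate_sim_config(config)
  with_stage_rng(config$seed, "karyotype", {
    pieces <- lapply(names(config$chrom_lengths), function(chrom) {
      L <- config$chrom_lengths[[chrom]]
      lens <- numeric(0)
      remaining <- L
      while (remaining > 0) {
        draw <- max(config$min_scaffold_len,
                    round(rlnorm(1, config$scaffold_len_logmean,
                                 config$scaffold_len_logsd)))
        if (draw >= remaining) {
          # last piece: absorb the remainder; fold into the previous scaffold
          # if the remainder alone would violate the minimum size
          if (remaining < config$min_scaffold_len && length(lens) > 0) {
            lens[length(lens)] <- lens[length(lens)] + remaining
          } else {
            lens <- c(lens, remaining)
          }
          remaining <- 0
        } else {
          lens <- c(lens, draw)
          remaining <- remaining - draw
        }
      }
      tibble::tibble(
        true_chromosome = chrom,
        length = lens,
        offset = cumsum(c(0, lens[-length(lens)]))
      )
    })
    out <- dplyr::bind_rows(pieces)
    out$scaffold_id <- sprintf("scaffold_%05d", seq_len(nrow(out)))
    out[, c("scaffold_id", "true_chromosome", "length", "offset")]
  })
}

truth_y_scaffolds <- function(truth) {
  truth$scaffold_id[chrom_group(truth$true_chromosome) == "Y"]
}

# Gamma multiplier with mean 1 and the given CV; degenerate at tiny CV.
gamma_noise <- function(n, cv) {
  if (cv <= 1e-9) return(rep(1, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape)
}

#' Simulate per-scaffold mean depths for a male and a female sample
#'
#' Expected depths follow single-copy dosage in an XY male: `depth_male` on
#' autosomes and `depth_male / 2` on X and Y; `depth_female` on autosomes and
#' X (two X copies in an XX female restore autosomal dosage), and
#' `female_y_background * depth_female` on Y (mismapping background only).
#' Noise is Gamma with marginal CV `depth_cv`, split into a shared
#' per-scaffold bias and a sex-independent residual (see [sim_config()]).
#'
#' @param truth a [simulate_karyotype()] table.
#' @param config the matching [sim_config()].
#' @return list with elements `male` and `female`, each a depth-summary
#'   tibble (`scaffold_id`, `length`, `mean_depth`, `sample_sex`).
#' @export
simulate_depths <- function(truth, config) {
  validate_sim_config(config)
  if (nrow(truth) == 0) stop_input("truth table is empty")
  grp <- chrom_group(truth$true_chromosome)
  mu_m <- ifelse(grp %in% c("X", "Y"), config$depth_male / 2, config$depth_male)
  mu_f <- ifelse(grp == "Y", config$female_y_background * config$depth_female,
                 config$depth_female)
  cv_r <- min(config$depth_cv_resid, config$depth_cv)
  cv_b <- sqrt(max(config$depth_cv^2 - cv_r^2, 0))
  with_stage_rng(config$seed, "depths", {
    n <- nrow(truth)
    bias <- gamma_noise(n, cv_b)
    male <- mu_m * bias * gamma_noise(n, cv_r)
    female <- mu_f * bias * gamma_noise(n, cv_r)
    list(
      male = tibble::tibble(scaffold_id = truth$scaffold_id,
                            length = truth$length,
                            mean_depth = male, sample_sex = "male"),
      female = tibble::tibble(scaffold_id = truth$scaffold_id,
                              length = truth$length,
                              mean_depth = female, sample_sex = "female")
    )
  })
}

# split `total` into k positive integer parts with random proportions
split_lengths <- function(total, k) {
  if (k == 1) return(total)
  p <- runif(k, 0.5, 1.5)
  parts <- floor(total * p / sum(p))
  parts[1] <- parts[1] + (total - sum(parts))
  pmax(parts, 1)
}

#' Simulate scaffold-to-reference alignment evidence
#'
#' With probability `1 - aln_miss_prob` a scaffold receives 1-3 disjoint
#' alignment blocks on its true chromosome jointly covering 60-95% of its
#' length; independently, with probability `aln_chimera_prob` it receives one
#' spurious block (5-20% of its length) on a random wrong chromosome. Query
#' coordinates are 0-based half-open.
#'
#' @inheritParams simulate_depths
#' @return tibble of alignment hits (`scaffold_id`, `q_start`, `q_end`,
#'   `chromosome`, `t_start`, `t_end`, `aligned_len`, `identity`).
#' @export
simulate_alignments <- function(truth, config) {
  validate_sim_config(config)
  if (nrow(truth) == 0) stop_input("truth table is empty")
  chroms <- names(config$chrom_lengths)
  with_stage_rng(config$seed, "alignments", {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      sc <- truth[i, ]
      L <- sc$length
      hits <- NULL
      if (runif(1) >= config$aln_miss_prob) {
        nb <- sample(1:3, 1)
        covered <- round(runif(1, 0.60, 0.95) * L)
        block_lens <- split_lengths(covered, nb)
        gap_total <- L - covered
        gaps <- if (nb > 1) split_lengths(max(gap_total, nb), nb) else gap_total
        # lay blocks left to right separated by gaps, clipped to the scaffold
        starts <- cumsum(c(0, block_lens[-nb] + gaps[seq_len(nb - 1)]))
        starts <- pmin(starts, L - block_lens)
        hits <- tibble::tibble(
          scaffold_id = sc$scaffold_id,
          q_start = starts, q_end = starts + block_lens,
          chromosome = sc$true_chromosome,
          t_start = sc$offset + starts, t_end = sc$offset + starts + block_lens,
          identity = runif(nb, 0.88, 0.99)
        )
      }
      if (runif(1) < config$aln_chimera_prob && length(chroms) > 1) {
        wrong <- sample(setdiff(chroms, sc$true_chromosome), 1)
        blen <- max(1, round(runif(1, 0.05, 0.20) * L))
        qs <- floor(runif(1, 0, L - blen + 1))
        ts <- floor(runif(1, 0, max(config$chrom_lengths[[wrong]] - blen, 1)))
        hits <- dplyr::bind_rows(hits, tibble::tibble(
          scaffold_id = sc$scaffold_id,
          q_start = qs, q_end = qs + blen,
          chromosome = wrong,
          t_start = ts, t_end = ts + blen,
          identity = runif(1, 0.88, 0.99)
        ))
      }
      rows[[i]] <- hits
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      return(tibble::tibble(scaffold_id = character(), q_start = numeric(),
                            q_end = numeric(), chromosome = character(),
                            t_start = numeric(), t_end = numeric(),
                            aligned_len = numeric(), identity = numeric()))
    }
    out$aligned_len <- out$q_end - out$q_start
    out[, c("scaffold_id", "q_start", "q_end", "chromosome",
            "t_start", "t_end", "aligned_len", "identity")]
  })
}

# Marsupial Y genes and their X/autosomal homologs (gametologue pairs used as
# placement markers; names are illustrative defaults, recycled if n > 20).
y_gene_catalog <- function(n) {
  pairs <- c(
    SRY = "SOX3",    ATRY = "ATRX",     RBMY = "RBMX",    SMCY = "SMCX",
    UBE1Y = "UBE1X", UTY = "UTX",       USP9Y = "USP9X",  DDX3Y = "DDX3X",
    EIF2S3Y = "EIF2S3X", HCFC1RY = "HCFC1R", RPL10LY = "RPL10L",
    THOC2Y = "THOC2X", PHF6Y = "PHF6X", HUWE1Y = "HUWE1X", MECP2Y = "MECP2X",
    NLGN3Y = "NLGN3X", RBM10Y = "RBM10X", KDM6BY = "KDM6B", TFE3Y = "TFE3X",
    IQSEC2Y = "IQSEC2X"
  )
  if (n <= length(pairs)) {
    pairs <- pairs[seq_len(n)]
  } else {
    extra <- setNames(sprintf("YG%02dX", seq_len(n - length(pairs))),
                      sprintf("YG%02d", seq_len(n - length(pairs))))
    pairs <- c(pairs, extra)
  }
  tibble::tibble(y_gene = names(pairs), homolog = unname(pairs))
}

marker_hit_row <- function(gene, gene_class, partner, scaffold, scaff_len,
                           frac = 1, bitscore, evalue, gene_len) {
  alen <- max(100, round(frac * gene_len))
  qs <- if (frac < 1) sample.int(gene_len - alen + 1, 1) else 1L
  ss <- sample.int(max(scaff_len - alen, 1), 1)
  tibble::tibble(
    gene = gene, gene_class = gene_class, partner_gene = partner,
    scaffold_id = scaffold, pident = round(runif(1, 75, 99), 2),
    aln_len = alen, mismatch = round(alen * runif(1, 0.01, 0.1)), gapopen = 0L,
    q_start = qs, q_end = qs + alen - 1L, s_start = ss, s_end = ss + alen - 1L,
    evalue = evalue, bitscore = bitscore
  )
}

#' Simulate Y marker-gene homology hits
#'
#' Places `n_y_genes` Y genes on Y scaffolds with strong hits (e-value well
#' below 1e-20) and each gene's X/autosomal homolog on a non-Y scaffold. A
#' `y_gene_ambiguous_frac` fraction of Y genes instead emit 2-4 partial hits
#' of near-equal bit score (within 20%) on distinct scaffolds — the behaviour
#' of genes like ATRY that cannot be pinned to a single scaffold. Coordinates
#' are 1-based inclusive (BLAST convention).
#'
#' @inheritParams simulate_depths
#' @return list with `hits` (BLAST-style marker-hit tibble), `manifest`
#'   (gene, gene_class, partner_gene) and `gene_truth` (Y gene to true
#'   scaffold; `NA` for ambiguous genes).
#' @export
simulate_marker_hits <- function(truth, config) {
  validate_sim_config(config)
  grp <- chrom_group(truth$true_chromosome)
  y_sc <- truth[grp == "Y", ]
  x_sc <- truth[grp == "X", ]
  other_sc <- truth[grp != "Y", ]
  if (nrow(y_sc) == 0) stop_input("truth contains no Y scaffolds")
  catalog <- y_gene_catalog(config$n_y_genes)
  with_stage_rng(config$seed, "markers", {
    homolog_pool <- if (nrow(x_sc) > 0) x_sc else other_sc
    rows <- list()
    gene_truth <- tibble::tibble(gene = catalog$y_gene,
                                 true_scaffold = NA_character_,
                                 ambiguous = runif(nrow(catalog)) <
                                   config$y_gene_ambiguous_frac)
    for (j in seq_len(nrow(catalog))) {
      yg <- catalog$y_gene[j]; hom <- catalog$homolog[j]
      gene_len <- sample(1000:3000, 1)
      if (!gene_truth$ambiguous[j]) {
        k <- sample.int(nrow(y_sc), 1)
        gene_truth$true_scaffold[j] <- y_sc$scaffold_id[k]
        rows[[length(rows) + 1]] <- marker_hit_row(
          yg, "Y_GENE", hom, y_sc$scaffold_id[k], y_sc$length[k],
          bitscore = round(runif(1, 400, 900)),
          evalue = 10^-runif(1, 30, 80), gene_len = gene_len)
      } else {
        nhit <- sample(2:4, 1)
        pool <- unique(c(sample(y_sc$scaffold_id, 1),
                         sample(other_sc$scaffold_id,
                                min(nhit - 1, nrow(other_sc)))))
        base <- round(runif(1, 150, 300))
        for (sc in pool) {
          slen <- truth$length[truth$scaffold_id == sc]
          rows[[length(rows) + 1]] <- marker_hit_row(
            yg, "Y_GENE", hom, sc, slen, frac = runif(1, 0.2, 0.45),
            bitscore = round(base * runif(1, 0.85, 1.0)),
            evalue = 10^-runif(1, 15, 25), gene_len = gene_len)
        }
      }
      k <- sample.int(nrow(homolog_pool), 1)
      rows[[length(rows) + 1]] <- marker_hit_row(
        hom, "HOMOLOG", yg, homolog_pool$scaffold_id[k],
        homolog_pool$length[k], bitscore = round(runif(1, 350, 800)),
        evalue = 10^-runif(1, 25, 70), gene_len = gene_len)
    }
    manifest <- dplyr::bind_rows(
      tibble::tibble(gene = catalog$y_gene, gene_class = "Y_GENE",
                     partner_gene = catalog$homolog),
      tibble::tibble(gene = catalog$homolog, gene_class = "HOMOLOG",
                     partner_gene = catalog$y_gene)
    )
    list(hits = dplyr::bind_rows(rows), manifest = manifest,
         gene_truth = gene_truth)
  })
}

#' Generate a complete labelled synthetic dataset
#'
#' Runs [simulate_karyotype()], [simulate_depths()], [simulate_alignments()]
#' and [simulate_marker_hits()] under one config.
#'
#' @param config a [sim_config()].
#' @return list with `truth`, `male_depth`, `female_depth`, `alignments`,
#'   `marker_hits`, `marker_manifest`, `gene_truth`, `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7))
#' nrow(sim$truth)
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_karyotype(config)
  depths <- simulate_depths(truth, config)
  aln <- simulate_alignments(truth, config)
  mk <- simulate_marker_hits(truth, config)
  list(truth = truth, male_depth = depths$male, female_depth = depths$female,
       alignments = aln, marker_hits = mk$hits,
       marker_manifest = mk$manifest, gene_truth = mk$gene_truth,
       config = config)
}

#' Write a synthetic dataset in the pipeline's on-disk formats
#'
#' Depth summaries in mosdepth-summary dialect, alignments as PAF, marker
#' hits as BLAST outfmt 6 plus a gene manifest TSV, scaffold lengths as a
#' fai-style TSV, truth labels as TSV and the config as YAML.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    male_depth = file.path(dir, "male.mosdepth.summary.txt"),
    female_depth = file.path(dir, "female.mosdepth.summary.txt"),
    alignments = file.path(dir, "alignments.paf"),
    marker_hits = file.path(dir, "ygenes.blast6"),
    marker_manifest = file.path(dir, "genes.tsv"),
    lengths = file.path(dir, "scaffolds.fai"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_mosdepth_summary(sim$male_depth, paths[["male_depth"]])
  write_mosdepth_summary(sim$female_depth, paths[["female_depth"]])
  write_paf(sim$alignments, sim$truth, sim$config, paths[["alignments"]])
  write_blast6(sim$marker_hits, paths[["marker_hits"]])
  readr::write_tsv(sim$marker_manifest, paths[["marker_manifest"]])
  fai <- sim$truth[, c("scaffold_id", "length")]
  readr::write_tsv(fai, paths[["lengths"]], col_names = FALSE)
  readr::write_tsv(sim$truth, paths[["truth"]])
  cfg <- unclass(sim$config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
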