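# Y-marker confirmation: place known Y genes (and their X/autosomal
# homologs) on scaffolds from homology hits, then confirm a scaffold as
# Y-linked when it carries a placed Y gene, its AD-ratio is in the Y band,
# and the gene's homolog placed elsewhere (a co-placed homolog indicates a
# non-Y or chimeric scaffold).

#' Place marker genes on scaffolds
#'
#' Hits with e-value above `evalue_max` are discarded. For each gene the
#' surviving hits are aggregated per scaffold by summed bit score (bit score,
#' not e-value, because it is database-size independent); the gene is PLACED
#' on the top scaffold iff its score is at least `ambiguity_margin` times the
#' runner-up's, otherwise UNPLACED_AMBIGUOUS (several near-equal partial
#' placements, the ATRY behaviour). Genes with no surviving hits are
#' UNPLACED_NO_HIT.
#'
#' @param hits marker-hit tibble (see [read_marker_hits()] /
#'   [simulate_marker_hits()]).
#' @param manifest optional gene manifest (`gene`, `gene_class`,
#'   `partner_gene`); genes listed there but absent from `hits` get an
#'   UNPLACED_NO_HIT row, so every known gene appears exactly once.
#' @param evalue_max per-hit e-value cutoff (default 1e-10).
#' @param ambiguity_margin required best / runner-up score ratio
#'   (default 1.2).
#' @return placement tibble (`gene`, `gene_class`, `partner_gene`, `status`,
#'   `scaffold_id`, `best_bitscore`, `runner_up_bitscore`, `n_scaffolds`).
#' @export
place_genes <- function(hits, manifest = NULL, evalue_max = 1e-10,
                        ambiguity_margin = 1.2) {
  if (evalue_max < 0 || ambiguity_margin < 1) {
    stop_input("evalue_max must be >= 0 and ambiguity_margin >= 1")
  }
  info <- unique(rbind(
    hits[, c("gene", "gene_class", "partner_gene")],
    if (!is.null(manifest)) manifest[, c("gene", "gene_class", "partner_gene")]
  ))
  if (anyDuplicated(info$gene)) {
    stop_input("inconsistent gene_class/partner_gene for gene(s): %s",
               paste(info$gene[duplicated(info$gene)], collapse = ", "))
  }
  kept <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  scores <- dplyr::summarise(
    dplyr::group_by(kept, .data$gene, .data$scaffold_id),
    score = sum(.data$bitscore), .groups = "drop"
  )
  place_one <- function(g) {
    s <- scores[scores$gene == g, ]
    if (nrow(s) == 0) {
      return(tibble::tibble(gene = g, status = "UNPLACED_NO_HIT",
                            scaffold_id = NA_character_, best_bitscore = 0,
                            runner_up_bitscore = 0, n_scaffolds = 0L))
    }
    s <- s[order(-s$score), ]
    best <- s$score[1]
    runner <- if (nrow(s) > 1) s$score[2] else 0
    placed <- best >= ambiguity_margin * runner
    tibble::tibble(
      gene = g,
      status = if (placed) "PLACED" else "UNPLACED_AMBIGUOUS",
      scaffold_id = if (placed) s$scaffold_id[1] else NA_character_,
      best_bitscore = best, runner_up_bitscore = runner,
      n_scaffolds = nrow(s)
    )
  }
  out <- dplyr::bind_rows(lapply(info$gene, place_one))
  dplyr::left_join(out, info, by = "gene")[,
    c("gene", "gene_class", "partner_gene", "status", "scaffold_id",
      "best_bitscore", "runner_up_bitscore", "n_scaffolds")]
}

#' Confirm Y scaffolds from gene placements and AD-ratios
#'
#' A scaffold is confirmed Y iff (a) at least one Y gene is placed on it,
#' (b) its AD-ratio is defined and at most `y_max`, and (c) at least one of
#' those Y genes has its homolog placed on a *different* scaffold (genes
#' whose homolog co-places on the scaffold are vetoed; an unplaced homolog
#' cannot veto). Candidate Y scaffolds (AD-ratio <= `y_max`) carrying no
#' placed Y gene are reported unconfirmed with reason NO_GENES.
#'
#' @param placements tibble from [place_genes()].
#' @param ad AD-ratio record tibble (classified or not) covering at least
#'   every scaffold a gene is placed on.
#' @param y_max inclusive AD-ratio ceiling for confirmation (default 0.3).
#' @return list with `confirmations` tibble (`scaffold_id`, `length`,
#'   `ad_ratio`, `supporting_genes`, `n_supporting`, `confirmed`,
#'   `excluded_reason`, `high_confidence`) and `total_confirmed_bp`.
#' @export
confirm_y <- function(placements, ad, y_max = 0.3) {
  y_placed <- placements[placements$gene_class == "Y_GENE" &
                           placements$status == "PLACED", ]
  missing <- setdiff(y_placed$scaffold_id, ad$scaffold_id)
  if (length(missing) > 0) {
    stop_input("placed scaffold(s) absent from AD-ratio table: %s",
               paste(missing, collapse = ", "))
  }
  hom_scaffold <- setNames(
    placements$scaffold_id[placements$gene_class == "HOMOLOG" &
                             placements$status == "PLACED"],
    placements$gene[placements$gene_class == "HOMOLOG" &
                      placements$status == "PLACED"])
  candidates <- unique(c(
    y_placed$scaffold_id,
    ad$scaffold_id[!is.na(ad$ad_ratio) & ad$ad_ratio <= y_max]
  ))
  rows <- lapply(candidates, function(sc) {
    genes <- y_placed$gene[y_placed$scaffold_id == sc]
    partners <- y_placed$partner_gene[y_placed$scaffold_id == sc]
    vetoed <- !is.na(hom_scaffold[partners]) & hom_scaffold[partners] == sc
    supporting <- genes[!vetoed]
    i <- match(sc, ad$scaffold_id)
    r <- ad$ad_ratio[i]
    ad_ok <- !is.na(r) && r <= y_max
    confirmed <- ad_ok && length(supporting) > 0
    reason <- if (confirmed) NA_character_
      else if (length(genes) == 0) "NO_GENES"
      else if (!ad_ok) "AD_TOO_HIGH"
      else "HOMOLOG_SAME_SCAFFOLD"
    tibble::tibble(
      scaffold_id = sc, length = ad$length[i], ad_ratio = r,
      supporting_genes = paste(supporting, collapse = ","),
      n_supporting = length(supporting), confirmed = confirmed,
      excluded_reason = reason,
      high_confidence = confirmed && !is.na(r) && r <= 0.01
    )
  })
  confirmations <- dplyr::arrange(dplyr::bind_rows(rows),
                                  dplyr::desc(.data$confirmed),
                                  .data$scaffold_id)
  list(confirmations = confirmations,
       total_confirmed_bp = sum(confirmations$length[confirmations$confirmed]))
}

#' Gene track along confirmed Y scaffolds
#'
#' Orders the Y genes placed on each confirmed scaffold by the subject-start
#' coordinate of their best hit and emits a GFF3-style table (1-based
#' inclusive) plus per-scaffold gene counts.
#'
#' @param placements tibble from [place_genes()].
#' @param hits the marker-hit tibble the placements were derived from.
#' @param confirmations confirmation tibble from [confirm_y()]; if `NULL`,
#'   every scaffold with a placed Y gene is reported.
#' @return list with `track` (seqid, source, type, start, end, score, strand,
#'   phase, attributes) and `counts` (scaffold_id, n_genes).
#' @export
gene_map_report <- function(placements, hits, confirmations = NULL) {
  y_placed <- placements[placements$gene_class == "Y_GENE" &
                           placements$status == "PLACED", ]
  if (!is.null(confirmations)) {
    keep <- confirmations$scaffold_id[confirmations$confirmed]
    y_placed <- y_placed[y_placed$scaffold_id %in% keep, ]
  }
  empty <- tibble::tibble(seqid = character(), source = character(),
                          type = character(), start = numeric(),
                          end = numeric(), score = numeric(),
                          strand = character(), phase = character(),
                          attributes = character())
  if (nrow(y_placed) == 0) {
    return(list(track = empty,
                counts = tibble::tibble(scaffold_id = character(),
                                        n_genes = integer())))
  }
  best_hit <- function(g, sc) {
    h <- hits[hits$gene == g & hits$scaffold_id == sc, ]
    h[which.max(h$bitscore), ]
  }
  feats <- dplyr::bind_rows(Map(function(g, sc) {
    h <- best_hit(g, sc)
    tibble::tibble(
      seqid = sc, source = "sexscaff", type = "gene",
      start = min(h$s_start, h$s_end), end = max(h$s_start, h$s_end),
      score = h$bitscore, strand = ifelse(h$s_end >= h$s_start, "+", "-"),
      phase = ".", attributes = sprintf("ID=%s;Name=%s", g, g)
    )
  }, y_placed$gene, y_placed$scaffold_id))
  feats <- dplyr::arrange(feats, .data$seqid, .data$start)
  counts <- dplyr::summarise(dplyr::group_by(feats, scaffold_id = .data$seqid),
                             n_genes = dplyr::n(), .groups = "drop")
  list(track = feats, counts = counts)
}

#' Write a gene track as GFF3
#'
#' @param track tibble from [gene_map_report()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(track, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(track) > 0) {
    utils::write.table(track, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
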