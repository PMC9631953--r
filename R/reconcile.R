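# Cross-validation of the two assignment methods. Coverage can only tell
# autosome from X from Y, so agreement is computed at that group level:
# chrX-like names map to X, chrY-like to Y, everything else to AUTOSOME.

#' Reconcile coverage classes with homology assignments
#'
#' Every scaffold falls in exactly one length-weighted category: `agree`
#' (both methods assigned, same chromosome group), `conflict` (both
#' assigned, different groups), `one_method_unassigned`, or
#' `both_unassigned`. The four categories partition the genome; both
#' unassigned-vs-unassigned and one-sided calls are excluded from the
#' agreement numerator but kept in its denominator.
#'
#' @param ad classified AD-ratio record tibble ([classify_scaffolds()]).
#' @param anchors assignment tibble ([assign_chromosomes()]) over the same
#'   scaffolds.
#' @return list with bp totals (`agree_bp`, `conflict_bp`,
#'   `one_method_unassigned_bp`, `both_unassigned_bp`, `total_bp`), fractions
#'   (`agree_frac`, `conflict_frac`), a `crosstab` tibble
#'   (coverage_class x chromosome group, bp) and the per-scaffold `detail`.
#' @export
reconcile <- function(ad, anchors) {
  if (!setequal(ad$scaffold_id, anchors$scaffold_id) ||
      nrow(ad) != nrow(anchors)) {
    stop_input("AD-ratio and anchoring tables cover different scaffolds")
  }
  an <- anchors[match(ad$scaffold_id, anchors$scaffold_id), ]
  cov_grp <- as.character(ad$coverage_class)
  hom_grp <- chrom_group(an$assigned_chromosome)
  cov_ok <- cov_grp != "UNASSIGNED"
  hom_ok <- hom_grp != "UNASSIGNED"
  category <- ifelse(cov_ok & hom_ok,
                     ifelse(cov_grp == hom_grp, "agree", "conflict"),
                     ifelse(!cov_ok & !hom_ok, "both_unassigned",
                            "one_method_unassigned"))
  detail <- tibble::tibble(
    scaffold_id = ad$scaffold_id, length = ad$length,
    coverage_group = cov_grp, homology_chromosome = an$assigned_chromosome,
    homology_group = hom_grp, category = category
  )
  bp <- function(cat) sum(ad$length[category == cat])
  total <- sum(ad$length)
  crosstab <- dplyr::summarise(
    dplyr::group_by(detail, coverage_class = .data$coverage_group,
                    chromosome_group = .data$homology_group),
    bp = sum(.data$length), .groups = "drop"
  )
  out <- list(
    agree_bp = bp("agree"), conflict_bp = bp("conflict"),
    one_method_unassigned_bp = bp("one_method_unassigned"),
    both_unassigned_bp = bp("both_unassigned"), total_bp = total,
    agree_frac = bp("agree") / total, conflict_frac = bp("conflict") / total,
    crosstab = crosstab, detail = detail
  )
  stopifnot(abs(out$agree_bp + out$conflict_bp + out$one_method_unassigned_bp +
                  out$both_unassigned_bp - total) < 1e-6)
  out
}

#' Consensus per-scaffold assignment
#'
#' Combines the three evidence sources with a fixed precedence: (1) a
#' marker-confirmed Y scaffold is chrY regardless of homology (the reference
#' Y is typically incomplete); (2) scaffolds on which both methods agree take
#' the homology chromosome; (3) homology-only scaffolds take the homology
#' chromosome; (4) coverage-only scaffolds take their coverage group (chrX /
#' chrY; autosome-group scaffolds stay `autosome_unplaced` because coverage
#' cannot pick an autosome); (5) non-Y conflicts stay unassigned and are
#' flagged CONFLICT.
#'
#' @inheritParams reconcile
#' @param confirmations confirmation tibble from [confirm_y()] (or `NULL`
#'   for no marker evidence).
#' @return tibble (`scaffold_id`, `length`, `label`, `provenance`).
#' @export
consensus_assignment <- function(ad, anchors, confirmations = NULL) {
  rec <- reconcile(ad, anchors)
  d <- rec$detail
  confirmed <- if (is.null(confirmations)) character(0) else
    confirmations$scaffold_id[confirmations$confirmed]
  label <- character(nrow(d))
  prov <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (d$scaffold_id[i] %in% confirmed) {
      label[i] <- "chrY"
      prov[i] <- if (d$homology_group[i] == "Y") "BOTH" else "COVERAGE_ONLY"
    } else if (d$category[i] == "agree") {
      label[i] <- d$homology_chromosome[i]; prov[i] <- "BOTH"
    } else if (d$homology_group[i] != "UNASSIGNED" &&
               d$coverage_group[i] == "UNASSIGNED") {
      label[i] <- d$homology_chromosome[i]; prov[i] <- "HOMOLOGY_ONLY"
    } else if (d$coverage_group[i] != "UNASSIGNED" &&
               d$homology_group[i] == "UNASSIGNED") {
      label[i] <- switch(d$coverage_group[i], X = "chrX", Y = "chrY",
                         AUTOSOME = "autosome_unplaced")
      prov[i] <- "COVERAGE_ONLY"
    } else if (d$category[i] == "conflict") {
      label[i] <- "unassigned"; prov[i] <- "CONFLICT"
    } else {
      label[i] <- "unassigned"; prov[i] <- "NONE"
    }
  }
  tibble::tibble(scaffold_id = d$scaffold_id, length = d$length,
                 label = label, provenance = prov)
}
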