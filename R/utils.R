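`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a per-stage RNG substream seed
#'
#' One user-facing seed drives the whole simulator; each stage (karyotype,
#' depths, alignments, markers) draws from its own substream so that adding
#' or reordering stages never perturbs the others. The substream seed is a
#' polynomial hash of the stage name added to the base seed, modulo 2^31-1.
#'
#' @param seed integer base seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

with_stage_rng <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

#' Length-weighted median
#'
#' Smallest value whose cumulative weight reaches half the total weight —
#' identical to the ordinary median of the vector obtained by repeating each
#' value `w` times (lower median for even totals).
#'
#' @param x numeric values.
#' @param w non-negative weights (e.g. scaffold lengths in bp).
#' @return a single numeric.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  ord <- order(x)
  cw <- cumsum(w[ord])
  x[ord][which(cw >= cw[length(cw)] / 2)[1L]]
}

#' Map a chromosome name to its comparison group
#'
#' Coverage evidence can only distinguish autosome / X / Y, so cross-method
#' comparison happens at that grouping: `chrX`-like names map to `"X"`,
#' `chrY`-like to `"Y"`, `"UNASSIGNED"` passes through, everything else is
#' `"AUTOSOME"`.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector over \{AUTOSOME, X, Y, UNASSIGNED\}.
#' @export
chrom_group <- function(chrom) {
  core <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  out <- rep("AUTOSOME", length(chrom))
  out[core == "X"] <- "X"
  out[core == "Y"] <- "Y"
  out[is.na(chrom) | core == "UNASSIGNED"] <- "UNASSIGNED"
  out
}

coverage_class_levels <- c("AUTOSOME", "X", "Y", "UNASSIGNED")

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("sexscaff_input_error", "error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("sexscaff_validation_error", "error")))
}
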