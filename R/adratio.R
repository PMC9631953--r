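# The AD-ratio (average-depth ratio) statistic: normalized female:male mean
# depth per scaffold. Autosomal scaffolds sit near 1 (equal dosage in both
# sexes), X-linked near 2 (two female X copies vs one male), Y-linked near 0
# (no female Y), so fixed bands around those values classify scaffolds.

#' AD-ratio classification thresholds
#'
#' The classification bands: autosomal for 0.7 < r < 1.3, X-linked for
#' 1.7 < r < 2.3 (both open intervals), Y-linked for r <= 0.3 (closed), with
#' everything else unassigned. Ratios at or below `y_high_conf` (0.01) are
#' additionally flagged high-confidence Y. Scaffolds whose male depth falls
#' below `min_male_depth` get an undefined ratio (division-blow-up guard) and
#' are reported as unassigned.
#'
#' @param autosome_lo,autosome_hi open autosomal band (default 0.7, 1.3).
#' @param x_lo,x_hi open X band (default 1.7, 2.3).
#' @param y_max inclusive Y threshold (default 0.3).
#' @param y_high_conf high-confidence Y flag threshold (default 0.01).
#' @param min_male_depth minimum male depth (x) for a defined ratio
#'   (default 1.0).
#' @return an `ad_thresholds` list.
#' @export
ad_thresholds <- function(autosome_lo = 0.7, autosome_hi = 1.3,
                          x_lo = 1.7, x_hi = 2.3,
                          y_max = 0.3, y_high_conf = 0.01,
                          min_male_depth = 1.0) {
  th <- list(autosome_lo = autosome_lo, autosome_hi = autosome_hi,
             x_lo = x_lo, x_hi = x_hi, y_max = y_max,
             y_high_conf = y_high_conf, min_male_depth = min_male_depth)
  ok <- 0 <= th$y_high_conf && th$y_high_conf <= th$y_max &&
    th$y_max < th$autosome_lo && th$autosome_lo < th$autosome_hi &&
    th$autosome_hi < th$x_lo && th$x_lo < th$x_hi
  if (!ok) {
    stop_validation(
      "thresholds must satisfy 0 <= y_high_conf <= y_max < autosome_lo < autosome_hi < x_lo < x_hi")
  }
  structure(th, class = "ad_thresholds")
}

check_same_scaffolds <- function(male, female) {
  only_m <- setdiff(male$scaffold_id, female$scaffold_id)
  only_f <- setdiff(female$scaffold_id, male$scaffold_id)
  if (length(only_m) + length(only_f) > 0) {
    stop_input(
      "scaffolds present in one sex only: %s",
      paste(utils::head(c(only_m, only_f), 10), collapse = ", "))
  }
}

#' Normalization factor for the female:male depth ratio
#'
#' Raw per-scaffold ratios F/M are rescaled by a factor k so autosomal
#' scaffolds center at 1. `mode = "median"` (default) chooses k so the
#' length-weighted median raw ratio equals 1 — robust, since the few percent
#' of sex-linked sequence cannot move a weighted median dominated by
#' autosomes. `mode = "total"` uses overall depth mass:
#' k = sum(M_i L_i) / sum(F_i L_i).
#'
#' @param male,female depth-summary tibbles covering the same scaffolds.
#' @param mode `"median"` or `"total"`.
#' @param thresholds an [ad_thresholds()]; scaffolds with male depth below
#'   `min_male_depth` are excluded from factor estimation.
#' @return a single positive numeric k such that AD-ratio_i = (F_i/M_i) * k.
#' @examples
#' m <- tibble::tibble(scaffold_id = c("s1", "s2"), length = c(100, 100),
#'                     mean_depth = c(30, 30), sample_sex = "male")
#' f <- m; f$sample_sex <- "female"; f$mean_depth <- c(60, 60)
#' compute_normalization(m, f, mode = "total")  # 0.5
#' @export
compute_normalization <- function(male, female, mode = c("median", "total"),
                                  thresholds = ad_thresholds()) {
  mode <- match.arg(mode)
  if (nrow(male) == 0 || nrow(female) == 0) {
    stop_input("empty depth table(s)")
  }
  check_same_scaffolds(male, female)
  f <- female[match(male$scaffold_id, female$scaffold_id), ]
  ok <- male$mean_depth >= thresholds$min_male_depth
  if (!any(ok)) {
    stop_input("all male depths below min_male_depth (%g x): cannot normalize",
               thresholds$min_male_depth)
  }
  if (mode == "median") {
    raw <- f$mean_depth[ok] / male$mean_depth[ok]
    med <- weighted_median(raw, male$length[ok])
    if (med <= 0) stop_input("length-weighted median raw ratio is 0")
    1 / med
  } else {
    denom <- sum(f$mean_depth[ok] * f$length[ok])
    if (denom <= 0) stop_input("total female depth mass is 0")
    sum(male$mean_depth[ok] * male$length[ok]) / denom
  }
}

#' Compute per-scaffold AD-ratios
#'
#' AD-ratio_i = (female_depth_i / male_depth_i) * factor when the male depth
#' is at least `min_male_depth`; otherwise the ratio is `NA` (undefined) and
#' the scaffold will be reported unassigned.
#'
#' @inheritParams compute_normalization
#' @param factor normalization factor from [compute_normalization()].
#' @return AD-ratio record tibble (`scaffold_id`, `length`, `male_depth`,
#'   `female_depth`, `ad_ratio`).
#' @export
compute_ad_ratios <- function(male, female, factor,
                              thresholds = ad_thresholds()) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop_input("normalization factor must be a single positive number")
  }
  check_same_scaffolds(male, female)
  f <- female[match(male$scaffold_id, female$scaffold_id), ]
  defined <- male$mean_depth >= thresholds$min_male_depth
  tibble::tibble(
    scaffold_id = male$scaffold_id,
    length = male$length,
    male_depth = male$mean_depth,
    female_depth = f$mean_depth,
    ad_ratio = ifelse(defined, f$mean_depth / male$mean_depth * factor, NA_real_)
  )
}

#' Classify scaffolds from their AD-ratio
#'
#' Band semantics follow the printed inequalities exactly: the autosomal and
#' X intervals are open (a ratio of exactly 0.7, 1.3, 1.7 or 2.3 is
#' unassigned) while the Y rule is inclusive (r <= y_max). Undefined ratios
#' are unassigned.
#'
#' @param records AD-ratio record tibble from [compute_ad_ratios()].
#' @param thresholds an [ad_thresholds()].
#' @return `records` with `coverage_class` (factor over AUTOSOME/X/Y/
#'   UNASSIGNED) and `high_confidence_y` columns added.
#' @examples
#' r <- tibble::tibble(scaffold_id = "s", length = 1, male_depth = 30,
#'                     female_depth = 30, ad_ratio = 1.0)
#' classify_scaffolds(r)$coverage_class  # AUTOSOME
#' @export
classify_scaffolds <- function(records, thresholds = ad_thresholds()) {
  r <- records$ad_ratio
  cls <- rep("UNASSIGNED", length(r))
  cls[!is.na(r) & r > thresholds$autosome_lo & r < thresholds$autosome_hi] <- "AUTOSOME"
  cls[!is.na(r) & r > thresholds$x_lo & r < thresholds$x_hi] <- "X"
  cls[!is.na(r) & r <= thresholds$y_max] <- "Y"
  records$coverage_class <- factor(cls, levels = coverage_class_levels)
  records$high_confidence_y <- !is.na(r) & r <= thresholds$y_high_conf
  records
}

#' Length-weighted AD-ratio histogram
#'
#' Total scaffold length per AD-ratio bin. Bins are half-open
#' `[k*w, (k+1)*w)`; each scaffold with a defined ratio contributes its full
#' length to exactly one bin; ratios at or above `range_max` pool into a
#' final overflow bin starting at `range_max`.
#'
#' @param records AD-ratio record tibble.
#' @param bin_width bin width (default 0.025).
#' @param range_max start of the overflow bin (default 3).
#' @return tibble (`lower_edge`, `upper_edge`, `total_length`), including
#'   empty bins from 0 to `range_max`.
#' @export
ad_histogram <- function(records, bin_width = 0.025, range_max = 3) {
  if (bin_width <= 0) stop_input("bin_width must be > 0")
  r <- records$ad_ratio[!is.na(records$ad_ratio)]
  len <- records$length[!is.na(records$ad_ratio)]
  n_bins <- ceiling(range_max / bin_width - 1e-9)
  # snap near-exact multiples of the width onto the edge before flooring so
  # that e.g. r = 1.025 lands in [1.025, 1.050) despite binary rounding
  q <- r / bin_width
  q <- ifelse(abs(q - round(q)) < 1e-9, round(q), floor(q))
  idx <- pmin(floor(q), n_bins) + 1L
  totals <- vapply(seq_len(n_bins + 1L), function(k) sum(len[idx == k]),
                   numeric(1))
  lower <- c(seq_len(n_bins) - 1L, n_bins) * bin_width
  lower[n_bins + 1L] <- range_max
  upper <- c(seq_len(n_bins) * bin_width, Inf)
  tibble::tibble(lower_edge = lower, upper_edge = upper,
                 total_length = totals)
}

#' Summarize coverage classes
#'
#' @param records classified AD-ratio record tibble.
#' @return tibble with one row per class (`coverage_class`, `n_scaffolds`,
#'   `total_bp`, `fraction`); fractions sum to 1 over the four classes.
#' @export
summarize_coverage_classes <- function(records) {
  if (nrow(records) == 0) stop_input("no scaffolds to summarize")
  if (!"coverage_class" %in% names(records)) {
    stop_input("records not classified; run classify_scaffolds() first")
  }
  out <- dplyr::summarise(
    dplyr::group_by(records, coverage_class = .data$coverage_class,
                    .drop = FALSE),
    n_scaffolds = dplyr::n(),
    total_bp = sum(.data$length),
    .groups = "drop"
  )
  out$fraction <- out$total_bp / sum(records$length)
  out
}

#' Plot the length-weighted AD-ratio histogram
#'
#' Bars colored by the band each bin midpoint falls in (Y green, autosomal
#' red, X blue, unassigned black).
#'
#' @param hist tibble from [ad_histogram()].
#' @param thresholds an [ad_thresholds()].
#' @return a ggplot object.
#' @export
plot_ad_histogram <- function(hist, thresholds = ad_thresholds()) {
  mid <- ifelse(is.finite(hist$upper_edge),
                (hist$lower_edge + hist$upper_edge) / 2, hist$lower_edge)
  band <- rep("unassigned", nrow(hist))
  band[mid <= thresholds$y_max] <- "Y"
  band[mid > thresholds$autosome_lo & mid < thresholds$autosome_hi] <- "autosomal"
  band[mid > thresholds$x_lo & mid < thresholds$x_hi] <- "X"
  df <- data.frame(lower_edge = hist$lower_edge, mb = hist$total_length / 1e6,
                   band = band)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lower_edge, y = .data$mb,
                                   fill = .data$band)) +
    ggplot2::geom_col(width = min(diff(unique(hist$lower_edge)))) +
    ggplot2::scale_fill_manual(values = c(Y = "darkgreen", autosomal = "firebrick",
                                          X = "steelblue", unassigned = "black")) +
    ggplot2::labs(x = "AD-ratio", y = "Total length (Mb)", fill = "Band") +
    ggplot2::theme_minimal()
}
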