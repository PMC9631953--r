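# Homology anchoring: assign each scaffold to the reference chromosome that
# dominates its merged aligned bases. Overlapping local alignments are merged
# per chromosome before summing, so repeat-driven multi-mapping cannot
# inflate a chromosome's support by covering the same query bases twice.

#' Merged aligned bases per scaffold and chromosome
#'
#' For each (scaffold, chromosome) pair, overlapping or adjacent query
#' intervals are merged and their widths summed, so each query base counts at
#' most once per chromosome. The result is bounded by the scaffold length for
#' every chromosome.
#'
#' @param hits alignment-hit tibble with `scaffold_id`, `q_start`, `q_end`
#'   (0-based half-open) and `chromosome`.
#' @return tibble (`scaffold_id`, `chromosome`, `merged_bp`).
#' @examples
#' h <- tibble::tibble(scaffold_id = "s", q_start = c(0, 50),
#'                     q_end = c(100, 150), chromosome = "chr1")
#' merged_coverage(h)$merged_bp  # 150
#' @export
merged_coverage <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(scaffold_id = character(), chromosome = character(),
                          merged_bp = numeric()))
  }
  if (any(hits$q_start >= hits$q_end)) {
    stop_input("alignment hits must have q_start < q_end")
  }
  key <- paste(hits$scaffold_id, hits$chromosome, sep = "\r")
  merged <- vapply(split(seq_len(nrow(hits)), key), function(i) {
    ir <- IRanges::IRanges(start = hits$q_start[i] + 1L, end = hits$q_end[i])
    sum(IRanges::width(IRanges::reduce(ir)))
  }, numeric(1))
  parts <- strsplit(names(merged), "\r", fixed = TRUE)
  out <- tibble::tibble(
    scaffold_id = vapply(parts, `[[`, character(1), 1),
    chromosome = vapply(parts, `[[`, character(1), 2),
    merged_bp = unname(merged)
  )
  dplyr::arrange(out, .data$scaffold_id, .data$chromosome)
}

#' Assign scaffolds to chromosomes by best-hit dominance
#'
#' Let B_c be the merged aligned bases of a scaffold on chromosome c and
#' T = sum(B_c). The scaffold is assigned to argmax_c B_c iff (i) T > 0,
#' (ii) the best chromosome holds at least `dominance_min` of T with a strict
#' argmax (an exact tie is never assigned), and (iii) at least `coverage_min`
#' of the scaffold length is aligned (T / length). Otherwise the scaffold is
#' unassigned with reason NO_HITS, NO_DOMINANT or LOW_COVERAGE.
#'
#' @param merged tibble from [merged_coverage()].
#' @param lengths tibble (`scaffold_id`, `length`) covering all scaffolds,
#'   including those without hits (e.g. from [read_fai()]).
#' @param dominance_min minimum share of merged aligned bases on the best
#'   chromosome (default 0.5).
#' @param coverage_min minimum aligned fraction of the scaffold (default
#'   0.05).
#' @return assignment tibble (`scaffold_id`, `length`,
#'   `assigned_chromosome`, `reason`, `dominance`, `coverage_fraction`).
#' @export
assign_chromosomes <- function(merged, lengths, dominance_min = 0.5,
                               coverage_min = 0.05) {
  if (nrow(lengths) == 0) stop_input("empty scaffold length table")
  by_scaffold <- split(merged[, c("chromosome", "merged_bp")],
                       merged$scaffold_id)
  one <- function(id, len) {
    m <- by_scaffold[[id]]
    if (is.null(m) || nrow(m) == 0 || sum(m$merged_bp) == 0) {
      return(list(chrom = "UNASSIGNED", reason = "NO_HITS",
                  dominance = NA_real_, coverage = 0))
    }
    total <- sum(m$merged_bp)
    best <- max(m$merged_bp)
    dominance <- best / total
    coverage <- total / len
    tie <- sum(m$merged_bp == best) > 1
    if (tie || dominance < dominance_min) {
      list(chrom = "UNASSIGNED", reason = "NO_DOMINANT",
           dominance = dominance, coverage = coverage)
    } else if (coverage < coverage_min) {
      list(chrom = "UNASSIGNED", reason = "LOW_COVERAGE",
           dominance = dominance, coverage = coverage)
    } else {
      list(chrom = m$chromosome[which.max(m$merged_bp)], reason = "OK",
           dominance = dominance, coverage = coverage)
    }
  }
  res <- unname(Map(one, lengths$scaffold_id, lengths$length))
  tibble::tibble(
    scaffold_id = lengths$scaffold_id,
    length = lengths$length,
    assigned_chromosome = vapply(res, `[[`, character(1), "chrom"),
    reason = vapply(res, `[[`, character(1), "reason"),
    dominance = vapply(res, `[[`, numeric(1), "dominance"),
    coverage_fraction = vapply(res, `[[`, numeric(1), "coverage")
  )
}

#' Summarize chromosome anchoring
#'
#' @param assignments tibble from [assign_chromosomes()].
#' @return list with `per_chromosome` (chromosome incl. UNASSIGNED,
#'   scaffold count, total bp, percent of scaffolds, percent of genome
#'   length; both percentage columns sum to 100) and `assigned_fraction`
#'   (length-weighted fraction of the genome anchored).
#' @export
summarize_anchoring <- function(assignments) {
  if (nrow(assignments) == 0) stop_input("no assignments to summarize")
  tab <- dplyr::summarise(
    dplyr::group_by(assignments, chromosome = .data$assigned_chromosome),
    n_scaffolds = dplyr::n(),
    total_bp = sum(.data$length),
    .groups = "drop"
  )
  tab$pct_scaffolds <- 100 * tab$n_scaffolds / sum(tab$n_scaffolds)
  tab$pct_length <- 100 * tab$total_bp / sum(tab$total_bp)
  tab <- tab[order(tab$chromosome == "UNASSIGNED", tab$chromosome), ]
  assigned <- assignments$assigned_chromosome != "UNASSIGNED"
  list(
    per_chromosome = tab,
    assigned_fraction = sum(assignments$length[assigned]) /
      sum(assignments$length),
    assigned_scaffold_fraction = mean(assigned)
  )
}
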