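# Independent oracles and tiny fixtures shared across tests.

# Per-base brute-force union size of 0-based half-open intervals.
brute_force_union <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts)) {
    covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(covered)
}

# Weighted median by explicit expansion: repeat each value w times and take
# the element at rank ceiling(n / 2).
expand_median <- function(x, w) {
  v <- sort(rep(x, times = w))
  v[ceiling(length(v) / 2)]
}

# Depth-summary tibble shorthand.
depth_tbl <- function(ids, lengths, depths, sex) {
  tibble::tibble(scaffold_id = ids, length = lengths, mean_depth = depths,
                 sample_sex = sex)
}

# AD-ratio record shorthand (ratios given directly).
ad_tbl <- function(ids, lengths, ratios) {
  tibble::tibble(scaffold_id = ids, length = lengths,
                 male_depth = 55, female_depth = 55 * ratios,
                 ad_ratio = ratios)
}

# Small fast config: ~60 scaffolds on a 6 Mb genome, same noise regime as
# the defaults.
tiny_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    chrom_lengths = c(chr1 = 2.2e6, chr2 = 1.6e6, chr3 = 1.0e6,
                      chrX = 0.9e6, chrY = 0.3e6),
    scaffold_len_logmean = log(8e4), scaffold_len_logsd = 0.6,
    ...
  )
}

truth_group <- function(truth) chrom_group(truth$true_chromosome)
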