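test_that("karyotype fragmentation partitions every chromosome exactly", {
  cfg <- sim_config(seed = 11)
  truth <- simulate_karyotype(cfg)
  sums <- tapply(truth$length, truth$true_chromosome, sum)
  expect_equal(sums[names(cfg$chrom_lengths)],
               cfg$chrom_lengths[names(cfg$chrom_lengths)],
               ignore_attr = TRUE)
  expect_false(anyDuplicated(truth$scaffold_id) > 0)
  # offsets tile each chromosome without overlap
  for (chrom in names(cfg$chrom_lengths)) {
    sub <- truth[truth$true_chromosome == chrom, ]
    sub <- sub[order(sub$offset), ]
    expect_equal(sub$offset, cumsum(c(0, sub$length[-nrow(sub)])))
  }
})

test_that("a chromosome that fits one scaffold yields the degenerate partition", {
  cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 1000),
                    scaffold_len_logmean = log(1e6), min_scaffold_len = 100)
  truth <- simulate_karyotype(cfg)
  expect_equal(nrow(truth), 1L)
  expect_equal(truth$length, 1000)
  expect_equal(truth$offset, 0)
})

test_that("a chromosome shorter than the minimum scaffold size is a config error", {
  expect_error(sim_config(chrom_lengths = c(chr1 = 500), min_scaffold_len = 1000),
               class = "sexscaff_validation_error")
})

test_that("the simulator is deterministic per seed and varies across seeds", {
  cfg <- sim_config(seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  other <- simulate_dataset(sim_config(seed = 43))
  expect_false(identical(a$male_depth$mean_depth, other$male_depth$mean_depth))
})

test_that("expected depths follow X/Y dosage and vanish in the noise-free limit", {
  cfg <- tiny_config(seed = 3, depth_cv = 1e-6, female_y_background = 0)
  truth <- simulate_karyotype(cfg)
  d <- simulate_depths(truth, cfg)
  grp <- truth_group(truth)
  expect_equal(d$male$mean_depth[grp == "AUTOSOME"],
               rep(55, sum(grp == "AUTOSOME")), tolerance = 1e-3)
  expect_equal(d$female$mean_depth[grp == "AUTOSOME"],
               rep(55, sum(grp == "AUTOSOME")), tolerance = 1e-3)
  expect_equal(d$male$mean_depth[grp %in% c("X", "Y")],
               rep(27.5, sum(grp %in% c("X", "Y"))), tolerance = 1e-3)
  expect_equal(d$female$mean_depth[grp == "X"],
               rep(55, sum(grp == "X")), tolerance = 1e-3)
  expect_identical(d$female$mean_depth[grp == "Y"],
                   rep(0, sum(grp == "Y")))
  expect_identical(d$male$scaffold_id, truth$scaffold_id)
  expect_identical(d$female$scaffold_id, truth$scaffold_id)
})

test_that("mean female:male autosomal ratio matches a brute-force Gamma-ratio oracle", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 115e6, chrY = 0.3e6),
                    scaffold_len_logmean = log(1e5), scaffold_len_logsd = 0.2)
  truth <- simulate_karyotype(cfg)
  auto <- truth_group(truth) == "AUTOSOME"
  expect_gte(sum(auto), 1000)
  d <- simulate_depths(truth, cfg)
  r <- d$female$mean_depth[auto] / d$male$mean_depth[auto]
  # oracle: direct large-n simulation of the ratio of two depth draws with
  # the same shared-bias + residual structure (bias cancels in the ratio)
  set.seed(99)
  cvr <- cfg$depth_cv_resid
  shape <- 1 / cvr^2
  oracle <- rgamma(2e5, shape, shape) / rgamma(2e5, shape, shape)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - mean(oracle)), 3 * se + 3 * sd(oracle) / sqrt(2e5))
  expect_lt(abs(mean(r) - 1), 0.01)
})

test_that("empirical depth CV tracks the configured depth_cv", {
  cfg <- sim_config(seed = 8)
  truth <- simulate_karyotype(cfg)
  d <- simulate_depths(truth, cfg)
  auto <- truth_group(truth) == "AUTOSOME"
  expect_gte(sum(auto), 500)
  cv <- sd(d$male$mean_depth[auto]) / mean(d$male$mean_depth[auto])
  expect_gt(cv, 0.08)
  expect_lt(cv, 0.12)
})

test_that("alignment evidence respects miss and chimera limits", {
  cfg0 <- tiny_config(seed = 2, aln_miss_prob = 1)
  truth0 <- simulate_karyotype(cfg0)
  aln <- simulate_alignments(truth0, cfg0)
  expect_equal(nrow(aln[aln$chromosome == truth0$true_chromosome[
    match(aln$scaffold_id, truth0$scaffold_id)], ]), 0)

  cfg1 <- tiny_config(seed = 2, aln_miss_prob = 0, aln_chimera_prob = 0)
  truth1 <- simulate_karyotype(cfg1)
  aln1 <- simulate_alignments(truth1, cfg1)
  expect_setequal(unique(aln1$scaffold_id), truth1$scaffold_id)
  expect_identical(
    aln1$chromosome,
    truth1$true_chromosome[match(aln1$scaffold_id, truth1$scaffold_id)])
  # true blocks jointly cover at least half of each scaffold
  cov <- merged_coverage(aln1)
  frac <- cov$merged_bp / truth1$length[match(cov$scaffold_id,
                                              truth1$scaffold_id)]
  expect_true(all(frac >= 0.5))
  expect_true(all(frac <= 1))
})

test_that("wrong-chromosome block rate sits in the binomial 99% CI of aln_chimera_prob", {
  cfg <- sim_config(seed = 21)
  truth <- simulate_karyotype(cfg)
  aln <- simulate_alignments(truth, cfg)
  wrong <- aln$chromosome != truth$true_chromosome[match(aln$scaffold_id,
                                                         truth$scaffold_id)]
  n_wrong <- length(unique(aln$scaffold_id[wrong]))
  n <- nrow(truth)
  ci <- qbinom(c(0.005, 0.995), n, cfg$aln_chimera_prob)
  expect_gte(n_wrong, ci[1])
  expect_lte(n_wrong, ci[2])
})

test_that("marker simulation places genes and reproduces its seeded draws", {
  cfg1 <- tiny_config(seed = 4, n_y_genes = 1, y_gene_ambiguous_frac = 0)
  truth <- simulate_karyotype(cfg1)
  mk <- simulate_marker_hits(truth, cfg1)
  yg <- mk$hits[mk$hits$gene_class == "Y_GENE", ]
  hom <- mk$hits[mk$hits$gene_class == "HOMOLOG", ]
  expect_equal(nrow(yg), 1L)
  expect_equal(nrow(hom), 1L)
  truth_y <- truth$scaffold_id[truth_group(truth) == "Y"]
  expect_true(yg$scaffold_id %in% truth_y)
  expect_false(hom$scaffold_id %in% truth_y)
  expect_lt(yg$evalue, 1e-20)

  cfg2 <- tiny_config(seed = 4, n_y_genes = 5, y_gene_ambiguous_frac = 1)
  mk2 <- simulate_marker_hits(truth, cfg2)
  for (g in unique(mk2$hits$gene[mk2$hits$gene_class == "Y_GENE"])) {
    h <- mk2$hits[mk2$hits$gene == g & mk2$hits$gene_class == "Y_GENE", ]
    best <- tapply(h$bitscore, h$scaffold_id, max)
    expect_gte(length(best), 2)
    expect_lt(max(best) / min(best), 1.25)
  }

  cfg3 <- sim_config(seed = 12)
  truth3 <- simulate_karyotype(cfg3)
  mk3a <- simulate_marker_hits(truth3, cfg3)
  mk3b <- simulate_marker_hits(truth3, cfg3)
  expect_identical(mk3a, mk3b)
  expect_equal(sum(mk3a$gene_truth$ambiguous) + sum(!mk3a$gene_truth$ambiguous),
               cfg3$n_y_genes)
})

test_that("marker simulation requires a Y scaffold", {
  cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 1e6))
  truth <- simulate_karyotype(cfg)
  expect_error(simulate_marker_hits(truth, cfg),
               class = "sexscaff_input_error")
})
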