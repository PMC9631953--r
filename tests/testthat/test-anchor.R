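test_that("alignment dialects normalize to 0-based half-open query intervals", {
  dir <- withr::local_tempdir()
  paf <- file.path(dir, "a.paf")
  writeLines("scf1\t500\t0\t100\t+\tchr1\t9000\t200\t300\t95\t100\t60", paf)
  h <- parse_alignments(paf, "paf")
  expect_equal(c(h$q_start, h$q_end), c(0, 100))

  coords <- file.path(dir, "a.coords")
  writeLines(c("/ref.fa /qry.fa", "NUCMER", "",
               "[S1]\t[E1]\t[S2]\t[E2]\t[LEN 1]\t[LEN 2]\t[% IDY]\t[TAGS]",
               "201\t300\t1\t100\t100\t100\t97.5\tchr1\tscf1"), coords)
  h2 <- parse_alignments(coords, "nucmer_coords")
  expect_equal(c(h2$q_start, h2$q_end), c(0, 100))
  expect_equal(h2$scaffold_id, "scf1")
  expect_equal(h2$chromosome, "chr1")

  b6 <- file.path(dir, "a.blast6")
  writeLines("scf1\tchr1\t97.5\t100\t2\t0\t100\t1\t201\t300\t1e-30\t180", b6)
  h3 <- parse_alignments(b6, "blast6")
  expect_equal(c(h3$q_start, h3$q_end), c(0, 100))
  expect_equal(h3$aligned_len, 100)

  bad <- file.path(dir, "bad.paf")
  writeLines(c("scf1\t500\t0\t100\t+\tchr1\t9000\t200\t300\t95\t100\t60",
               "scf2\tonly\tthree"), bad)
  expect_error(parse_alignments(bad, "paf"), "line")
  expect_error(parse_alignments(paf, "bogus"))
})

test_that("merged coverage unions overlapping, adjacent and nested intervals", {
  h <- tibble::tibble(scaffold_id = "s",
                      q_start = c(0, 50), q_end = c(100, 150),
                      chromosome = "chr1")
  expect_equal(merged_coverage(h)$merged_bp, 150)
  h2 <- tibble::tibble(scaffold_id = "s", q_start = c(0, 20),
                       q_end = c(10, 30), chromosome = "chr1")
  expect_equal(merged_coverage(h2)$merged_bp, 20)
  h3 <- tibble::tibble(scaffold_id = "s", q_start = c(0, 10),
                       q_end = c(100, 20), chromosome = "chr1")
  expect_equal(merged_coverage(h3)$merged_bp, 100)
  expect_error(merged_coverage(tibble::tibble(scaffold_id = "s", q_start = 5,
                                              q_end = 5, chromosome = "c")),
               class = "sexscaff_input_error")
})

test_that("merged coverage equals the per-base oracle on random hit sets", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    starts <- sample(0:500, n, replace = TRUE)
    ends <- starts + sample(1:100, n, replace = TRUE)
    h <- tibble::tibble(scaffold_id = "s", q_start = starts, q_end = ends,
                        chromosome = "chr1")
    expect_identical(merged_coverage(h)$merged_bp,
                     as.numeric(brute_force_union(starts, ends)))
  }
})

test_that("dominance assignment follows the best-hit rule with reasons", {
  lens <- tibble::tibble(scaffold_id = c("s1", "s2", "s3", "s4"),
                         length = c(2000, 1000, 1000, 100000))
  merged <- tibble::tibble(
    scaffold_id = c("s1", "s1", "s2", "s2", "s4"),
    chromosome = c("chr1", "chr2", "chr1", "chr2", "chr1"),
    merged_bp = c(900, 100, 500, 500, 1000)
  )
  a <- assign_chromosomes(merged, lens)
  expect_equal(a$assigned_chromosome, c("chr1", "UNASSIGNED", "UNASSIGNED",
                                        "UNASSIGNED"))
  expect_equal(a$reason, c("OK", "NO_DOMINANT", "NO_HITS", "LOW_COVERAGE"))
  expect_equal(a$dominance[1], 0.9)
  expect_equal(a$coverage_fraction[1], 0.5)
  # sub-threshold dominance without a tie is also NO_DOMINANT
  m2 <- tibble::tibble(scaffold_id = "s2", chromosome = c("chr1", "chr2", "chr3"),
                       merged_bp = c(400, 350, 250))
  expect_equal(assign_chromosomes(m2, lens[2, ])$reason, "NO_DOMINANT")
})

test_that("assignments are invariant to hit-row order", {
  cfg <- tiny_config(seed = 9)
  truth <- simulate_karyotype(cfg)
  aln <- simulate_alignments(truth, cfg)
  lens <- truth[, c("scaffold_id", "length")]
  a1 <- assign_chromosomes(merged_coverage(aln), lens)
  set.seed(1)
  a2 <- assign_chromosomes(merged_coverage(aln[sample(nrow(aln)), ]), lens)
  expect_identical(a1, a2)
})

test_that("anchoring summary percentages cover the whole genome", {
  a <- tibble::tibble(scaffold_id = c("s1", "s2", "s3"),
                      length = c(100, 100, 100),
                      assigned_chromosome = c("chr1", "chr1", "UNASSIGNED"),
                      reason = c("OK", "OK", "NO_HITS"),
                      dominance = c(1, 1, NA), coverage_fraction = c(1, 1, 0))
  s <- summarize_anchoring(a)
  chr1 <- s$per_chromosome[s$per_chromosome$chromosome == "chr1", ]
  expect_equal(chr1$pct_length, 200 / 3)
  expect_equal(sum(s$per_chromosome$pct_length), 100)
  expect_equal(sum(s$per_chromosome$pct_scaffolds), 100)
  a$assigned_chromosome <- "UNASSIGNED"
  expect_equal(summarize_anchoring(a)$assigned_fraction, 0)
  expect_error(summarize_anchoring(a[0, ]), class = "sexscaff_input_error")
})

test_that("assigned length fraction recovers 1 - aln_miss_prob on synthetic data", {
  cfg <- sim_config(seed = 31, aln_miss_prob = 0.05, aln_chimera_prob = 0)
  truth <- simulate_karyotype(cfg)
  aln <- simulate_alignments(truth, cfg)
  a <- assign_chromosomes(merged_coverage(aln),
                          truth[, c("scaffold_id", "length")])
  n_assigned <- sum(a$assigned_chromosome != "UNASSIGNED")
  ci <- qbinom(c(0.005, 0.995), nrow(truth), 0.95)
  expect_gte(n_assigned, ci[1])
  expect_lte(n_assigned, ci[2])
  # every assignment matches truth when there is no chimerism
  ok <- a$assigned_chromosome == "UNASSIGNED" |
    a$assigned_chromosome == truth$true_chromosome[match(a$scaffold_id,
                                                         truth$scaffold_id)]
  expect_true(all(ok))
})
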