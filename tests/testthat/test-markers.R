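mk_hit <- function(gene, gene_class, partner, scaffold, bitscore, evalue,
                   s_start = 100, s_end = 1100) {
  tibble::tibble(gene = gene, gene_class = gene_class, partner_gene = partner,
                 scaffold_id = scaffold, pident = 90, aln_len = 1000,
                 mismatch = 10, gapopen = 0L, q_start = 1, q_end = 1000,
                 s_start = s_start, s_end = s_end, evalue = evalue,
                 bitscore = bitscore)
}

test_that("gene placement applies the e-value cutoff and ambiguity margin", {
  h1 <- mk_hit("SRY", "Y_GENE", "SOX3", "scfY", 500, 1e-20)
  p1 <- place_genes(h1)
  expect_equal(p1$status, "PLACED")
  expect_equal(p1$scaffold_id, "scfY")

  p2 <- place_genes(mk_hit("SRY", "Y_GENE", "SOX3", "scfY", 500, 1e-5))
  expect_equal(p2$status, "UNPLACED_NO_HIT")
  expect_true(is.na(p2$scaffold_id))

  h3 <- rbind(mk_hit("ATRY", "Y_GENE", "ATRX", "scfA", 200, 1e-20),
              mk_hit("ATRY", "Y_GENE", "ATRX", "scfB", 190, 1e-20))
  p3 <- place_genes(h3)
  expect_equal(p3$status, "UNPLACED_AMBIGUOUS")
  expect_equal(p3$best_bitscore, 200)
  expect_equal(p3$runner_up_bitscore, 190)

  # duplicate (gene, scaffold) rows aggregate by summed bitscore
  h4 <- rbind(mk_hit("RBMY", "Y_GENE", "RBMX", "scfA", 150, 1e-20),
              mk_hit("RBMY", "Y_GENE", "RBMX", "scfA", 150, 1e-20),
              mk_hit("RBMY", "Y_GENE", "RBMX", "scfB", 200, 1e-20))
  p4 <- place_genes(h4)
  expect_equal(p4$status, "PLACED")
  expect_equal(p4$scaffold_id, "scfA")
  expect_equal(p4$best_bitscore, 300)
})

test_that("every manifest gene yields exactly one placement row", {
  manifest <- tibble::tibble(gene = c("SRY", "SOX3", "UTY"),
                             gene_class = c("Y_GENE", "HOMOLOG", "Y_GENE"),
                             partner_gene = c("SOX3", "SRY", "UTX"))
  p <- place_genes(mk_hit("SRY", "Y_GENE", "SOX3", "scfY", 500, 1e-30),
                   manifest)
  expect_equal(sort(p$gene), sort(manifest$gene))
  expect_equal(p$status[p$gene == "UTY"], "UNPLACED_NO_HIT")
  expect_equal(anyDuplicated(p$gene), 0L)
})

test_that("placement is monotone in the cutoffs", {
  set.seed(23)
  hits <- dplyr::bind_rows(lapply(1:15, function(i) {
    n <- sample(1:3, 1)
    dplyr::bind_rows(lapply(seq_len(n), function(j) {
      mk_hit(paste0("G", i), "Y_GENE", paste0("H", i),
             paste0("scf", sample(1:6, 1)), runif(1, 100, 500),
             10^-runif(1, 2, 40))
    }))
  }))
  status_at <- function(ev, margin) {
    p <- place_genes(hits, evalue_max = ev, ambiguity_margin = margin)
    split(p$gene, p$status)
  }
  # relaxing the e-value cutoff never loses a gene's hit support (it can,
  # however, turn a clean placement ambiguous by admitting a runner-up)
  for (pair in list(c(1e-30, 1e-10), c(1e-10, 1e-4))) {
    lo <- status_at(pair[1], 1.2); hi <- status_at(pair[2], 1.2)
    with_hits <- function(s) setdiff(unlist(s[c("PLACED", "UNPLACED_AMBIGUOUS")]),
                                     NULL)
    expect_true(all(with_hits(lo) %in% with_hits(hi)))
  }
  # at margin 1 every gene with hits is placed, so placement is monotone too
  expect_true(all(status_at(1e-30, 1)$PLACED %in% status_at(1e-10, 1)$PLACED))
  # tightening the ambiguity margin never places an extra gene
  for (pair in list(c(1.2, 1.05), c(2, 1.2))) {
    expect_true(all(status_at(1e-10, pair[1])$PLACED %in%
                      status_at(1e-10, pair[2])$PLACED))
  }
})

test_that("Y confirmation combines genes, AD-ratio and homolog exclusion", {
  placements <- place_genes(rbind(
    mk_hit("SRY", "Y_GENE", "SOX3", "scfY", 500, 1e-30),
    mk_hit("SOX3", "HOMOLOG", "SRY", "scfX", 450, 1e-30),
    mk_hit("UTY", "Y_GENE", "UTX", "scfHi", 400, 1e-30),
    mk_hit("UTX", "HOMOLOG", "UTY", "scfZ", 420, 1e-30),
    mk_hit("RBMY", "Y_GENE", "RBMX", "scfBoth", 300, 1e-30),
    mk_hit("RBMX", "HOMOLOG", "RBMY", "scfBoth", 280, 1e-30)
  ))
  ad <- ad_tbl(c("scfY", "scfX", "scfHi", "scfZ", "scfBoth"),
               rep(1e5, 5), c(0.005, 2.0, 1.0, 1.0, 0.005))
  yc <- confirm_y(placements, ad)
  conf <- yc$confirmations
  expect_true(conf$confirmed[conf$scaffold_id == "scfY"])
  expect_true(conf$high_confidence[conf$scaffold_id == "scfY"])
  expect_equal(conf$excluded_reason[conf$scaffold_id == "scfHi"],
               "AD_TOO_HIGH")
  expect_equal(conf$excluded_reason[conf$scaffold_id == "scfBoth"],
               "HOMOLOG_SAME_SCAFFOLD")
  expect_equal(yc$total_confirmed_bp, 1e5)

  expect_error(confirm_y(placements, ad[ad$scaffold_id != "scfY", ]),
               class = "sexscaff_input_error")
})

test_that("candidate Y scaffolds without markers are reported, not confirmed", {
  placements <- place_genes(mk_hit("SRY", "Y_GENE", "SOX3", "scfY", 500, 1e-30))
  ad <- ad_tbl(c("scfY", "scfOrphan"), c(1e5, 5e4), c(0.005, 0.02))
  yc <- confirm_y(placements, ad)
  orphan <- yc$confirmations[yc$confirmations$scaffold_id == "scfOrphan", ]
  expect_false(orphan$confirmed)
  expect_equal(orphan$excluded_reason, "NO_GENES")
})

test_that("gene track orders genes by scaffold coordinate", {
  hits <- rbind(
    mk_hit("A", "Y_GENE", "Ax", "scfY", 500, 1e-30, s_start = 10000, s_end = 11000),
    mk_hit("B", "Y_GENE", "Bx", "scfY", 400, 1e-30, s_start = 5000, s_end = 6000),
    mk_hit("C", "Y_GENE", "Cx", "scfY", 300, 1e-30, s_start = 20000, s_end = 21000)
  )
  placements <- place_genes(hits)
  gm <- gene_map_report(placements, hits)
  expect_equal(gm$track$start, c(5000, 10000, 20000))
  expect_equal(gm$counts$n_genes, 3L)
  # empty case
  none <- placements; none$status <- "UNPLACED_NO_HIT"
  gm0 <- gene_map_report(none, hits)
  expect_equal(nrow(gm0$track), 0L)
  expect_equal(sum(gm0$counts$n_genes), 0L)
})

test_that("synthetic default marker run places the unambiguous genes on Y scaffolds", {
  cfg <- sim_config(seed = 17)
  truth <- simulate_karyotype(cfg)
  d <- simulate_depths(truth, cfg)
  mk <- simulate_marker_hits(truth, cfg)
  k <- compute_normalization(d$male, d$female)
  ad <- compute_ad_ratios(d$male, d$female, k)
  placements <- place_genes(mk$hits, mk$manifest)
  yc <- confirm_y(placements, ad)
  gm <- gene_map_report(placements, mk$hits, yc$confirmations)
  n_unamb <- sum(!mk$gene_truth$ambiguous)
  expect_equal(sum(gm$counts$n_genes), n_unamb)
  expect_equal(sum(placements$status == "PLACED" &
                     placements$gene_class == "Y_GENE"), n_unamb)
  # placements recover the simulator's truth map exactly
  placed <- placements[placements$gene_class == "Y_GENE" &
                         placements$status == "PLACED", ]
  expect_equal(placed$scaffold_id,
               mk$gene_truth$true_scaffold[match(placed$gene,
                                                 mk$gene_truth$gene)])
})
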