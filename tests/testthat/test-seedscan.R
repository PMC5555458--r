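test_that("seed derivation takes positions 2-8 of the mature sequence", {
  expect_identical(derive_seed("UGAGGUAGUAGGUUGUAUAGUU"), "GAGGUAG")
  expect_identical(derive_seed("UAAAAAAA"), "AAAAAAA")
  expect_identical(derive_seed("tgaggtagtaggttgtatagtt"), "GAGGUAG")
  expect_error(derive_seed("UAAAAAA"), "at least 8")
  expect_error(derive_seed("UGAGGXAGUA"), "non-IUPAC")
})

test_that("site classes and coordinates follow the canonical definitions", {
  # let-7 seed: one 8mer spanning [3, 11) with its internal 7mers absorbed
  s <- find_seed_sites("AAACUACCUCAAA", "GAGGUAG")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 3L)
  expect_equal(s$end, 11L)
  expect_equal(s$site_type, "8mer")

  # 7mer-m8: seed complement without the trailing A
  s <- find_seed_sites("GGCUACCUCGGG", "GAGGUAG")
  expect_equal(s$site_type, "7mer-m8")
  expect_equal(s$end - s$start, 7L)

  # 7mer-A1: positions 2-7 complement followed by A, no position-8 match
  s <- find_seed_sites("GGUACCUCAGGG", "GAGGUAG")
  expect_equal(s$site_type, "7mer-A1")
  expect_equal(s$end - s$start, 7L)

  # no match at all
  expect_equal(nrow(find_seed_sites("GGGGGGG", "GAGGUAG")), 0L)
  # T and U representations give identical sites
  expect_equal(find_seed_sites("AAACTACCTCAAA", "GAGGUAG"),
               find_seed_sites("AAACUACCUCAAA", "GAGGUAG"))
  expect_error(find_seed_sites("ACGUN", "GAGGUAG"), "position 5")
})

test_that("matcher agrees with a brute-force window scan on random input", {
  set.seed(401)
  for (i in 1:300) {
    utr <- rand_rna(sample(7:200, 1))
    seed7 <- substr(rand_rna(8), 2, 8)
    got <- find_seed_sites(utr, seed7)
    want <- oracle_seed_sites(utr, seed7)
    expect_equal(got, want, info = paste("utr:", utr, "seed:", seed7))
  }
})

test_that("family tables require one seed per family", {
  fam <- data.frame(
    family = c("f1", "f1"), member = c("a", "b"),
    mature_sequence = c("UGAGGUAGUAGG", "AGAGGUAGAAAA"),
    stringsAsFactors = FALSE)
  seeds <- family_seeds(fam)
  expect_identical(unname(seeds["f1"]), "GAGGUAG")
  fam$mature_sequence[2] <- "ACCCCCCCAAAA"
  expect_error(family_seeds(fam), "share one seed")
})

test_that("gene summaries pair the two medians in the density formula", {
  s <- gene_summary("g1", 3, 600)
  expect_equal(s$density_per_kb, 5.0)
  # even isoform count: mean-of-middle-two median, possibly half-integer
  s <- gene_summary("g2", c(2, 4), c(500, 1500))
  expect_equal(s$median_sites, 3)
  expect_equal(s$median_length, 1000)
  expect_equal(s$density_per_kb, 3.0)
  expect_equal(gene_summary("g3", c(0, 0, 0), c(100, 200, 900))$density_per_kb, 0)
  expect_error(gene_summary("g4", c(1, 2), c(0, 10)), "positive")
})

test_that("density is invariant under duplicating a gene's isoform set", {
  counts <- c(1, 4, 2)
  lens <- c(120, 300, 200)
  once <- gene_summary("g", counts, lens)
  twice <- gene_summary("g", rep(counts, 2), rep(lens, 2))
  expect_equal(once$density_per_kb, twice$density_per_kb)
  expect_equal(once$median_sites, twice$median_sites)
})

test_that("density comparison filters by expression and detects planting", {
  summaries <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    median_sites = c(4, 4, 1, 1), median_length = c(400, 400, 400, 400),
    density_per_kb = c(10, 10, 2.5, 2.5), stringsAsFactors = FALSE)
  cmp <- density_comparison(c("a", "b"), c("a", "b", "c", "d"), summaries,
                            expressed_genes = summaries$gene_id)
  expect_equal(cmp$fold_change, 10 / 6.25)
  # identical sets give fold change 1
  same <- density_comparison(c("a", "c"), c("a", "c"), summaries,
                             summaries$gene_id)
  expect_equal(same$fold_change, 1)
  # expression filter that removes every target is an error
  expect_error(
    density_comparison(c("a", "b"), summaries$gene_id, summaries,
                       expressed_genes = c("c", "d")),
    "no target genes")
})
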