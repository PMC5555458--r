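test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(n_genes = 10, n_bound = 11), "n_bound")
  expect_error(sim_config(nb_dispersion = -0.1), "nonnegative")
  expect_error(sim_config(library_sizes = c(IP = 0, CTRL = 1, TOTAL = 1)),
               "positive")
  expect_error(sim_config(utr_length = list(mean = 10, sd = 1, min = 4)),
               "min >= 8")
  expect_error(sim_config(n_interacting = 9, n_families = 8),
               "n_interacting")
})

test_that("annotation planting is exact: forced counts rediscovered on scan", {
  cfg <- sim_config(n_genes = 1, n_bound = 1, isoforms_per_gene = c(1, 1),
                    utr_length = list(mean = 50, sd = 0, min = 50),
                    n_families = 1, n_interacting = 1,
                    planted_sites_bound = 2, planted_sites_unbound = 0,
                    sites_exact = TRUE, rng_seed = 5)
  ann <- simulate_annotation(cfg)
  expect_length(ann$utrs, 1L)
  expect_equal(nchar(ann$utrs[[1]]), 50L)
  seed7 <- family_seeds(ann$families)[[1]]
  det <- find_seed_sites(ann$utrs[[1]], seed7)
  expect_equal(nrow(det), 2L)
  expect_equal(nrow(ann$truth$planted_sites), 2L)
  expect_equal(det$start, sort(ann$truth$planted_sites$start))
})

test_that("a seed whose site needs an excluded base cannot match", {
  # alphabet without G: the site pattern of a C-rich seed needs G, so
  # with no planting the scan must come up empty
  cfg <- sim_config(n_genes = 3, n_bound = 0, isoforms_per_gene = c(1, 1),
                    utr_length = list(mean = 80, sd = 0, min = 80),
                    n_families = 1, n_interacting = 1, ip_effect = 1,
                    planted_sites_bound = 0, planted_sites_unbound = 0,
                    sites_exact = TRUE, alphabet = c("A", "C", "T"),
                    rng_seed = 6)
  ann <- simulate_annotation(cfg)
  seed7 <- "CCCCCCC"  # its 7mer site GGGGGGG cannot occur without G
  for (u in ann$utrs)
    expect_equal(nrow(find_seed_sites(u, seed7)), 0L)
})

test_that("annotation and counts are deterministic given config + seed", {
  cfg <- sim_config(n_genes = 25, n_bound = 5, rng_seed = 12,
                    utr_length = list(mean = 100, sd = 20, min = 50))
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- simulate_counts(cfg, a1$truth)
  c2 <- simulate_counts(cfg, a2$truth)
  expect_identical(c1, c2)
  # FASTA round-trip is byte-exact
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(a1$utrs, p1)
  write_utr_fasta(a2$utrs, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(read_utr_fasta(p1), a1$utrs)
})

test_that("sites that cannot fit the minimum UTR length raise an error", {
  cfg <- sim_config(n_genes = 1, n_bound = 1, isoforms_per_gene = c(1, 1),
                    utr_length = list(mean = 16, sd = 0, min = 16),
                    n_families = 1, n_interacting = 1,
                    planted_sites_bound = 3, planted_sites_unbound = 0,
                    sites_exact = TRUE, rng_seed = 5)
  expect_error(simulate_annotation(cfg), "gene0001")
})

test_that("count matrix matches the design and its configured moments", {
  cfg <- sim_config(n_genes = 400, n_bound = 40, ip_effect = 4,
                    nb_dispersion = 0.05, rng_seed = 18)
  truth <- minimal_truth(400, sprintf("g%05d", 1:40), 4)
  cm <- simulate_counts(cfg, truth)
  info <- sample_info(cm)
  expect_equal(unname(table(info$class)[c("IP", "CTRL", "TOTAL")]),
               c(3L, 2L, 2L), ignore_attr = TRUE)
  expect_true(all(cm >= 0))
  # column sums within 3 SD of their expected totals (bound mass included)
  baseline_mass <- 1  # baselines are normalised proportions
  for (j in seq_len(ncol(cm))) {
    cls <- info$class[j]
    lib <- cfg$library_sizes[[cls]]
    # expected column total: lib * sum(baseline * effect); recover the
    # realized effect mass from the truth object
    eff <- if (cls == "IP") truth$true_ip_effect[truth$isoforms] else
      rep(1, 400)
    # bound with the crude upper bound mu <= lib * max effect:
    exp_tot_lo <- lib * baseline_mass
    exp_tot_hi <- lib * baseline_mass * max(eff)
    sd_hi <- sqrt(exp_tot_hi + cfg$nb_dispersion * exp_tot_hi^2 / 400)
    expect_gt(sum(cm[, j]), exp_tot_lo - 3 * sd_hi)
    expect_lt(sum(cm[, j]), exp_tot_hi + 3 * sd_hi)
  }
})

test_that("with no effect, IP and CTRL log fold changes centre on zero", {
  cfg <- sim_config(n_genes = 1000, n_bound = 0, ip_effect = 1,
                    nb_dispersion = 0, rng_seed = 23)
  cm <- simulate_counts(cfg, minimal_truth(1000))
  info <- sample_info(cm)
  adj <- adjusted_counts(cm)
  ip <- rowMeans(adj[, info$class == "IP"])
  ct <- rowMeans(adj[, info$class == "CTRL"])
  keep <- ip > 0 & ct > 0
  expect_lt(abs(mean(log2(ip[keep] / ct[keep]))), 0.1)
})

test_that("phenotype tables are binomial draws with the given penetrance", {
  g <- data.frame(label = c("a", "b", "c"), n = c(50L, 100L, 10000L),
                  arrest_prob = c(0, 1, 0.5), stringsAsFactors = FALSE)
  tab <- simulate_phenotypes(g, rng_seed = 2)
  expect_equal(tab$n_arrested[1], 0L)
  expect_equal(tab$n_arrested[2], 100L)
  expect_lt(abs(tab$n_arrested[3] / 10000 - 0.5), 0.02)
  expect_identical(tab, simulate_phenotypes(g, rng_seed = 2))
  g$arrest_prob[1] <- 1.2
  expect_error(simulate_phenotypes(g), "\\[0, 1\\]")
})
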