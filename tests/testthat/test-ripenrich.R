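make_counts <- function(m, classes) {
  colnames(m) <- classes
  rownames(m) <- sprintf("t%03d", seq_len(nrow(m)))
  storage.mode(m) <- "integer"
  m
}

test_that("adjusted counts are within-library proportions", {
  m <- make_counts(matrix(c(5, 95, 10, 190), ncol = 2),
                   c("IP:1", "CTRL:1"))
  adj <- adjusted_counts(m)
  expect_equal(adj["t001", "IP:1"], 0.05)
  expect_equal(unname(colSums(adj)), c(1, 1))
  # zero raw count stays zero; one-transcript library normalises to 1
  m2 <- make_counts(matrix(c(0, 100, 7, 0), ncol = 2),
                    c("IP:1", "CTRL:1"))
  adj2 <- adjusted_counts(m2)
  expect_equal(adj2["t001", "IP:1"], 0)
  expect_equal(adj2["t001", "CTRL:1"], 1)
  # scale invariance: multiplying a library by k changes nothing
  m3 <- m; m3[, 1] <- m3[, 1] * 7L
  expect_equal(adjusted_counts(m3), adjusted_counts(m))
  # zero-total library is rejected by name
  m4 <- make_counts(matrix(c(1, 1, 0, 0), ncol = 2), c("IP:1", "CTRL:1"))
  expect_error(adjusted_counts(m4), "CTRL:1")
})

test_that("the IP enrichment score reproduces hand-computed values", {
  expect_equal(ip_enrichment_score(0.02, 0.005, 0.01), 1.5)
  expect_equal(ip_enrichment_score(0.0, 0.004, 0.002), -2.0)
  expect_equal(ip_enrichment_score(0.03, 0.03, 0.5), 0)
  # antisymmetry under swapping IP and CTRL
  set.seed(17)
  ip <- runif(50); ct <- runif(50); tot <- runif(50) + 0.01
  expect_equal(ip_enrichment_score(ip, ct, tot),
               -ip_enrichment_score(ct, ip, tot))
  # zero total: 0/0 -> 0, nonzero numerator -> NA with a message
  expect_equal(ip_enrichment_score(0, 0, 0), 0)
  expect_message(s <- ip_enrichment_score(0.1, 0, 0), "undefined")
  expect_true(is.na(s))
})

test_that("BH adjustment matches the step-up procedure on known cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical IP and CTRL columns give null results everywhere", {
  set.seed(31)
  base <- matrix(rpois(200 * 2, 60), ncol = 2)
  m <- make_counts(cbind(base, base), c("IP:1", "IP:2", "CTRL:1", "CTRL:2"))
  de <- nb_differential(m)
  expect_equal(de$log2_fold_enrichment, rep(0, 200))
  expect_equal(de$p_value, rep(1, 200))
})

test_that("all-zero transcripts are flagged with p = 1 and lfc = 0", {
  set.seed(32)
  m <- make_counts(matrix(rpois(50 * 4, 40), ncol = 4),
                   c("IP:1", "IP:2", "CTRL:1", "CTRL:2"))
  m[7, ] <- 0L
  de <- nb_differential(m)
  expect_true(de$flagged[7])
  expect_equal(de$p_value[7], 1)
  expect_equal(de$log2_fold_enrichment[7], 0)
})

test_that("target calling thresholds on q and direction, collapsing genes", {
  res <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    log2_fold_enrichment = c(1, 3, -2),
    q_value = c(0.05, 0.2, 0.01), stringsAsFactors = FALSE)
  expect_equal(call_targets(res, q_threshold = 0.1), "t1")  # t3 is depleted
  res$q_value <- rep(1, 3)
  expect_equal(call_targets(res), character(0))
  # gene-level any-isoform rule
  res2 <- data.frame(
    transcript_id = c("g1.1", "g1.2", "g2.1"),
    log2_fold_enrichment = c(2, 0.1, 1),
    q_value = c(0.01, 0.9, 0.5), stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = c("g1", "g1", "g2"),
                   isoform_id = c("g1.1", "g1.2", "g2.1"),
                   stringsAsFactors = FALSE)
  expect_equal(call_targets(res2, gm, 0.1), "g1")
  expect_warning(out <- call_targets(res2[0, ]), "empty")
  expect_equal(out, character(0))
})

test_that("the called set shrinks as the q threshold tightens", {
  set.seed(33)
  res <- data.frame(
    transcript_id = sprintf("t%03d", 1:300),
    log2_fold_enrichment = rnorm(300, 0.5),
    q_value = runif(300), stringsAsFactors = FALSE)
  prev <- NULL
  for (thr in c(0.2, 0.1, 0.05, 0.01)) {
    cur <- call_targets(res, q_threshold = thr)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("fold-change summaries behave on constant input and full sets", {
  res <- data.frame(transcript_id = c("a", "b", "c"),
                    log2_fold_enrichment = c(0, 0, 0),
                    stringsAsFactors = FALSE)
  fc <- fold_change_summary(res, c("a", "b"))
  expect_equal(unlist(fc), c(median_fc_targets = 1, mean_fc_targets = 1,
                             median_fc_all = 1, mean_fc_all = 1))
  res$log2_fold_enrichment <- c(1, 2, 3)
  all_t <- fold_change_summary(res, res$transcript_id)
  expect_equal(all_t$median_fc_targets, all_t$median_fc_all)
  expect_equal(all_t$mean_fc_targets, all_t$mean_fc_all)
  none <- fold_change_summary(res, character(0))
  expect_true(is.na(none$median_fc_targets))
  expect_false(is.na(none$median_fc_all))
})

test_that("the rip_enrichment fit object carries results and methods", {
  cfg <- sim_config(n_genes = 60, n_bound = 10, rng_seed = 7,
                    utr_length = list(mean = 120, sd = 20, min = 60))
  ann <- simulate_annotation(cfg)
  cm <- simulate_counts(cfg, ann$truth)
  fit <- rip_enrichment(cm, ann$gene_map)
  expect_s3_class(fit, "rip_enrichment")
  r <- as.data.frame(fit)
  expect_true(all(c("transcript_id", "gene_id", "adj_IP", "adj_CTRL",
                    "adj_TOTAL", "enrichment_score",
                    "log2_fold_enrichment", "p_value", "q_value",
                    "is_target") %in% names(r)))
  expect_true(all(r$is_target == (r$q_value < 0.1 &
                                    r$log2_fold_enrichment > 0)))
  expect_output(print(fit), "RIP-Seq enrichment")
  expect_output(print(summary(fit)), "fold enrichment")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("counts TSV round-trips bit-exactly", {
  cfg <- sim_config(n_genes = 15, n_bound = 3, rng_seed = 9)
  cm <- simulate_counts(cfg, minimal_truth(15, sprintf("g%05d", 1:3), 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cm, path)
  expect_identical(read_counts_tsv(path), cm)
})
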