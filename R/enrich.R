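#' Library-proportion adjusted counts
#'
#' The adjusted count of a transcript in a library is its raw mapped reads
#' divided by the library's total reads, so every column of the result sums
#' to one. This removes sequencing-depth differences before the IP
#' enrichment score is formed.
#'
#' @param counts RIP-Seq count matrix (see [validate_counts()]).
#' @return Matrix of within-library proportions, same dimnames as `counts`.
#' @export
adjusted_counts <- function(counts) {
  validate_counts(counts)
  sweep(counts, 2L, colSums(counts), "/")
}

#' IP enrichment score from class-averaged adjusted counts
#'
#' Computes `(adj_ip - adj_ctrl) / adj_total` per transcript: how much of a
#' transcript's IP signal exceeds the tag-only control, expressed relative
#' to its abundance in pre-IP total RNA. Replicates within a class are
#' expected to have been averaged already (see [rip_enrichment()]).
#'
#' Where the total-RNA proportion is zero the score is undefined: `NA` is
#' returned when the numerator is nonzero (and a count of such cases is
#' reported via a message), and 0 when the numerator is also zero.
#'
#' @param adj_ip,adj_ctrl,adj_total Numeric vectors of class-averaged
#'   adjusted counts (equal length).
#' @return Numeric vector of scores; positive = enriched in the IP,
#'   negative = depleted.
#' @examples
#' ip_enrichment_score(0.02, 0.005, 0.01)  # 1.5
#' @export
ip_enrichment_score <- function(adj_ip, adj_ctrl, adj_total) {
  n <- length(adj_ip)
  if (length(adj_ctrl) != n || length(adj_total) != n)
    stop("adj_ip, adj_ctrl, adj_total must have equal length")
  if (any(c(adj_ip, adj_ctrl, adj_total) < 0, na.rm = TRUE))
    stop("adjusted counts must be nonnegative")
  num <- adj_ip - adj_ctrl
  out <- num / adj_total
  zero_tot <- adj_total == 0
  out[zero_tot & num == 0] <- 0
  undef <- zero_tot & num != 0
  if (any(undef, na.rm = TRUE)) {
    out[undef] <- NA_real_
    message(sum(undef, na.rm = TRUE),
            " transcript(s) with zero total-RNA signal: enrichment score",
            " undefined (NA)")
  }
  out
}

# DESeq-style median-of-ratios size factors; falls back to total-count
# scaling when no transcript is observed in every library.
size_factors <- function(counts) {
  logs <- log(counts)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (sum(use) >= 10L) {
    sf <- apply(logs[use, , drop = FALSE], 2L, function(lc)
      exp(stats::median(lc - loggeo[use])))
  } else {
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  sf
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

#' Negative-binomial Wald test of IP versus control enrichment
#'
#' A self-contained moderated NB test for small-replicate RIP-Seq designs.
#' Counts are scaled by median-of-ratios size factors; a per-transcript
#' method-of-moments dispersion (NB variance = mu + alpha * mu^2) is shrunk
#' 50/50 toward a fitted mean-dispersion trend `a0 + a1 / mu`; the log
#' ratio of group means is tested with a Wald statistic whose variance
#' comes from the NB model with the moderated dispersion, referred to
#' the standard normal (the usual Wald reference; the trend shrinkage is
#' what keeps small-replicate designs calibrated).
#'
#' @param counts RIP-Seq count matrix; needs at least one IP and one CTRL
#'   column. With fewer than two replicates in either class, dispersion is
#'   pooled across both classes (which absorbs true signal into the
#'   dispersion) and the affected transcripts are flagged.
#' @return Data frame with columns `transcript_id`, `base_mean`,
#'   `log2_fold_enrichment`, `p_value`, `dispersion`, `flagged`
#'   (all-zero transcripts get `log2_fold_enrichment = 0`, `p_value = 1`,
#'   `flagged = TRUE`).
#' @export
nb_differential <- function(counts) {
  validate_counts(counts)
  info <- sample_info(counts)
  ip_cols <- info$sample[info$class == "IP"]
  ct_cols <- info$sample[info$class == "CTRL"]
  if (length(ip_cols) < 1L || length(ct_cols) < 1L)
    stop("need at least one IP and one CTRL sample for the differential test")
  m <- counts[, c(ip_cols, ct_cols), drop = FALSE]
  pooled <- length(ip_cols) < 2L || length(ct_cols) < 2L
  if (pooled)
    warning("fewer than two replicates in a class: dispersion pooled across",
            " IP and CTRL; results flagged")

  sf <- size_factors(m)
  norm <- sweep(m, 2L, sf, "/")
  ip <- norm[, ip_cols, drop = FALSE]
  ct <- norm[, ct_cols, drop = FALSE]
  nI <- length(ip_cols); nC <- length(ct_cols)
  mu_ip <- rowMeans(ip)
  mu_ct <- rowMeans(ct)
  base_mean <- rowMeans(norm)
  allzero <- rowSums(m) == 0

  # method-of-moments dispersion on the normalized scale:
  # Var(count/sf) = mu/sf + alpha * mu^2, pooled within groups
  inv_sf_ip <- mean(1 / sf[ip_cols])
  inv_sf_ct <- mean(1 / sf[ct_cols])
  if (!pooled) {
    v_ip <- .row_vars(ip); v_ct <- .row_vars(ct)
    wvar <- ((nI - 1L) * v_ip + (nC - 1L) * v_ct) / (nI + nC - 2L)
    shot <- ((nI - 1L) * mu_ip * inv_sf_ip +
             (nC - 1L) * mu_ct * inv_sf_ct) / (nI + nC - 2L)
    gmu <- (nI * mu_ip + nC * mu_ct) / (nI + nC)
  } else {
    wvar <- .row_vars(norm)
    shot <- base_mean * mean(1 / sf)
    gmu <- base_mean
  }
  disp_raw <- pmax((wvar - shot) / gmu^2, 0)
  disp_raw[!is.finite(disp_raw)] <- 0

  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted on informative rows
  use <- is.finite(disp_raw) & gmu > 1 & !allzero
  if (sum(use) >= 20L) {
    fit <- stats::lm(disp_raw[use] ~ I(1 / gmu[use]))
    a0 <- max(stats::coef(fit)[1L], 1e-4)
    a1 <- max(stats::coef(fit)[2L], 0)
  } else {
    a0 <- max(mean(disp_raw[use], na.rm = TRUE), 1e-4)
    a1 <- 0
  }
  disp_trend <- a0 + a1 / pmax(gmu, 1e-8)
  disp <- pmax(0.5 * disp_raw + 0.5 * disp_trend, 1e-8)

  pc <- 0.5  # pseudocount stabilises log ratios of low-count transcripts
  q_ip <- mu_ip + pc
  q_ct <- mu_ct + pc
  lfc <- log2(q_ip / q_ct)
  # Var(mean of normalized counts) per group under the NB model
  v_ip <- (q_ip * inv_sf_ip + disp * q_ip^2) / nI
  v_ct <- (q_ct * inv_sf_ct + disp * q_ct^2) / nC
  se_log <- sqrt(v_ip / q_ip^2 + v_ct / q_ct^2)
  wald <- (log(q_ip) - log(q_ct)) / se_log
  p <- 2 * stats::pnorm(-abs(wald))

  lfc[allzero] <- 0
  p[allzero] <- 1
  data.frame(transcript_id = rownames(counts),
             base_mean = base_mean,
             log2_fold_enrichment = lfc,
             p_value = pmin(p, 1),
             dispersion = disp,
             flagged = allzero | pooled,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH step-up adjusted values (q-values).
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call bound targets from differential-enrichment results
#'
#' A transcript is called when `q_value < q_threshold` and its fold
#' enrichment is positive ("enriched" targets only). When a gene map is
#' supplied, calls are collapsed to gene level: a gene is a target if any
#' of its transcripts is called.
#'
#' @param results Data frame with columns `transcript_id`,
#'   `log2_fold_enrichment`, `q_value`.
#' @param gene_map Optional data frame with `gene_id`, `isoform_id`
#'   (isoform IDs matching `transcript_id`).
#' @param q_threshold FDR threshold (default 0.1).
#' @return Character vector of target gene IDs (or transcript IDs when no
#'   map is given).
#' @export
call_targets <- function(results, gene_map = NULL, q_threshold = 0.1) {
  if (nrow(results) == 0L) {
    warning("empty results: no targets to call")
    return(character(0))
  }
  stopifnot(q_threshold > 0, q_threshold < 1)
  hit <- results$q_value < q_threshold & results$log2_fold_enrichment > 0
  hit[is.na(hit)] <- FALSE
  tx <- results$transcript_id[hit]
  if (is.null(gene_map)) return(unique(tx))
  sort(unique(gene_map$gene_id[gene_map$isoform_id %in% tx]))
}

#' Fold-change summaries for targets versus all transcripts
#'
#' Summaries are computed on the fold-enrichment (ratio IP/CTRL) scale,
#' i.e. `2^log2_fold_enrichment`; transcripts with missing fold changes are
#' excluded.
#'
#' @param results Data frame with `transcript_id` and
#'   `log2_fold_enrichment`.
#' @param target_transcripts Character vector of target transcript IDs.
#' @return List with `median_fc_targets`, `mean_fc_targets`,
#'   `median_fc_all`, `mean_fc_all` (target entries are `NA` when the
#'   target set is empty).
#' @export
fold_change_summary <- function(results, target_transcripts) {
  if (nrow(results) == 0L) stop("empty results")
  fc <- 2^results$log2_fold_enrichment
  ok <- is.finite(fc)
  fc_all <- fc[ok]
  in_t <- ok & results$transcript_id %in% target_transcripts
  fc_t <- fc[in_t]
  list(
    median_fc_targets = if (length(fc_t)) stats::median(fc_t) else NA_real_,
    mean_fc_targets = if (length(fc_t)) mean(fc_t) else NA_real_,
    median_fc_all = stats::median(fc_all),
    mean_fc_all = mean(fc_all))
}
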