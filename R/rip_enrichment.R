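#' Fit a RIP-Seq enrichment analysis
#'
#' The front door of the package: takes a transcript count matrix from a
#' RIP-Seq design (tagged-protein IP, tag-only control IP, pre-IP total
#' RNA) and produces, per transcript, library-proportion adjusted counts,
#' the IP enrichment score `(adj_IP - adj_CTRL) / adj_TOTAL` on
#' replicate-averaged adjusted counts, a moderated negative-binomial Wald
#' test of IP versus CTRL, Benjamini-Hochberg q-values, and bound/unbound
#' target calls at `q < q_threshold` with positive fold enrichment.
#'
#' @param counts Count matrix with columns named `"CLASS:replicate"`,
#'   `CLASS` in `IP`/`CTRL`/`TOTAL`; at least one IP and one CTRL column
#'   (two each for per-class dispersion estimation), and at least one
#'   TOTAL column if enrichment scores are wanted.
#' @param gene_map Optional data frame (`gene_id`, `isoform_id`) used to
#'   collapse transcript calls to gene-level targets (any-isoform rule).
#' @param q_threshold FDR threshold for target calling (default 0.1).
#' @param score_filter If `TRUE`, additionally require
#'   `enrichment_score > score_threshold` for a transcript to be called
#'   (off by default).
#' @param score_threshold Cutoff used when `score_filter = TRUE`.
#' @return An object of class `"rip_enrichment"`: a list with `results`
#'   (per-transcript data frame), `targets` (gene-level target IDs, or
#'   transcript IDs without a map), `target_transcripts`, `fold_change`
#'   (summaries from [fold_change_summary()]), `q_threshold`, `design`
#'   (sample info) and `gene_map`.
#' @seealso [nb_differential()], [ip_enrichment_score()], [call_targets()]
#' @examples
#' cfg <- sim_config(n_genes = 60, n_bound = 10, rng_seed = 7)
#' ann <- simulate_annotation(cfg)
#' cm <- simulate_counts(cfg, ann$truth)
#' fit <- rip_enrichment(cm, ann$gene_map)
#' fit
#' head(as.data.frame(fit))
#' @export
rip_enrichment <- function(counts, gene_map = NULL, q_threshold = 0.1,
                           score_filter = FALSE, score_threshold = 0) {
  validate_counts(counts)
  info <- sample_info(counts)
  adj <- adjusted_counts(counts)
  class_mean <- function(cls) {
    cols <- info$sample[info$class == cls]
    if (length(cols) == 0L) return(rep(NA_real_, nrow(adj)))
    rowMeans(adj[, cols, drop = FALSE])
  }
  adj_ip <- class_mean("IP")
  adj_ct <- class_mean("CTRL")
  adj_to <- class_mean("TOTAL")
  score <- if (all(is.na(adj_to))) rep(NA_real_, nrow(adj)) else
    ip_enrichment_score(adj_ip, adj_ct, adj_to)

  de <- nb_differential(counts)
  q <- bh_adjust(de$p_value)

  results <- data.frame(
    transcript_id = rownames(counts),
    gene_id = if (is.null(gene_map)) rownames(counts) else
      gene_map$gene_id[match(rownames(counts), gene_map$isoform_id)],
    adj_IP = adj_ip, adj_CTRL = adj_ct, adj_TOTAL = adj_to,
    enrichment_score = score,
    log2_fold_enrichment = de$log2_fold_enrichment,
    p_value = de$p_value, q_value = q,
    stringsAsFactors = FALSE)
  is_target <- results$q_value < q_threshold &
    results$log2_fold_enrichment > 0
  if (score_filter)
    is_target <- is_target & !is.na(results$enrichment_score) &
      results$enrichment_score > score_threshold
  is_target[is.na(is_target)] <- FALSE
  results$is_target <- is_target

  target_tx <- results$transcript_id[is_target]
  targets <- if (is.null(gene_map)) target_tx else
    sort(unique(gene_map$gene_id[gene_map$isoform_id %in% target_tx]))

  structure(list(
    results = results,
    targets = targets,
    target_transcripts = target_tx,
    fold_change = fold_change_summary(results, target_tx),
    q_threshold = q_threshold,
    score_filter = score_filter,
    design = info,
    gene_map = gene_map,
    call = match.call()), class = "rip_enrichment")
}

#' @export
print.rip_enrichment <- function(x, ...) {
  n_cls <- table(factor(x$design$class, levels = c("IP", "CTRL", "TOTAL")))
  cat("RIP-Seq enrichment analysis\n")
  cat(sprintf("  %d transcripts; design: %d IP / %d CTRL / %d TOTAL\n",
              nrow(x$results), n_cls[["IP"]], n_cls[["CTRL"]],
              n_cls[["TOTAL"]]))
  cat(sprintf("  targets at q < %g (log2FC > 0): %d transcripts, %d genes\n",
              x$q_threshold, length(x$target_transcripts),
              length(x$targets)))
  invisible(x)
}

#' @export
summary.rip_enrichment <- function(object, ...) {
  fc <- object$fold_change
  out <- list(
    n_transcripts = nrow(object$results),
    n_target_transcripts = length(object$target_transcripts),
    n_target_genes = length(object$targets),
    q_threshold = object$q_threshold,
    fold_change = fc)
  class(out) <- "summary.rip_enrichment"
  out
}

#' @export
print.summary.rip_enrichment <- function(x, ...) {
  cat("RIP-Seq enrichment summary\n")
  cat(sprintf("  %d transcripts, %d called (q < %g), %d target genes\n",
              x$n_transcripts, x$n_target_transcripts, x$q_threshold,
              x$n_target_genes))
  fc <- x$fold_change
  cat(sprintf("  fold enrichment (IP/CTRL)  targets: median %.2f mean %.2f\n",
              fc$median_fc_targets, fc$mean_fc_targets))
  cat(sprintf("                             all:     median %.2f mean %.2f\n",
              fc$median_fc_all, fc$mean_fc_all))
  invisible(x)
}

#' MA-style plot of a RIP-Seq enrichment fit
#'
#' Mean normalized abundance (log10) against log2 fold enrichment, with
#' called targets highlighted.
#'
#' @param x A `rip_enrichment` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rip_enrichment <- function(x, ...) {
  r <- x$results
  base <- (r$adj_IP + r$adj_CTRL) / 2
  graphics::plot(log10(base + 1e-9), r$log2_fold_enrichment,
                 pch = 20, cex = 0.5,
                 col = ifelse(r$is_target, "firebrick", "grey50"),
                 xlab = "log10 mean adjusted count",
                 ylab = "log2 fold enrichment (IP/CTRL)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.rip_enrichment <- function(x, ...) x$results
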