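# Independent oracles used to validate package computations. These are
# deliberately naive re-derivations (window-by-window scans, exhaustive
# enumeration of draws/tables) kept separate from the implementation path.

# Reverse complement in RNA space, written from scratch.
oracle_revcomp <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  map <- c(A = "U", C = "G", G = "C", U = "A")
  paste(map[ch], collapse = "")
}

# Brute-force seed-site scan: build the three explicit site patterns and
# test every 7- and 8-nt window of the UTR against them. A 7mer window is
# suppressed when it is part of an 8mer site (the 8mer claims the window).
oracle_seed_sites <- function(utr, seed7) {
  seq <- chartr("T", "U", toupper(utr))
  pat8 <- paste0(oracle_revcomp(seed7), "A")
  pat7m8 <- oracle_revcomp(seed7)
  pat7a1 <- paste0(oracle_revcomp(substr(seed7, 1, 6)), "A")
  L <- nchar(seq)
  win <- function(p, w) if (L < w) character(0) else
    substring(seq, p, p + w - 1)
  out <- list()
  if (L >= 8) {
    for (p in 1:(L - 7)) {
      if (win(p, 8) == pat8)
        out[[length(out) + 1]] <- data.frame(
          start = p - 1L, end = p + 7L, site_type = "8mer",
          stringsAsFactors = FALSE)
    }
  }
  if (L >= 7) {
    for (p in 1:(L - 6)) {
      w <- win(p, 7)
      if (w == pat7m8) {
        # not a standalone site when the next base extends it to an 8mer
        extends <- p + 7 <= L && substring(seq, p + 7, p + 7) == "A"
        if (!extends)
          out[[length(out) + 1]] <- data.frame(
            start = p - 1L, end = p + 6L, site_type = "7mer-m8",
            stringsAsFactors = FALSE)
      }
      if (w == pat7a1) {
        # not a standalone site when the preceding base completes the 8mer
        extends <- p > 1 &&
          substring(seq, p - 1, p + 6) == pat8
        if (!extends)
          out[[length(out) + 1]] <- data.frame(
            start = p - 1L, end = p + 6L, site_type = "7mer-A1",
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive hypergeometric upper tail: enumerate every size-b subset of
# 1..N, fix set A = 1..a, and count draws with overlap >= k.
oracle_hyper_upper <- function(N, a, b, k) {
  draws <- utils::combn(N, b)
  overlap <- colSums(draws <= a)
  mean(overlap >= k)
}

# Exhaustive two-sided Fisher p: enumerate all tables with the observed
# margins, weight by the (multivariate) hypergeometric probability, and
# sum tables no more likely than the observed one.
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(a_range, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  p_obs <- prob[a_range == a_obs]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")

# A minimal ground-truth object for count simulation when no annotation
# is needed (one isoform per gene).
minimal_truth <- function(n_genes, bound = character(0), ip_effect = 1) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  iso <- paste0(genes, ".1")
  eff <- stats::setNames(ifelse(genes %in% bound, ip_effect, 1), genes)
  list(isoforms = stats::setNames(genes, iso),
       true_ip_effect = eff, bound_genes = bound)
}
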