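#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least `k` shared genes between a
#' set of size `a` and a set of size `b` drawn from a universe of `N`
#' genes, plus the expected overlap and fold enrichment — the standard
#' over-representation test for comparing a target list against predicted
#' miRNA-target sets.
#'
#' @param N Universe size.
#' @param a,b Sizes of the two gene sets.
#' @param k Observed overlap.
#' @return Object of class `"overlap_test"`: list with `N`, `a`, `b`, `k`,
#'   `expected`, `fold_enrichment` and `p_value` (= P\[X >= k\]).
#' @examples
#' hypergeometric_overlap(10, 5, 5, 5) # p = 1/252
#' @export
hypergeometric_overlap <- function(N, a, b, k) {
  if (any(c(N, a, b, k) < 0) || a > N || b > N)
    stop("need 0 <= a, b <= N and k >= 0")
  if (k > min(a, b))
    stop("overlap k cannot exceed min(a, b)")
  if (k < a + b - N)
    stop("overlap k below the minimum forced by the set sizes")
  p <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  expected <- a * b / N
  structure(list(N = N, a = a, b = b, k = k, expected = expected,
                 fold_enrichment = if (expected > 0) k / expected else
                   NA_real_,
                 p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Gene-set overlap: %d / expected %.2f (N=%d, |A|=%d, |B|=%d)\n",
    x$k, x$expected, x$N, x$a, x$b))
  cat(sprintf("  fold enrichment %.2f, hypergeometric P[X >= k] = %.4g\n",
              x$fold_enrichment, x$p_value))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood convention: the sum of
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2)) # 1/3
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop("table must be a 2x2 matrix")
  if (any(table < 0) || any(table != round(table)))
    stop("table cells must be nonnegative integers")
  if (sum(table) == 0) stop("empty table: all margins are zero")
  stats::fisher.test(table)$p.value
}

#' Standard error of a proportion
#'
#' `sqrt(p(1-p)/n)` with `p = k/n` — the error bar used for scored
#' phenotype penetrances.
#'
#' @param k Number of events (e.g. arrested animals).
#' @param n Number scored.
#' @return The standard error.
#' @export
proportion_se <- function(k, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0 | k > n)) stop("k must be between 0 and n")
  p <- k / n
  sqrt(p * (1 - p) / n)
}

#' Genetic enhancer-screen statistics on a phenotype table
#'
#' For each non-reference genotype: arrest proportion, its standard error,
#' and a two-sided Fisher exact p-value against every reference genotype.
#' A genotype is flagged as an enhancer when its p-value beats `alpha`
#' against all references and its arrest proportion exceeds every
#' reference's — the pattern of a synthetic-lethal interaction worsening a
#' sensitised background.
#'
#' @param phenotypes Data frame with columns `genotype`, `n_scored`,
#'   `n_arrested`.
#' @param reference_labels Character vector of reference genotypes (e.g.
#'   wild type and the single mutant), all present in the table.
#' @param alpha Significance threshold (default 0.001).
#' @param bh If `TRUE`, apply Benjamini-Hochberg correction to each
#'   reference's p-values across genotypes before flagging (off by
#'   default: screens conventionally report raw Fisher significance at a
#'   fixed alpha).
#' @return Data frame with one row per non-reference genotype:
#'   `genotype`, `n_scored`, `n_arrested`, `proportion`, `se`, one
#'   `p_vs_<reference>` column per reference, and `enhancer`.
#' @export
enhancer_screen <- function(phenotypes, reference_labels, alpha = 0.001,
                            bh = FALSE) {
  need <- c("genotype", "n_scored", "n_arrested")
  if (!all(need %in% names(phenotypes)))
    stop("phenotypes needs columns: ", paste(need, collapse = ", "))
  if (any(phenotypes$n_arrested < 0 |
          phenotypes$n_arrested > phenotypes$n_scored))
    stop("n_arrested must be between 0 and n_scored")
  miss <- setdiff(reference_labels, phenotypes$genotype)
  if (length(miss) > 0L)
    stop("reference genotype(s) not in table: ", paste(miss, collapse = ", "))
  refs <- phenotypes[match(reference_labels, phenotypes$genotype), ]
  cand <- phenotypes[!(phenotypes$genotype %in% reference_labels), ,
                     drop = FALSE]
  if (nrow(cand) == 0L) stop("no non-reference genotypes to test")

  pmat <- sapply(seq_len(nrow(refs)), function(r) {
    vapply(seq_len(nrow(cand)), function(i) {
      tab <- matrix(c(cand$n_arrested[i],
                      cand$n_scored[i] - cand$n_arrested[i],
                      refs$n_arrested[r],
                      refs$n_scored[r] - refs$n_arrested[r]), nrow = 2L)
      fisher_exact(tab)
    }, numeric(1))
  })
  pmat <- matrix(pmat, nrow = nrow(cand))
  if (bh) pmat <- apply(pmat, 2L, bh_adjust)
  pmat <- matrix(pmat, nrow = nrow(cand))
  colnames(pmat) <- paste0("p_vs_", reference_labels)

  prop <- cand$n_arrested / cand$n_scored
  ref_prop <- refs$n_arrested / refs$n_scored
  enhancer <- apply(pmat < alpha, 1L, all) &
    vapply(prop, function(p) all(p > ref_prop), logical(1))
  out <- data.frame(genotype = cand$genotype, n_scored = cand$n_scored,
                    n_arrested = cand$n_arrested, proportion = prop,
                    se = proportion_se(cand$n_arrested, cand$n_scored),
                    stringsAsFactors = FALSE)
  cbind(out, pmat, enhancer = enhancer)
}
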