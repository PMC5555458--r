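#' @title miRNA seed-site scanning in 3' UTRs
#' @name seedscan
#' @description
#' Canonical seed-match detection for the three conserved site classes used
#' by TargetScan-style analyses: 8mer (perfect match to miRNA positions 2-8
#' plus an A opposite position 1), 7mer-m8 (match to positions 2-8), and
#' 7mer-A1 (match to positions 2-7 plus an A opposite position 1).
NULL

# Internal sequence utilities. UTRs may arrive as DNA (T) or RNA (U); all
# matching is done in RNA space.
.norm_rna <- function(x) chartr("Tt", "UU", toupper(x))

.revcomp_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.check_rna_alphabet <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGU]", seq)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  }
  invisible(seq)
}

#' Derive the 7-nt seed from a mature miRNA sequence
#'
#' The seed is defined as nucleotides 2-8 (1-based) of the mature miRNA,
#' read 5' to 3'. miRNAs sharing this heptamer form a family with a common
#' predicted target repertoire.
#'
#' @param mature_sequence Mature miRNA sequence, 5' to 3', at least 8 nt.
#'   `T` is accepted and treated as `U`.
#' @return A 7-character RNA string (positions 2-8).
#' @examples
#' derive_seed("UGAGGUAGUAGGUUGUAUAGUU") # let-7 -> "GAGGUAG"
#' @export
derive_seed <- function(mature_sequence) {
  if (!is.character(mature_sequence) || length(mature_sequence) != 1L)
    stop("mature_sequence must be a single character string")
  s <- .norm_rna(mature_sequence)
  .check_rna_alphabet(s, "mature sequence")
  if (nchar(s) < 8L)
    stop("mature sequence must be at least 8 nt to define a seed (got ",
         nchar(s), ")")
  substr(s, 2L, 8L)
}

#' Find canonical seed-match sites for one miRNA seed in one UTR
#'
#' Scans the UTR sense strand for the reverse complement of the seed. Each
#' match of the 6-nt core (reverse complement of seed positions 2-7, i.e.
#' miRNA positions 2-7) is classified by its flanks into the single
#' strongest applicable class: 8mer when both the position-8 match and the
#' position-1 A are present, otherwise 7mer-m8 or 7mer-A1. Matches of the
#' core in different registers may overlap and are all reported; 6mer-only
#' matches (no qualifying flank) are not sites.
#'
#' @param utr_sequence UTR sequence, sense strand, 5' to 3' (DNA or RNA).
#' @param seed7 7-nt seed as returned by [derive_seed()].
#' @return A data frame with columns `start`, `end` (0-based, half-open
#'   coordinates on the UTR) and `site_type` (one of `"8mer"`, `"7mer-m8"`,
#'   `"7mer-A1"`), ordered by `start`.
#' @examples
#' find_seed_sites("AAACUACCUCAAA", "GAGGUAG") # one 8mer at [3, 11)
#' @export
find_seed_sites <- function(utr_sequence, seed7) {
  if (!is.character(utr_sequence) || length(utr_sequence) != 1L ||
      nchar(utr_sequence) == 0L)
    stop("utr_sequence must be a single non-empty string")
  if (!is.character(seed7) || length(seed7) != 1L || nchar(seed7) != 7L)
    stop("seed7 must be a single 7-nt string")
  seq <- .norm_rna(utr_sequence)
  .check_rna_alphabet(seq, "UTR sequence")
  sd <- .norm_rna(seed7)
  .check_rna_alphabet(sd, "seed")

  empty <- data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < 7L) return(empty)

  p7m8 <- .revcomp_rna(sd)          # site matching miRNA positions 2-8
  core <- substr(p7m8, 2L, 7L)      # matches miRNA positions 2-7
  m8ch <- substr(p7m8, 1L, 1L)      # base pairing miRNA position 8

  starts <- seq_len(L - 5L)         # 1-based starts of 6-nt windows
  hit <- starts[substring(seq, starts, starts + 5L) == core]
  if (length(hit) == 0L) return(empty)

  has_m8 <- hit > 1L & substring(seq, hit - 1L, hit - 1L) == m8ch
  has_a1 <- hit + 6L <= L & substring(seq, hit + 6L, hit + 6L) == "A"

  keep <- has_m8 | has_a1
  hit <- hit[keep]; has_m8 <- has_m8[keep]; has_a1 <- has_a1[keep]
  if (length(hit) == 0L) return(empty)

  type <- ifelse(has_m8 & has_a1, "8mer",
                 ifelse(has_m8, "7mer-m8", "7mer-A1"))
  start0 <- ifelse(has_m8, hit - 2L, hit - 1L)      # 0-based
  end0 <- ifelse(has_a1, hit + 6L, hit + 5L)        # half-open
  out <- data.frame(start = as.integer(start0), end = as.integer(end0),
                    site_type = type, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of UTRs against a table of miRNA families
#'
#' All members of a family must share the same seed (checked); each family
#' is scanned once with that seed. Within a family, sites are deduplicated
#' by (start, end).
#'
#' @param utrs Named character vector of UTR sequences (names = isoform IDs).
#' @param families Data frame with columns `family`, `member`,
#'   `mature_sequence` as written by [simulate_annotation()] /
#'   [read_families_tsv()].
#' @return Data frame with columns `isoform_id`, `family`, `start`, `end`,
#'   `site_type`.
#' @export
scan_seed_sites <- function(utrs, families) {
  if (is.null(names(utrs)) || any(!nzchar(names(utrs))))
    stop("utrs must be a named character vector (names = isoform IDs)")
  seeds <- family_seeds(families)
  res <- vector("list", length(utrs) * length(seeds))
  k <- 0L
  for (i in seq_along(utrs)) {
    for (f in seq_along(seeds)) {
      s <- find_seed_sites(utrs[[i]], seeds[[f]])
      if (nrow(s) > 0L) {
        s <- s[!duplicated(s[, c("start", "end")]), , drop = FALSE]
        k <- k + 1L
        res[[k]] <- cbind(
          data.frame(isoform_id = names(utrs)[i], family = names(seeds)[f],
                     stringsAsFactors = FALSE),
          s)
      }
    }
  }
  if (k == 0L)
    return(data.frame(isoform_id = character(0), family = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Derive per-family seeds from a family table, checking consistency
#'
#' @param families Data frame with columns `family`, `member`,
#'   `mature_sequence`.
#' @return Named character vector family -> seed7.
#' @export
family_seeds <- function(families) {
  need <- c("family", "member", "mature_sequence")
  if (!all(need %in% names(families)))
    stop("families table needs columns: ", paste(need, collapse = ", "))
  if (nrow(families) == 0L) return(stats::setNames(character(0), character(0)))
  seeds7 <- vapply(families$mature_sequence, derive_seed, character(1),
                   USE.NAMES = FALSE)
  by_fam <- split(seeds7, families$family)
  bad <- names(by_fam)[vapply(by_fam, function(x) length(unique(x)) > 1L,
                              logical(1))]
  if (length(bad) > 0L)
    stop("members of family '", bad[1L], "' do not share one seed sequence")
  vapply(by_fam, `[[`, character(1), 1L)[unique(families$family)]
}

#' Per-gene UTR summary: median site count, median length, density per kb
#'
#' When a gene has several annotated 3' UTR isoforms, the median site count
#' across isoforms and the median UTR length are taken separately, and the
#' density pairs the two medians:
#' `density_per_kb = median_sites / median_length * 1000`. With an even
#' number of isoforms the median is the mean of the two middle values, so
#' `median_sites` may be half-integer.
#'
#' @param gene_id Gene identifier (carried through to the output).
#' @param site_counts Integer vector, one seed-site count per isoform.
#' @param utr_lengths Numeric vector of UTR lengths (nt), same order.
#' @return A one-row data frame with `gene_id`, `median_sites`,
#'   `median_length`, `density_per_kb`.
#' @examples
#' gene_summary("g1", 3, 600)          # density 5 per kb
#' gene_summary("g2", c(2, 4), c(500, 1500)) # medians 3 and 1000 -> 3 per kb
#' @export
gene_summary <- function(gene_id, site_counts, utr_lengths) {
  if (length(site_counts) == 0L || length(site_counts) != length(utr_lengths))
    stop("site_counts and utr_lengths must be nonempty and equal length")
  if (any(utr_lengths <= 0))
    stop("UTR lengths must be positive for gene ", gene_id)
  if (any(site_counts < 0))
    stop("site counts must be nonnegative for gene ", gene_id)
  med_s <- stats::median(site_counts)
  med_l <- stats::median(utr_lengths)
  if (med_l == 0) stop("zero median UTR length for gene ", gene_id)
  data.frame(gene_id = gene_id, median_sites = med_s, median_length = med_l,
             density_per_kb = med_s / med_l * 1000,
             stringsAsFactors = FALSE)
}

#' Per-gene site-density table for a scanned UTR set
#'
#' Counts distinct classified windows per isoform — a window matching under
#' several families is counted once, keyed by (start, end) — optionally
#' restricted to a subset of families, then summarises per gene with
#' [gene_summary()].
#'
#' @param sites Site table from [scan_seed_sites()].
#' @param utrs Named character vector of UTR sequences (for lengths).
#' @param gene_map Data frame with columns `gene_id`, `isoform_id`.
#' @param families Optional character vector of family names to restrict to
#'   (default: all families present in `sites`).
#' @return Data frame with one row per gene: `gene_id`, `median_sites`,
#'   `median_length`, `density_per_kb`.
#' @export
utr_density_table <- function(sites, utrs, gene_map, families = NULL) {
  if (!all(c("gene_id", "isoform_id") %in% names(gene_map)))
    stop("gene_map needs columns gene_id and isoform_id")
  if (!is.null(families)) sites <- sites[sites$family %in% families, ,
                                         drop = FALSE]
  lens <- nchar(utrs)
  counts <- vapply(names(utrs), function(iso) {
    s <- sites[sites$isoform_id == iso, c("start", "end"), drop = FALSE]
    nrow(unique(s))
  }, integer(1))
  keep <- gene_map$isoform_id %in% names(utrs)
  gm <- gene_map[keep, , drop = FALSE]
  genes <- unique(gm$gene_id)
  out <- do.call(rbind, lapply(genes, function(g) {
    iso <- gm$isoform_id[gm$gene_id == g]
    gene_summary(g, counts[iso], lens[iso])
  }))
  rownames(out) <- NULL
  out
}

#' Compare seed-site density between a target set and a background set
#'
#' Both gene sets are first filtered to an expressed-gene universe (the
#' stand-in for "annotated expression at the stage of interest"), then mean
#' densities and their ratio are reported.
#'
#' @param target_genes,background_genes Character vectors of gene IDs.
#' @param summaries Per-gene density table from [utr_density_table()].
#' @param expressed_genes Character vector: the expressed-gene filter.
#' @return List with `mean_density_targets`, `mean_density_background`,
#'   `fold_change`, `n_targets`, `n_background`.
#' @export
density_comparison <- function(target_genes, background_genes, summaries,
                               expressed_genes) {
  t_set <- intersect(intersect(target_genes, expressed_genes),
                     summaries$gene_id)
  b_set <- intersect(intersect(background_genes, expressed_genes),
                     summaries$gene_id)
  if (length(t_set) == 0L)
    stop("no target genes remain after expression filtering")
  if (length(b_set) == 0L)
    stop("no background genes remain after expression filtering")
  dt <- summaries$density_per_kb[match(t_set, summaries$gene_id)]
  db <- summaries$density_per_kb[match(b_set, summaries$gene_id)]
  mt <- mean(dt); mb <- mean(db)
  list(mean_density_targets = mt, mean_density_background = mb,
       fold_change = if (mb == 0) NA_real_ else mt / mb,
       n_targets = length(t_set), n_background = length(b_set))
}
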