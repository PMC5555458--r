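# Readers and writers for the plain-text interchange formats: FASTA for
# UTRs, TSV for gene maps / miRNA families / phenotypes / sites, and
# one-ID-per-line gene lists. All round-trip bit-exactly.

#' Read / write UTR sequences as FASTA
#'
#' Headers are isoform IDs. Sequences are returned as a plain named
#' character vector; matching functions accept DNA or RNA letters.
#'
#' @param path File path.
#' @return `read_utr_fasta()` returns a named character vector.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param utrs Named character vector of sequences to write.
#' @rdname read_utr_fasta
#' @export
write_utr_fasta <- function(utrs, path) {
  x <- Biostrings::DNAStringSet(chartr("Uu", "Tt", utrs))
  names(x) <- names(utrs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write the gene-to-isoform map (`gene_id`, `isoform_id`)
#' @param path File path.
#' @return `read_gene_map_tsv()` returns the data frame.
#' @export
read_gene_map_tsv <- function(path)
  .read_tsv(path, c("gene_id", "isoform_id"))

#' @param gene_map Data frame to write.
#' @rdname read_gene_map_tsv
#' @export
write_gene_map_tsv <- function(gene_map, path) .write_tsv(gene_map, path)

#' Read / write the miRNA family table
#' (`family`, `member`, `mature_sequence`)
#' @param path File path.
#' @return `read_families_tsv()` returns the data frame (seed consistency
#'   within each family is checked on load).
#' @export
read_families_tsv <- function(path) {
  df <- .read_tsv(path, c("family", "member", "mature_sequence"))
  family_seeds(df)  # errors if members of a family disagree on the seed
  df
}

#' @param families Data frame to write.
#' @rdname read_families_tsv
#' @export
write_families_tsv <- function(families, path) .write_tsv(families, path)

#' Read / write a phenotype table (`genotype`, `n_scored`, `n_arrested`)
#' @param path File path.
#' @return `read_phenotypes_tsv()` returns the data frame.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- .read_tsv(path, c("genotype", "n_scored", "n_arrested"))
  if (any(df$n_arrested < 0 | df$n_arrested > df$n_scored))
    stop("n_arrested must be between 0 and n_scored")
  df
}

#' @param phenotypes Data frame to write.
#' @rdname read_phenotypes_tsv
#' @export
write_phenotypes_tsv <- function(phenotypes, path)
  .write_tsv(phenotypes, path)

#' Read / write a gene list (one ID per line)
#' @param path File path.
#' @return `read_gene_list()` returns a character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @param genes Character vector of gene IDs to write.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read / write a seed-site table
#' (`isoform_id`, `family`, `start`, `end`, `site_type`; BED-like 0-based
#' half-open coordinates)
#' @param path File path.
#' @return `read_sites_tsv()` returns the data frame.
#' @export
read_sites_tsv <- function(path)
  .read_tsv(path, c("isoform_id", "family", "start", "end", "site_type"))

#' @param sites Data frame to write.
#' @rdname read_sites_tsv
#' @export
write_sites_tsv <- function(sites, path) .write_tsv(sites, path)
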