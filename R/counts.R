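# Count matrices are plain integer matrices: rows = transcripts (rownames =
# transcript IDs), columns = samples named "<CLASS>:<replicate>" with CLASS
# in {IP, CTRL, TOTAL}, e.g. "IP:1". This mirrors a RIP-Seq design with a
# tagged-protein IP, a tag-only control IP, and pre-IP total RNA.

.SAMPLE_CLASSES <- c("IP", "CTRL", "TOTAL")

#' Parse sample classes and replicate indices from count-matrix column names
#'
#' @param counts Count matrix with columns named `"CLASS:replicate"`.
#' @return Data frame with columns `sample`, `class`, `replicate`.
#' @export
sample_info <- function(counts) {
  cn <- colnames(counts)
  if (is.null(cn)) stop("count matrix has no column names")
  parts <- strsplit(cn, ":", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 2L
  if (any(!ok))
    stop("sample name(s) not of the form CLASS:replicate: ",
         paste(cn[!ok], collapse = ", "))
  cls <- vapply(parts, `[[`, character(1), 1L)
  rep <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  bad <- !(cls %in% .SAMPLE_CLASSES) | is.na(rep)
  if (any(bad))
    stop("invalid sample name(s): ", paste(cn[bad], collapse = ", "),
         " (class must be one of ", paste(.SAMPLE_CLASSES, collapse = "/"),
         ")")
  data.frame(sample = cn, class = cls, replicate = rep,
             stringsAsFactors = FALSE)
}

#' Validate a RIP-Seq count matrix
#'
#' Checks that counts are a nonnegative integral matrix with transcript
#' rownames and parseable sample column names, and that every library has a
#' positive total.
#'
#' @param counts Candidate count matrix.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)))
    stop("counts must have transcript IDs as rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  info <- sample_info(counts)
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total reads: ",
         paste(info$sample[tot <= 0], collapse = ", "))
  invisible(counts)
}

#' Read / write a transcript count table as TSV
#'
#' The TSV has a `transcript_id` first column and one column per sample,
#' with the header encoding class and replicate (e.g. `IP:1`).
#'
#' @param path File path.
#' @return `read_counts_tsv()` returns the count matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "transcript_id")
    stop("first column of a counts TSV must be transcript_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$transcript_id
  validate_counts(m)
  m
}

#' @param counts Count matrix to write.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
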