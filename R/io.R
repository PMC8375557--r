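#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) { next }
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped).
#' @return list with character vectors `seq` and `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities),
       id = names(x))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param seqs character vector of read sequences.
#' @param path output file.
#' @param qual quality strings; default constant 'I' (Phred 40).
#' @param ids read names; default read1..readN.
#' @export
write_fastq <- function(seqs, path, qual = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  if (is.null(qual)) qual <- vapply(nchar(seqs), function(w)
    strrep("I", w), character(1))
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Write a BED6 file of tag sites
#'
#' Coordinates are 0-based half-open; score column holds 0.
#'
#' @param sites data.frame with contig, core_start, core_end, strand and a
#'   name column (canonical_sequence or locus id).
#' @param path output file.
#' @param name_col column to use for the BED name field.
#' @export
write_bed <- function(sites, path, name_col = "canonical_sequence") {
  bed <- data.frame(sites$contig, sites$core_start, sites$core_end,
                    sites[[name_col]], 0L, sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (individual_id, sex)
#'
#' @param path TSV with columns individual_id and sex (F or M).
#' @return data.frame with character individual_id and sex.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("individual_id", "sex") %in% names(ss)))
    stop("sample sheet needs columns individual_id, sex")
  if (!all(ss$sex %in% c("F", "M")))
    stop("sex must be F or M")
  ss
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
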