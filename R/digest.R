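#' Recognition specification for a type IIB restriction enzyme
#'
#' A type IIB enzyme cuts on both sides of its recognition site and releases
#' a fixed-length fragment. The default models BsaXI: an 11-nt interrupted
#' recognition motif AC(N5)CTCC with 9 nt retained 5' and 7 nt retained 3',
#' giving the 27-nt tag core (9 + 11 + 7) seen in 2b-RAD libraries, plus 3-nt
#' terminal bases on each side of the core in the 33-nt sequenced read.
#'
#' @param enzyme_name label for reports.
#' @param motif IUPAC recognition motif.
#' @param left_core nucleotides retained 5' of the motif in the core.
#' @param right_core nucleotides retained 3' of the motif in the core.
#' @param left_read,right_read terminal nucleotides flanking the core in the
#'   sequenced read.
#' @return an object of class `recognition_spec`.
#' @export
recognition_spec <- function(enzyme_name = "BsaXI", motif = "ACNNNNNCTCC",
                             left_core = 9L, right_core = 7L,
                             left_read = 3L, right_read = 3L) {
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop("motif contains non-IUPAC characters: ", paste(bad, collapse = ","))
  stopifnot_scalar_count(left_core, "left_core")
  stopifnot_scalar_count(right_core, "right_core")
  spec <- list(enzyme_name = enzyme_name, motif = motif,
               motif_length = nchar(motif),
               left_core = as.integer(left_core),
               right_core = as.integer(right_core),
               left_read = as.integer(left_read),
               right_read = as.integer(right_read))
  spec$core_length <- spec$left_core + spec$motif_length + spec$right_core
  spec$read_length <- spec$left_read + spec$core_length + spec$right_read
  class(spec) <- "recognition_spec"
  spec
}

#' Canonical (strand-independent) form of a tag core
#'
#' Returns the lexicographic minimum of a sequence and its reverse
#' complement, so that the same physical tag read from either strand maps to
#' one identity. Idempotent, and invariant under reverse complement of the
#' input.
#'
#' @param x character vector of core sequences (ACGT only).
#' @param core_length required length (default 27).
#' @return character vector of canonical sequences.
#' @export
canonicalize <- function(x, core_length = 27L) {
  if (length(x) == 0L) return(character(0))
  if (any(nchar(x) != core_length))
    stop("all sequences must have length ", core_length)
  if (any(grepl("[^ACGT]", x)))
    stop("sequences must contain only A, C, G, T")
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Scan a sequence for type IIB recognition sites on both strands
#'
#' Finds every position where the IUPAC motif matches (motif-side ambiguity
#' codes expanded; subject-side N never matches) and the full core window
#' fits inside the sequence. Sites whose core window contains a non-ACGT
#' base are skipped and counted. Palindromic loci that match identically on
#' both strands are reported once (deduplicated by interval and canonical
#' core).
#'
#' @param sequence a nucleotide string (ACGTN + IUPAC).
#' @param spec a [recognition_spec()].
#' @param contig contig name used in the output.
#' @return data.frame with columns contig, motif_start (0-based), strand,
#'   core_start, core_end (0-based half-open), core_sequence (strand
#'   oriented, motif-forward) and canonical_sequence; attribute
#'   `n_skipped_ambiguous` counts sites dropped for N in the core window.
#' @export
scan_motif <- function(sequence, spec = recognition_spec(),
                       contig = "seq1") {
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop("non-nucleotide characters in sequence: ",
         paste(bad, collapse = ","))
  L <- nchar(sequence)
  empty <- data.frame(contig = character(0), motif_start = integer(0),
                      strand = character(0), core_start = integer(0),
                      core_end = integer(0), core_sequence = character(0),
                      canonical_sequence = character(0),
                      stringsAsFactors = FALSE)
  if (L < spec$core_length) {
    attr(empty, "n_skipped_ambiguous") <- 0L
    return(empty)
  }
  subj <- Biostrings::DNAString(sequence)
  pat_f <- Biostrings::DNAString(spec$motif)
  pat_r <- Biostrings::reverseComplement(pat_f)
  hit_f <- Biostrings::matchPattern(pat_f, subj, fixed = "subject")
  hit_r <- Biostrings::matchPattern(pat_r, subj, fixed = "subject")

  rows <- list()
  # forward strand: core = [start-1-left_core, end+right_core) 0-based
  if (length(hit_f) > 0L) {
    s <- Biostrings::start(hit_f); e <- Biostrings::end(hit_f)
    cs <- s - 1L - spec$left_core
    ce <- e + spec$right_core
    keep <- cs >= 0L & ce <= L
    if (any(keep)) {
      cs <- cs[keep]; ce <- ce[keep]; s <- s[keep]
      rows[[1]] <- data.frame(
        contig = contig, motif_start = s - 1L, strand = "+",
        core_start = cs, core_end = ce,
        core_sequence = substring(sequence, cs + 1L, ce),
        stringsAsFactors = FALSE)
    }
  }
  # minus strand: motif on revcomp; in forward coords the left_core extends
  # rightwards past the match end
  if (length(hit_r) > 0L) {
    s <- Biostrings::start(hit_r); e <- Biostrings::end(hit_r)
    cs <- s - 1L - spec$right_core
    ce <- e + spec$left_core
    keep <- cs >= 0L & ce <= L
    if (any(keep)) {
      cs <- cs[keep]; ce <- ce[keep]; s <- s[keep]
      rows[[2]] <- data.frame(
        contig = contig, motif_start = s - 1L, strand = "-",
        core_start = cs, core_end = ce,
        core_sequence = revcomp(substring(sequence, cs + 1L, ce)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L || all(vapply(rows, is.null, logical(1)))) {
    attr(empty, "n_skipped_ambiguous") <- 0L
    return(empty)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ambiguous <- grepl("[^ACGT]", out$core_sequence)
  n_skipped <- sum(ambiguous)
  out <- out[!ambiguous, , drop = FALSE]
  if (nrow(out) > 0L) {
    out$canonical_sequence <- canonicalize(out$core_sequence,
                                           spec$core_length)
    out <- out[order(out$core_start, out$strand), , drop = FALSE]
    dup <- duplicated(out[, c("contig", "core_start", "core_end",
                              "canonical_sequence")])
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$canonical_sequence <- character(0)
  }
  attr(out, "n_skipped_ambiguous") <- n_skipped
  out
}

#' Extract the genome-wide tag catalog from a reference
#'
#' Runs [scan_motif()] over every contig and collates the sites: the
#' in-silico equivalent of a complete type IIB digestion.
#'
#' @param reference named character vector of contig sequences, or a path to
#'   a FASTA file.
#' @param spec a [recognition_spec()].
#' @return data.frame of sites (see [scan_motif()]), sorted by contig then
#'   core_start then strand. Empty reference gives an empty catalog with a
#'   warning.
#' @export
extract_tag_catalog <- function(reference, spec = recognition_spec()) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference))
    reference <- read_fasta(reference)
  if (length(reference) == 0L || all(nchar(reference) == 0L)) {
    warning("empty reference: empty tag catalog")
    out <- scan_motif(strrep("A", spec$core_length), spec)[0, ]
    return(out)
  }
  if (is.null(names(reference)))
    names(reference) <- paste0("contig", seq_along(reference))
  parts <- lapply(names(reference), function(ctg) {
    if (nchar(reference[[ctg]]) == 0L) return(NULL)
    scan_motif(reference[[ctg]], spec, contig = ctg)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- do.call(rbind, parts)
  out <- out[order(out$contig, out$core_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the core sequences of a tag catalog to FASTA
#'
#' Headers encode contig:start-end:strand (0-based half-open).
#'
#' @param sites site table from [extract_tag_catalog()].
#' @param path output FASTA.
#' @export
write_core_fasta <- function(sites, path) {
  seqs <- sites$core_sequence
  names(seqs) <- sprintf("%s:%d-%d:%s", sites$contig, sites$core_start,
                         sites$core_end, sites$strand)
  write_fasta(seqs, path)
}
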