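IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Reverse complement of nucleotide strings
#'
#' Vectorised over a character vector; handles IUPAC ambiguity codes.
#'
#' @param x character vector of nucleotide sequences (ACGT + IUPAC).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert an IUPAC motif to a base-R regular expression
#'
#' Each ambiguity code becomes a character class over the plain bases it
#' denotes, so a subject-side N is never matched by a motif N.
#'
#' @param motif IUPAC motif string.
#' @return a regular expression string.
#' @export
iupac_to_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

# integer codes A=0 C=1 G=2 T=3, NA otherwise; x a single string
seq_to_codes <- function(x) {
  map <- rep(NA_integer_, 256)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
  map[utf8ToInt(x) + 1L - 1L]
}

# character matrix (reads x positions) from equal-length strings
seq_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), 0, 0))
  w <- nchar(x[1])
  matrix(unlist(strsplit(x, ""), use.names = FALSE), nrow = length(x),
         ncol = w, byrow = TRUE)
}

# Hamming distance between one sequence (integer codes, length w) and the
# columns of a w x n integer matrix
hamming_to_all <- function(q, consmat) {
  if (ncol(consmat) == 0L) return(integer(0))
  .colSums(consmat != q, nrow(consmat), ncol(consmat))
}

hamming_pair <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(name, " must be a single integer >= ", min)
}
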