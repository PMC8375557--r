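#' Quality-control parameters for raw 2b-RAD reads
#'
#' @param max_n_fraction maximum tolerated fraction of ambiguous bases (N);
#'   a read fails when its N fraction strictly exceeds this (default 0.08).
#' @param min_mean_quality minimum mean Phred quality (default 20).
#' @param require_motif drop reads without a recognition-site match on
#'   either strand (default TRUE).
#' @param read_length expected read length (default 33).
#' @param core_length tag core length (default 27).
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(max_n_fraction = 0.08, min_mean_quality = 20,
                      require_motif = TRUE, read_length = 33L,
                      core_length = 27L) {
  if (max_n_fraction < 0 || max_n_fraction > 1)
    stop("max_n_fraction must be in [0, 1]")
  if (read_length < core_length)
    stop("read_length must be >= core_length")
  structure(list(max_n_fraction = max_n_fraction,
                 min_mean_quality = min_mean_quality,
                 require_motif = require_motif,
                 read_length = as.integer(read_length),
                 core_length = as.integer(core_length)),
            class = "qc_params")
}

# first forward-strand motif start (1-based) that leaves a full core window
# inside each read; NA where none. seqs all same length.
motif_core_start <- function(seqs, spec) {
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  w <- nchar(seqs[1])
  hits <- Biostrings::vmatchPattern(Biostrings::DNAString(spec$motif),
                                    Biostrings::DNAStringSet(seqs),
                                    fixed = "subject")
  starts <- Biostrings::startIndex(hits)
  vapply(seq_len(n), function(i) {
    st <- starts[[i]]
    if (is.null(st) || length(st) == 0L) return(NA_integer_)
    cs <- st - spec$left_core          # 1-based core start
    ce <- st + spec$motif_length - 1L + spec$right_core
    ok <- cs >= 1L & ce <= w
    if (any(ok)) cs[ok][1] else -1L    # -1: motif present, window truncated
  }, integer(1))
}

#' Filter a single read
#'
#' Failure reasons are checked in a fixed order: wrong_length, then
#' n_excess (N fraction strictly above the threshold), then low_quality
#' (mean Phred below threshold), then no_motif (no recognition-site match
#' on either strand).
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string of the same length.
#' @param params a [qc_params()].
#' @param spec a [recognition_spec()].
#' @return list with `pass` (logical) and `reason` (NA or one of
#'   "wrong_length", "n_excess", "low_quality", "no_motif").
#' @export
filter_read <- function(seq, qual, params = qc_params(),
                        spec = recognition_spec()) {
  if (nchar(qual) != nchar(seq))
    stop("quality string length differs from sequence length")
  res <- qc_classify(seq, qual, params, spec)
  list(pass = is.na(res), reason = res)
}

# vectorised QC classification; returns NA for pass else the reason
qc_classify <- function(seqs, quals, params, spec) {
  n <- length(seqs)
  reason <- rep(NA_character_, n)
  seqs <- toupper(seqs)
  len_ok <- nchar(seqs) == params$read_length
  reason[!len_ok] <- "wrong_length"

  todo <- which(is.na(reason))
  if (length(todo) > 0L) {
    nfrac <- (nchar(seqs[todo]) -
                nchar(gsub("N", "", seqs[todo], fixed = TRUE))) /
      nchar(seqs[todo])
    reason[todo[nfrac > params$max_n_fraction]] <- "n_excess"
  }

  todo <- which(is.na(reason))
  if (length(todo) > 0L) {
    qlists <- methods::as(Biostrings::PhredQuality(quals[todo]),
                          "IntegerList")
    meanq <- sum(qlists) / lengths(qlists)
    reason[todo[meanq < params$min_mean_quality]] <- "low_quality"
  }

  if (isTRUE(params$require_motif)) {
    todo <- which(is.na(reason))
    if (length(todo) > 0L) {
      s <- seqs[todo]
      # N never matches the motif scanner; mask rare leftover ambiguity
      s_clean <- gsub("[^ACGT]", "N", s)
      fwd <- motif_core_start(s_clean, spec)
      rev_ <- motif_core_start(revcomp(s_clean), spec)
      has <- (!is.na(fwd) & fwd > 0L) | (!is.na(rev_) & rev_ > 0L)
      reason[todo[!has]] <- "no_motif"
    }
  }
  reason
}

#' Trim a clean read to its motif-forward tag core
#'
#' Locates the recognition motif (forward strand first, then the reverse
#' complement) and returns the core window that places the motif at offset
#' `left_core`. Minus-strand matches are reverse-complemented so the output
#' is always motif-forward.
#'
#' @param seq read sequence (ACGT).
#' @param spec a [recognition_spec()].
#' @return the core sequence, or NA with attribute reason "wrong_structure"
#'   when the motif sits too close to a read end for a full core window.
#' @export
trim_to_core <- function(seq, spec = recognition_spec()) {
  out <- trim_to_core_vec(seq, spec)[1]
  if (is.na(out)) attr(out, "reason") <- "wrong_structure"
  out
}

# vectorised trim; NA where no full-window motif on either strand
trim_to_core_vec <- function(seqs, spec) {
  n <- length(seqs)
  if (n == 0L) return(character(0))
  seqs <- toupper(seqs)
  cs_f <- motif_core_start(seqs, spec)
  out <- rep(NA_character_, n)
  ok_f <- !is.na(cs_f) & cs_f > 0L
  if (any(ok_f))
    out[ok_f] <- substring(seqs[ok_f], cs_f[ok_f],
                           cs_f[ok_f] + spec$core_length - 1L)
  rest <- which(!ok_f)
  if (length(rest) > 0L) {
    rc <- revcomp(seqs[rest])
    cs_r <- motif_core_start(rc, spec)
    ok_r <- !is.na(cs_r) & cs_r > 0L
    if (any(ok_r))
      out[rest[ok_r]] <- substring(rc[ok_r], cs_r[ok_r],
                                   cs_r[ok_r] + spec$core_length - 1L)
  }
  out
}

#' Run quality control over a set of per-individual read files
#'
#' Applies [filter_read()]'s rules to every read, trims survivors to their
#' 27-nt cores, canonicalizes them, and tallies a per-individual accounting
#' report. Every input read lands in exactly one bucket (clean or one
#' failure reason).
#'
#' @param reads named list (individual -> character vector of read
#'   sequences), or named list of FASTQ paths, or a directory plus
#'   `samples`.
#' @param samples sample sheet data.frame (individual_id, sex); every read
#'   set must correspond to a row.
#' @param params a [qc_params()].
#' @param spec a [recognition_spec()].
#' @param quals optional named list of quality strings parallel to `reads`;
#'   constant maximal quality assumed when absent.
#' @return list with `cores` (named list of canonical core vectors) and
#'   `report` (data.frame: individual, raw_reads, clean_reads, wrong_length,
#'   n_excess, low_quality, no_motif).
#' @export
run_qc <- function(reads, samples, params = qc_params(),
                   spec = recognition_spec(), quals = NULL) {
  if (is.character(reads)) {  # paths
    paths <- reads
    parsed <- lapply(paths, read_fastq)
    reads <- lapply(parsed, `[[`, "seq")
    quals <- lapply(parsed, `[[`, "qual")
    names(reads) <- names(quals) <- names(paths)
  }
  missing_ids <- setdiff(names(reads), samples$individual_id)
  if (length(missing_ids) > 0L)
    stop("individuals absent from sample sheet: ",
         paste(missing_ids, collapse = ", "))
  cores <- vector("list", length(reads))
  names(cores) <- names(reads)
  rep_rows <- vector("list", length(reads))
  for (ind in names(reads)) {
    s <- reads[[ind]]
    q <- if (!is.null(quals)) quals[[ind]] else
      vapply(nchar(s), function(w) strrep("I", w), character(1))
    reason <- qc_classify(s, q, params, spec)
    pass <- is.na(reason)
    core <- trim_to_core_vec(s[pass], spec)
    # motif found during classification but window truncated
    bad_struct <- is.na(core)
    reason[which(pass)[bad_struct]] <- "no_motif"
    core <- core[!bad_struct]
    cores[[ind]] <- canonicalize(core, spec$core_length)
    tab <- table(factor(reason, levels = c("wrong_length", "n_excess",
                                           "low_quality", "no_motif")))
    rep_rows[[ind]] <- data.frame(
      individual = ind, raw_reads = length(s), clean_reads = sum(is.na(reason)),
      wrong_length = as.integer(tab[["wrong_length"]]),
      n_excess = as.integer(tab[["n_excess"]]),
      low_quality = as.integer(tab[["low_quality"]]),
      no_motif = as.integer(tab[["no_motif"]]),
      stringsAsFactors = FALSE)
  }
  list(cores = cores, report = do.call(rbind, rep_rows))
}
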