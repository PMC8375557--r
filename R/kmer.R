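# canonical 2-bit k-mer values over a set of sequences, computed in one
# rolling pass over the N-joined concatenation (the joining N invalidates
# every window spanning a sequence boundary)
kmer_values <- function(seqs, k, canonical = TRUE) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(numeric(0))
  s <- paste(seqs, collapse = "N")
  cf <- seq_to_codes(s)
  n <- length(cf) - k + 1L
  vf <- numeric(n)
  vr <- if (canonical) numeric(n) else NULL
  for (j in 0:(k - 1L)) {
    cj <- cf[(1L + j):(n + j)]
    vf <- vf * 4 + cj
    if (canonical) vr <- vr + (3 - cj) * 4^j
  }
  keep <- which(!is.na(vf))
  if (canonical) pmin(vf[keep], vr[keep]) else vf[keep]
}

#' Count k-mers across sequences
#'
#' Builds the k-mer multiplicity spectrum (the jellyfish "histo"): how many
#' distinct k-mers occur with each multiplicity. In canonical mode (the
#' `-C` behaviour) a k-mer and its reverse complement count as one species.
#' K-mers containing non-ACGT characters are skipped.
#'
#' @param seqs character vector of sequences (reads or contigs), or a FASTA/
#'   FASTQ path.
#' @param k k-mer length (default 17; a warning is issued for even k in
#'   canonical mode, where palindromes make the spectrum ambiguous).
#' @param canonical count min(kmer, revcomp) (default TRUE).
#' @return object of class `kmer_histogram`: list with `k`, `canonical`,
#'   `counts` (data.frame: multiplicity, n_kmers), `total_kmers`,
#'   `distinct_kmers`.
#' @export
count_kmers <- function(seqs, k = 17L, canonical = TRUE) {
  if (length(seqs) == 1L && nchar(seqs) < 1000L && file.exists(seqs)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", seqs)) "fastq" else "fasta"
    seqs <- as.character(Biostrings::readDNAStringSet(seqs, format = fmt))
  }
  if (canonical && k %% 2L == 0L)
    warning("even k with canonical counting: palindromic k-mers collapse")
  seqs <- toupper(seqs)
  if (all(nchar(seqs) < k)) warning("all sequences shorter than k")
  vals <- sort(kmer_values(seqs, k, canonical))
  if (length(vals) == 0L) {
    counts <- data.frame(multiplicity = integer(0), n_kmers = integer(0))
  } else {
    mult <- rle(vals)$lengths
    tab <- table(mult)
    counts <- data.frame(multiplicity = as.integer(names(tab)),
                         n_kmers = as.integer(tab))
  }
  structure(list(k = as.integer(k), canonical = canonical, counts = counts,
                 total_kmers = sum(as.numeric(counts$multiplicity) *
                                     counts$n_kmers),
                 distinct_kmers = sum(counts$n_kmers)),
            class = "kmer_histogram")
}

#' Estimate genome size and heterozygosity from a k-mer spectrum
#'
#' A simplified single-peak survey estimator. The error cutoff is the first
#' local minimum of the (window-3 smoothed) spectrum; the homozygous peak
#' depth is the raw argmax of multiplicity x count within 2 of the smoothed
#' argmax above the cutoff. Genome size is total k-mer mass above the cutoff
#' divided by the homozygous peak depth. Heterozygosity: distinct k-mers in
#' the half-depth (heterozygous) band count two variants per diverged locus,
#' so the fraction of affected loci is h = (het/2) / (het/2 + hom), and the
#' per-base rate is 1 - (1 - h)^(1/k).
#'
#' @param hist a `kmer_histogram` from [count_kmers()].
#' @param het_boundary_factor multiplicities in (cutoff,
#'   factor x peak\] count as the heterozygous band (default 0.75).
#' @return object of class `survey_estimate`: list with
#'   `homozygous_peak_depth`, `error_cutoff`, `genome_size_bp`,
#'   `heterozygosity`.
#' @export
estimate_genome_size <- function(hist, het_boundary_factor = 0.75) {
  ct <- hist$counts
  if (nrow(ct) == 0L) stop("empty k-mer histogram")
  mmax <- max(ct$multiplicity)
  full <- numeric(mmax)
  full[ct$multiplicity] <- ct$n_kmers
  if (mmax >= 3L) {
    sm <- stats::filter(full, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- full[is.na(sm)]
    sm <- as.numeric(sm)
  } else {
    sm <- full
  }
  # first local minimum (first rising point) of the smoothed spectrum
  cutoff <- 1L
  if (mmax >= 2L) {
    rising <- which(diff(sm) > 0)
    cutoff <- if (length(rising) > 0L) rising[1] else 1L
  }
  y <- seq_len(mmax) * full
  ysm <- seq_len(mmax) * sm
  cand <- seq_len(mmax) > cutoff
  if (!any(cand) || all(ysm[cand] == 0))
    stop("no coverage peak above the error cutoff; spectrum: ",
         paste(utils::head(full, 30), collapse = ","))
  sm_peak <- which(cand)[which.max(ysm[cand])]
  win <- max(cutoff + 1L, sm_peak - 2L):min(mmax, sm_peak + 2L)
  peak <- win[which.max(y[win])]
  mass_above <- sum(as.numeric(which(cand)) * full[cand])
  genome_size <- mass_above / peak
  # heterozygous band: distinct k-mers at roughly half the homozygous depth
  boundary <- floor(het_boundary_factor * peak)
  het_band <- seq_len(mmax) > cutoff & seq_len(mmax) <= boundary
  hom_band <- seq_len(mmax) > boundary
  het_distinct <- sum(full[het_band])
  hom_distinct <- sum(full[hom_band])
  h <- (het_distinct / 2) / (het_distinct / 2 + hom_distinct)
  het_rate <- 1 - (1 - h)^(1 / hist$k)
  structure(list(homozygous_peak_depth = peak,
                 error_cutoff = as.integer(cutoff),
                 genome_size_bp = genome_size,
                 heterozygosity = het_rate),
            class = "survey_estimate")
}

#' Write a k-mer histogram in the two-column histo format
#'
#' @param hist a `kmer_histogram`.
#' @param path output TSV (multiplicity, count).
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
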