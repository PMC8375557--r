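# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (base-R regex and arithmetic only) so that agreement is a
# genuine cross-check.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# IUPAC motif -> regex using an independent code table
ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
                     Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
                     M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
                     V = "[ACG]", N = "[ACGT]")

oracle_motif_regex <- function(motif) {
  paste(unlist(ORACLE_IUPAC[strsplit(motif, "")[[1]]]), collapse = "")
}

# all (0-based motif start, strand) sites with a full core window, the way
# the scanner defines them, found by overlapping regex on both strands
oracle_scan <- function(seq, motif = "ACNNNNNCTCC", left_core = 9,
                        right_core = 7) {
  L <- nchar(seq)
  mlen <- nchar(motif)
  find_all <- function(s, pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
    hits[hits != -1L]
  }
  fwd <- find_all(seq, oracle_motif_regex(motif))
  rev_ <- find_all(seq, oracle_motif_regex(oracle_revcomp(motif)))
  rows <- list()
  for (p in fwd) {  # 1-based motif start
    cs <- p - 1L - left_core
    ce <- p - 1L + mlen + right_core
    if (cs >= 0 && ce <= L) {
      core <- substr(seq, cs + 1L, ce)
      if (!grepl("[^ACGT]", core))
        rows[[length(rows) + 1L]] <- data.frame(
          motif_start = p - 1L, strand = "+", core = core)
    }
  }
  for (p in rev_) {
    cs <- p - 1L - right_core
    ce <- p - 1L + mlen + left_core
    if (cs >= 0 && ce <= L) {
      core <- oracle_revcomp(substr(seq, cs + 1L, ce))
      if (!grepl("[^ACGT]", core))
        rows[[length(rows) + 1L]] <- data.frame(
          motif_start = p - 1L, strand = "-", core = core)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif_start = integer(0), strand = character(0),
                      core = character(0)))
  do.call(rbind, rows)
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(k, r1, n - r1, c1)
  p_obs <- probs[k == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# k-mer spectrum via an associative table over substrings
oracle_kmer_hist <- function(seqs, k, canonical = TRUE) {
  tab <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in 1:(L - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      if (canonical) {
        rc <- oracle_revcomp(km)
        if (rc < km) km <- rc
      }
      assign(km, get0(km, envir = tab, ifnotfound = 0L) + 1L, envir = tab)
    }
  }
  mult <- unlist(as.list(tab), use.names = FALSE)
  if (length(mult) == 0L)
    return(data.frame(multiplicity = integer(0), n_kmers = integer(0)))
  t <- table(mult)
  data.frame(multiplicity = as.integer(names(t)), n_kmers = as.integer(t))
}

oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# random flank that leaves an embedded construct with no accidental motif
random_seq_motif_free <- function(n) {
  for (i in 1:100) {
    s <- random_seq(n)
    if (nrow(oracle_scan_sites_only(s)) == 0L) return(s)
  }
  stop("no motif-free flank found")
}

# like oracle_scan but without the core-window requirement (any motif hit)
oracle_scan_sites_only <- function(seq, motif = "ACNNNNNCTCC") {
  find_all <- function(s, pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
    hits[hits != -1L]
  }
  fwd <- find_all(seq, oracle_motif_regex(motif))
  rev_ <- find_all(seq, oracle_motif_regex(oracle_revcomp(motif)))
  data.frame(pos = c(fwd, rev_),
             strand = rep(c("+", "-"), c(length(fwd), length(rev_))))
}

# embed a tag between motif-free flanks such that the construct contains
# exactly one motif occurrence (the tag's own)
embed_in_motif_free <- function(tag, flank) {
  for (i in 1:100) {
    s <- paste0(random_seq(flank), tag, random_seq(flank))
    if (nrow(oracle_scan_sites_only(s)) == 1L) return(s)
  }
  stop("embedding failed")
}
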