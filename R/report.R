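fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "rad2b")
  if (p == "") p <- file.path("inst", "extdata", name)
  p
}

#' Load the per-individual sequencing run table
#'
#' The shipped fixture transcribes the published 20-individual 2b-RAD run
#' summary (the clean column of the printed table is a read count: it sums
#' exactly to the clean-read totals quoted in the accompanying text).
#'
#' @param path TSV with columns name, sex, raw_reads, raw_bases,
#'   clean_reads, tags, depth; default the shipped fixture.
#' @return data.frame of per-individual rows.
#' @export
load_run_table <- function(path = fixture_path("table1.tsv")) {
  rt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sex", "raw_reads", "raw_bases", "clean_reads", "tags",
            "depth")
  if (!all(need %in% names(rt)))
    stop("run table needs columns: ", paste(need, collapse = ", "))
  rt
}

#' Summarize a sequencing run table
#'
#' Exact integer totals overall and per sex, plus the unrounded mean depth
#' (and its 2-dp rendering).
#'
#' @param rows data.frame as from [load_run_table()].
#' @return list with `total` (raw_reads, raw_bases, clean_reads, tags,
#'   mean_depth, mean_depth_2dp) and `by_sex` (same per sex).
#' @export
summarize_run_table <- function(rows) {
  if (nrow(rows) < 1L) stop("run table must have at least one row")
  num <- c("raw_reads", "raw_bases", "clean_reads", "tags", "depth")
  if (any(vapply(rows[num], function(x) any(x < 0), logical(1))))
    stop("negative counts in run table")
  sum_block <- function(r) list(
    raw_reads = sum(r$raw_reads), raw_bases = sum(r$raw_bases),
    clean_reads = sum(r$clean_reads), tags = sum(r$tags),
    mean_depth = mean(r$depth),
    mean_depth_2dp = sprintf("%.2f", mean(r$depth)))
  by_sex <- lapply(split(rows, rows$sex), sum_block)
  list(total = sum_block(rows), by_sex = by_sex)
}

#' Load the candidate sex-specific tag fixture
#'
#' Validates that every record is a 27-nt ACGT sequence.
#'
#' @param path fixture TSV (tag_name, ref_id, sequence); default shipped.
#' @param core_length expected tag length (default 27).
#' @return data.frame of tag records.
#' @export
load_candidate_tags <- function(path = fixture_path("table3.tsv"),
                                core_length = 27L) {
  tg <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tag_name", "ref_id", "sequence") %in% names(tg)))
    stop("tag fixture needs columns tag_name, ref_id, sequence")
  if (any(nchar(tg$sequence) != core_length))
    stop("tag sequences must all have length ", core_length)
  if (any(grepl("[^ACGT]", tg$sequence)))
    stop("tag sequences must be ACGT only")
  tg
}

#' Load the candidate sex-specific SNP fixture
#'
#' Validates the schema (1-based SNP position on the 27-nt tag, single-base
#' ref/alt, slash-separated genotype strings per sex).
#'
#' @param path fixture TSV; default shipped.
#' @param core_length tag length bound for snp_position (default 27).
#' @return data.frame of SNP records.
#' @export
load_candidate_snps <- function(path = fixture_path("table4.tsv"),
                                core_length = 27L) {
  sn <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_name", "ref_id", "snp_position", "ref_base", "alt_base",
            "female_genotype", "male_genotype")
  if (!all(need %in% names(sn)))
    stop("SNP fixture needs columns: ", paste(need, collapse = ", "))
  if (any(sn$snp_position < 1L | sn$snp_position > core_length))
    stop("snp_position must be within 1..", core_length)
  gt_ok <- function(g) grepl("^[ACGT]/[ACGT]$", g)
  if (!all(gt_ok(sn$female_genotype)) || !all(gt_ok(sn$male_genotype)))
    stop("genotypes must parse as base/base")
  sn
}

#' Build an in-silico PCR assay around a tag hit
#'
#' Locates the tag (exact 27-mer or its reverse complement) in the
#' scaffolds, requires a unique hit, and returns an amplicon window of up
#' to `amplicon_max` bp centered on the tag, clipped to the scaffold ends.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param tag_seq the 27-nt tag core.
#' @param marker_id assay label.
#' @param amplicon_min,amplicon_max amplicon length bounds (default
#'   100-1000 bp).
#' @param expected_presence named character vector sex -> "band"/"no_band"
#'   (default female-limited: F band, M no band).
#' @return object of class `marker_assay`: list with marker_id,
#'   scaffold_id, start, end (0-based half-open), expected_presence.
#' @export
extract_flanks <- function(scaffolds, tag_seq, marker_id = tag_seq,
                           amplicon_min = 100L, amplicon_max = 1000L,
                           expected_presence = c(F = "band",
                                                 M = "no_band")) {
  hits <- list()
  for (ctg in names(scaffolds)) {
    for (pat in unique(c(tag_seq, revcomp(tag_seq)))) {
      m <- gregexpr(pat, scaffolds[[ctg]], fixed = TRUE)[[1]]
      if (m[1] != -1L)
        for (p in m) hits[[length(hits) + 1L]] <- c(ctg, p)
    }
  }
  if (length(hits) != 1L)
    stop("tag must map uniquely: ", length(hits), " hit(s) found")
  ctg <- hits[[1]][1]
  p <- as.integer(hits[[1]][2])            # 1-based tag start
  L <- nchar(scaffolds[[ctg]])
  center <- p - 1L + nchar(tag_seq) %/% 2L # 0-based
  half <- amplicon_max %/% 2L
  start <- max(0L, center - half)
  end <- min(L, center + half)
  if (end - start < amplicon_min)
    stop("amplicon window (", end - start, " bp) shorter than amplicon_min")
  structure(list(marker_id = marker_id, scaffold_id = ctg, start = start,
                 end = end, expected_presence = expected_presence),
            class = "marker_assay")
}

#' In-silico PCR concordance between marker band calls and phenotypic sex
#'
#' For each assay, an individual shows a band when it carries the marker
#' tag above the presence threshold. Concordance is the fraction of
#' individuals whose band call matches the assay's expectation for their
#' phenotypic sex.
#'
#' @param assays list of `marker_assay` objects whose marker_id matches a
#'   row of the presence matrix (e.g. "locus12").
#' @param pm a [presence_matrix()].
#' @return list with `per_marker` (data.frame: marker_id, n_correct, n,
#'   concordance) and `confusion` (band x expected-band matrix over all
#'   assays and individuals); empty assays give empty outputs.
#' @export
insilico_pcr_concordance <- function(assays, pm) {
  if (length(assays) == 0L)
    return(list(per_marker = data.frame(marker_id = character(0),
                                        n_correct = integer(0),
                                        n = integer(0),
                                        concordance = numeric(0)),
                confusion = matrix(0L, 2, 2,
                                   dimnames = list(c("band", "no_band"),
                                                   c("band", "no_band")))))
  conf <- matrix(0L, 2, 2, dimnames = list(observed = c("band", "no_band"),
                                           expected = c("band", "no_band")))
  per <- lapply(assays, function(a) {
    row <- which(rownames(pm$present) == a$marker_id)
    if (length(row) != 1L)
      stop("assay marker ", a$marker_id, " not in presence matrix")
    band <- pm$present[row, ]
    expected <- a$expected_presence[pm$sex] == "band"
    for (i in seq_along(band)) {
      conf[ifelse(band[i], "band", "no_band"),
           ifelse(expected[i], "band", "no_band")] <<-
        conf[ifelse(band[i], "band", "no_band"),
             ifelse(expected[i], "band", "no_band")] + 1L
    }
    data.frame(marker_id = a$marker_id, n_correct = sum(band == expected),
               n = length(band), concordance = mean(band == expected),
               stringsAsFactors = FALSE)
  })
  list(per_marker = do.call(rbind, per), confusion = conf)
}

#' Assembly summary statistics for a scaffold set
#'
#' N50 is the length at which the cumulative sum of descending-sorted
#' scaffold lengths first reaches half the total.
#'
#' @param scaffolds named character vector of sequences, or a numeric
#'   vector of lengths.
#' @return list: n_scaffolds, max_length, total_length, n50,
#'   n_over_2kb.
#' @export
scaffold_stats <- function(scaffolds) {
  lens <- if (is.character(scaffolds)) nchar(scaffolds) else scaffolds
  if (length(lens) < 1L) stop("at least one scaffold required")
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  n50 <- lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
  list(n_scaffolds = length(lens), max_length = max(lens),
       total_length = sum(lens), n50 = n50,
       n_over_2kb = sum(lens > 2000))
}

#' Find open reading frames in all six frames
#'
#' An ORF is an ATG..stop span with at least `min_aa` codons of coding
#' sequence (start codon included, stop excluded); both the start and the
#' stop must lie inside the sequence. Nested starts sharing a stop are all
#' reported.
#'
#' @param sequence nucleotide string.
#' @param min_aa minimum ORF length in codons (default 50).
#' @return data.frame: start, end (0-based half-open, forward coordinates,
#'   stop codon included in the span), strand, frame (0-2), n_aa.
#' @export
find_orfs <- function(sequence, min_aa = 50L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      n_aa = integer(0))
  if (L < (min_aa + 1L) * 3L) return(empty)
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand) {
    rows <- list()
    for (frame in 0:2) {
      n_codon <- (nchar(s) - frame) %/% 3L
      if (n_codon < min_aa + 1L) next
      starts1 <- frame + (seq_len(n_codon) - 1L) * 3L + 1L
      codons <- substring(s, starts1, starts1 + 2L)
      stop_idx <- which(codons %in% stops)
      atg_idx <- which(codons == "ATG")
      for (a in atg_idx) {
        nxt <- stop_idx[stop_idx > a]
        if (length(nxt) == 0L) next
        st <- nxt[1]
        n_aa <- st - a
        if (n_aa < min_aa) next
        beg0 <- starts1[a] - 1L          # 0-based on this strand
        end0 <- starts1[st] + 2L         # incl stop codon, half-open
        if (strand == "-") {
          tmp <- L - end0
          end0 <- L - beg0
          beg0 <- tmp
        }
        rows[[length(rows) + 1L]] <- data.frame(
          start = beg0, end = end0, strand = strand, frame = frame,
          n_aa = n_aa, stringsAsFactors = FALSE)
      }
    }
    rows
  }
  rows <- c(scan_strand(sequence, "+"), scan_strand(revcomp(sequence), "-"))
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}
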