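#' Configuration for the synthetic 2b-RAD population simulator
#'
#' The defaults emulate the study design this package targets: 10 females
#' and 10 males of a ZW species genotyped by BsaXI 2b-RAD at a per-tag depth
#' around 37x, with a female-limited (W) region carrying extra tags and
#' Z/W-diverged (gametolog) SNP sites at which every female is
#' constitutively heterozygous.
#'
#' @param seed integer seed; every simulation product is a pure function of
#'   the configuration, so a fixed seed gives byte-identical outputs.
#' @param genome_length autosomal/Z contig length in bp.
#' @param n_females,n_males individuals per sex.
#' @param system "ZW" (female heterogametic), "XY" (male heterogametic) or
#'   "NONE" (no sex-linked region).
#' @param n_sex_limited_tags tags on the W (ZW) or Y (XY) contig.
#' @param n_gametolog_snps shared tags carrying one heterogametic-sex
#'   heterozygous SNP each.
#' @param n_autosomal_snps autosomal tag loci carrying one Hardy-Weinberg
#'   SNP each.
#' @param coverage_mean expected reads per haploid tag copy per individual
#'   (Poisson); a homozygous diploid locus sequences at about twice this.
#' @param error_rate per-base substitution probability in reads.
#' @param read_length sequenced read length (default 33).
#' @param core_length tag core length (default 27).
#' @param allele_freq autosomal alternative-allele frequency (default 0.5).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L, n_females = 10L,
                       n_males = 10L, system = c("ZW", "XY", "NONE"),
                       n_sex_limited_tags = 3L, n_gametolog_snps = 10L,
                       n_autosomal_snps = 200L, coverage_mean = 37,
                       error_rate = 0.01, read_length = 33L,
                       core_length = 27L, allele_freq = 0.5) {
  system <- match.arg(system)
  for (nm in c("n_females", "n_males", "n_sex_limited_tags",
               "n_gametolog_snps", "n_autosomal_snps"))
    stopifnot_scalar_count(get(nm), nm)
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)")
  if (core_length > read_length)
    stop("core_length must be <= read_length")
  if (system == "NONE" && (n_sex_limited_tags > 0 || n_gametolog_snps > 0))
    stop("system NONE cannot carry sex-limited tags or gametolog SNPs")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_females = as.integer(n_females), n_males = as.integer(n_males),
              system = system,
              n_sex_limited_tags = as.integer(n_sex_limited_tags),
              n_gametolog_snps = as.integer(n_gametolog_snps),
              n_autosomal_snps = as.integer(n_autosomal_snps),
              coverage_mean = coverage_mean, error_rate = error_rate,
              read_length = as.integer(read_length),
              core_length = as.integer(core_length),
              allele_freq = allele_freq)
  class(cfg) <- "sim_config"
  cfg
}

# random sequence with every recognition-site occurrence (both strands)
# disrupted by a point change, iterated to a fixed point
# 0-based offsets of non-wildcard motif positions (mutating one of these
# is guaranteed to break the match)
motif_fixed_offsets <- function(motif) {
  which(strsplit(motif, "")[[1]] != "N") - 1L
}

random_motif_free <- function(length, spec) {
  bases <- c("A", "C", "G", "T")
  s <- paste(sample(bases, length, replace = TRUE), collapse = "")
  pat_f <- paste0("(?=", iupac_to_regex(spec$motif), ")")
  pat_r <- paste0("(?=", iupac_to_regex(revcomp(spec$motif)), ")")
  off_f <- motif_fixed_offsets(spec$motif)
  off_r <- motif_fixed_offsets(revcomp(spec$motif))
  for (iter in 1:50) {
    hf <- gregexpr(pat_f, s, perl = TRUE)[[1]]
    hr <- gregexpr(pat_r, s, perl = TRUE)[[1]]
    hf <- hf[hf != -1L]; hr <- hr[hr != -1L]
    if (length(hf) + length(hr) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (h in hf) {
      p <- h + off_f[sample.int(length(off_f), 1L)]
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    for (h in hr) {
      p <- h + off_r[sample.int(length(off_r), 1L)]
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    s <- paste(ch, collapse = "")
  }
  stop("could not scrub recognition motifs from random sequence")
}

# instantiate the IUPAC motif (N and ambiguity codes sampled uniformly)
instantiate_motif <- function(spec) {
  paste(vapply(strsplit(spec$motif, "")[[1]], function(ch) {
    opts <- strsplit(IUPAC_CODES[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# count motif occurrences (both strands, overlapping) in a string
count_motifs <- function(s, spec) {
  pat <- paste0("(?=", iupac_to_regex(spec$motif), ")|(?=",
                iupac_to_regex(revcomp(spec$motif)), ")")
  hits <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

# disrupt motif occurrences that are not the planted forward-strand sites
# (they can arise where a planted window abuts background sequence); only
# background bases outside every planted window are touched
scrub_unplanted <- function(contig_seq, fwd_motif_starts1, window_ranges,
                            spec) {
  bases <- c("A", "C", "G", "T")
  fwd_pat <- paste0("(?=", iupac_to_regex(spec$motif), ")")
  rev_pat <- paste0("(?=", iupac_to_regex(revcomp(spec$motif)), ")")
  off_f <- motif_fixed_offsets(spec$motif)
  off_r <- motif_fixed_offsets(revcomp(spec$motif))
  in_window <- rep(FALSE, nchar(contig_seq))
  for (r in window_ranges) in_window[r[1]:r[2]] <- TRUE
  for (iter in 1:20) {
    hf <- gregexpr(fwd_pat, contig_seq, perl = TRUE)[[1]]
    hr <- gregexpr(rev_pat, contig_seq, perl = TRUE)[[1]]
    hf <- setdiff(hf[hf != -1L], fwd_motif_starts1)
    hr <- hr[hr != -1L]
    if (length(hf) + length(hr) == 0L) return(contig_seq)
    ch <- strsplit(contig_seq, "")[[1]]
    scrub_one <- function(p, offs) {
      # mutate a fixed motif position lying outside every planted window
      free <- (p + offs)[!in_window[p + offs]]
      if (length(free) == 0L) return(invisible(NULL))
      q <- free[sample.int(length(free), 1L)]
      ch[q] <<- sample(setdiff(bases, ch[q]), 1L)
    }
    for (p in hf) scrub_one(p, off_f)
    for (p in hr) scrub_one(p, off_r)
    contig_seq <- paste(ch, collapse = "")
  }
  stop("could not scrub junction motifs")
}

# one planted tag: 33-nt window with exactly one motif occurrence, plus an
# optional alternative allele differing at one non-motif core offset
make_planted_tag <- function(spec, with_snp) {
  bases <- c("A", "C", "G", "T")
  motif_chars <- strsplit(spec$motif, "")[[1]]
  fixed_off <- spec$left_core + which(motif_chars != "N") - 1L  # 0-based
  free_off <- setdiff(seq_len(spec$core_length) - 1L, fixed_off)
  for (try in 1:200) {
    core <- paste0(
      paste(sample(bases, spec$left_core, TRUE), collapse = ""),
      instantiate_motif(spec),
      paste(sample(bases, spec$right_core, TRUE), collapse = ""))
    lpad <- paste(sample(bases, spec$left_read, TRUE), collapse = "")
    rpad <- paste(sample(bases, spec$right_read, TRUE), collapse = "")
    window <- paste0(lpad, core, rpad)
    if (count_motifs(window, spec) != 1L) next
    if (!with_snp)
      return(list(core = core, window = window, snp_offset = NA_integer_,
                  ref_base = NA_character_, alt_base = NA_character_))
    off <- sample(free_off, 1L)
    ref_base <- substring(core, off + 1L, off + 1L)
    alt_base <- sample(setdiff(bases, ref_base), 1L)
    alt_core <- core
    substring(alt_core, off + 1L, off + 1L) <- alt_base
    alt_window <- paste0(lpad, alt_core, rpad)
    if (count_motifs(alt_window, spec) != 1L) next
    return(list(core = core, window = window, alt_core = alt_core,
                alt_window = alt_window, snp_offset = off,
                ref_base = ref_base, alt_base = alt_base))
  }
  stop("failed to synthesize a clean planted tag")
}

#' Simulate the reference genome of a synthetic ZW/XY population
#'
#' Builds a motif-free random autosomal/Z contig, plants tag loci (each an
#' exact recognition-site instance with 3-nt read pads and no accidental
#' second site in its window), and, for sex-linked systems, a separate
#' sex-limited (W or Y) contig carrying extra tags that the homogametic sex
#' lacks entirely. Gametolog and autosomal loci each carry one planned SNP
#' at a non-motif core offset. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param spec a [recognition_spec()].
#' @return list with `reference` (named character vector: autosome plus,
#'   when sex-linked, W or Y), `truth` (list: loci data.frame,
#'   sex_by_individual data.frame, sites BED-like data.frame), and the
#'   `config`/`spec` used.
#' @export
simulate_reference <- function(config, spec = recognition_spec()) {
  set.seed(config$seed)
  slot <- spec$read_length + 7L
  n_auto_tags <- config$n_autosomal_snps + config$n_gametolog_snps
  capacity <- (config$genome_length - 20L) %/% slot
  if (n_auto_tags > capacity)
    stop("genome_length too small for ", n_auto_tags, " tag loci (capacity ",
         capacity, ")")
  auto <- random_motif_free(config$genome_length, spec)

  plant <- function(contig_seq, n, classes, contig_name) {
    if (n == 0L)
      return(list(seq = contig_seq, loci = NULL))
    starts <- sort(sample.int((nchar(contig_seq) - 20L) %/% slot, n)) - 1L
    starts <- starts * slot + 10L   # 0-based window starts
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      tg <- make_planted_tag(spec, with_snp = classes[i] != "sex_limited")
      substring(contig_seq, starts[i] + 1L,
                starts[i] + spec$read_length) <- tg$window
      rows[[i]] <- data.frame(
        class = classes[i], contig = contig_name,
        core_start = starts[i] + spec$left_read, strand = "+",
        core_seq = tg$core,
        alt_core = if (is.na(tg$snp_offset)) NA_character_ else tg$alt_core,
        snp_offset = tg$snp_offset, ref_base = tg$ref_base,
        alt_base = tg$alt_base, stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, rows)
    contig_seq <- scrub_unplanted(
      contig_seq, loci$core_start + spec$left_core + 1L,
      lapply(starts, function(s) c(s + 1L, s + spec$read_length)), spec)
    list(seq = contig_seq, loci = loci)
  }

  classes_auto <- c(rep("gametolog", config$n_gametolog_snps),
                    rep("autosomal", config$n_autosomal_snps))
  pa <- plant(auto, n_auto_tags, classes_auto, "autosome")
  reference <- c(autosome = pa$seq)
  loci <- pa$loci

  sex_contig <- switch(config$system, ZW = "W", XY = "Y", NONE = NA)
  if (config$system != "NONE") {
    wlen <- max(1000L, config$n_sex_limited_tags * 5L * slot)
    wseq <- random_motif_free(wlen, spec)
    pw <- plant(wseq, config$n_sex_limited_tags,
                rep("sex_limited", config$n_sex_limited_tags), sex_contig)
    reference[sex_contig] <- pw$seq
    loci <- rbind(loci, pw$loci)
  }
  if (is.null(loci))
    loci <- data.frame(class = character(0), contig = character(0),
                       core_start = integer(0), strand = character(0),
                       core_seq = character(0), alt_core = character(0),
                       snp_offset = integer(0), ref_base = character(0),
                       alt_base = character(0), stringsAsFactors = FALSE)
  loci$locus_id <- seq_len(nrow(loci))
  loci <- loci[, c("locus_id", "class", "contig", "core_start", "strand",
                   "core_seq", "alt_core", "snp_offset", "ref_base",
                   "alt_base")]

  ids <- c(if (config$n_females > 0) paste0("F", seq_len(config$n_females)),
           if (config$n_males > 0) paste0("M", seq_len(config$n_males)))
  sexes <- c(rep("F", config$n_females), rep("M", config$n_males))
  truth <- list(
    loci = loci,
    sex_by_individual = data.frame(individual_id = ids, sex = sexes,
                                   stringsAsFactors = FALSE),
    sites = data.frame(contig = loci$contig, start = loci$core_start,
                       end = loci$core_start + spec$core_length,
                       name = paste0("locus", loci$locus_id), score = 0L,
                       strand = loci$strand, stringsAsFactors = FALSE))
  list(reference = reference, truth = truth, config = config, spec = spec)
}

#' Simulate diploid genotypes for every individual
#'
#' Heterogametic-sex individuals carry one copy of each sex-limited tag and
#' are heterozygous (one reference, one alternative copy) at every gametolog
#' locus; homogametic-sex individuals are homozygous reference there and
#' carry no sex-limited tags. Autosomal genotypes are drawn under
#' Hardy-Weinberg at the configured allele frequency.
#'
#' @param sim output of [simulate_reference()].
#' @return data.table with one row per individual x locus: individual, sex,
#'   locus_id, class, n_ref, n_alt (copies of each core allele; sex-limited
#'   loci use n_ref for the single-copy tag) and truth_genotype
#'   ("ref/ref", "ref/alt", "alt/alt" or "absent").
#' @export
simulate_individuals <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1000L)
  truth <- sim$truth
  loci <- truth$loci
  ind <- truth$sex_by_individual
  if (nrow(loci) == 0L || nrow(ind) == 0L)
    return(data.table::data.table(individual = character(0),
                                  sex = character(0), locus_id = integer(0),
                                  class = character(0), n_ref = integer(0),
                                  n_alt = integer(0),
                                  truth_genotype = character(0)))
  het_sex <- switch(config$system, ZW = "F", XY = "M", NONE = NA_character_)
  grid <- data.table::CJ(individual = ind$individual_id,
                         locus_id = loci$locus_id, sorted = FALSE)
  grid <- merge(grid,
                data.table::data.table(individual = ind$individual_id,
                                       sex = ind$sex),
                by = "individual", sort = FALSE)
  grid <- merge(grid,
                data.table::data.table(locus_id = loci$locus_id,
                                       class = loci$class),
                by = "locus_id", sort = FALSE)
  data.table::setorder(grid, individual, locus_id)
  n <- nrow(grid)
  n_ref <- integer(n); n_alt <- integer(n)
  is_auto <- grid$class == "autosomal"
  n_alt[is_auto] <- stats::rbinom(sum(is_auto), 2L, config$allele_freq)
  n_ref[is_auto] <- 2L - n_alt[is_auto]
  is_gam <- grid$class == "gametolog"
  hetero <- !is.na(het_sex) & grid$sex == het_sex
  n_ref[is_gam] <- ifelse(hetero[is_gam], 1L, 2L)
  n_alt[is_gam] <- ifelse(hetero[is_gam], 1L, 0L)
  is_sl <- grid$class == "sex_limited"
  n_ref[is_sl] <- ifelse(hetero[is_sl], 1L, 0L)
  grid$n_ref <- n_ref
  grid$n_alt <- n_alt
  grid$truth_genotype <- ifelse(
    n_ref + n_alt == 0L, "absent",
    ifelse(n_alt == 0L, "ref/ref",
           ifelse(n_ref == 0L, "alt/alt", "ref/alt")))
  grid[]
}

# vectorised substitution errors at iid per-base rate; reads equal length
inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  w <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), w, rate)
  idx <- which(nerr > 0L)
  if (length(idx) == 0L) return(reads)
  mat <- seq_matrix(reads[idx])
  rows <- rep(seq_along(idx), nerr[idx])
  cols <- sample.int(w, length(rows), replace = TRUE)
  cells <- cbind(rows, cols)
  bases <- c("A", "C", "G", "T")
  cur <- match(mat[cells], bases) - 1L
  mat[cells] <- bases[((cur + sample.int(3L, length(rows),
                                         replace = TRUE)) %% 4L) + 1L]
  reads[idx] <- apply(mat, 1L, paste, collapse = "")
  reads
}

#' Simulate per-individual 2b-RAD reads
#'
#' Each haploid tag copy an individual carries yields a Poisson
#' (`coverage_mean`) number of 33-nt reads (3-nt pad + 27-nt core + 3-nt
#' pad, taken from the planted reference window, with the allele's SNP base
#' substituted for alternative copies). Reads get iid substitution errors
#' at `error_rate`, a random strand, and constant Phred+33 'I' qualities.
#'
#' @param sim output of [simulate_reference()].
#' @param genotypes output of [simulate_individuals()].
#' @return named list: individual -> character vector of reads.
#' @export
simulate_reads <- function(sim, genotypes) {
  config <- sim$config
  spec <- sim$spec
  set.seed(config$seed + 2000L)
  loci <- sim$truth$loci
  windows_ref <- character(nrow(loci))
  windows_alt <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    ctg <- sim$reference[[loci$contig[i]]]
    ws <- loci$core_start[i] - spec$left_read
    windows_ref[i] <- substring(ctg, ws + 1L, ws + spec$read_length)
    if (!is.na(loci$alt_core[i])) {
      w <- windows_ref[i]
      substring(w, spec$left_read + loci$snp_offset[i] + 1L,
                spec$left_read + loci$snp_offset[i] + 1L) <- loci$alt_base[i]
      windows_alt[i] <- w
    }
  }
  inds <- sim$truth$sex_by_individual$individual_id
  out <- vector("list", length(inds))
  names(out) <- inds
  for (ind in inds) {
    g <- genotypes[genotypes$individual == ind, ]
    li <- match(g$locus_id, loci$locus_id)
    n_ref_reads <- stats::rpois(nrow(g), g$n_ref * config$coverage_mean)
    n_alt_reads <- stats::rpois(nrow(g), g$n_alt * config$coverage_mean)
    reads <- c(rep(windows_ref[li], n_ref_reads),
               rep(windows_alt[li], n_alt_reads))
    reads <- inject_errors(reads, config$error_rate)
    if (length(reads) > 0L) {
      flip <- stats::runif(length(reads)) < 0.5
      reads[flip] <- revcomp(reads[flip])
    }
    out[[ind]] <- reads
  }
  out
}

#' Simulate whole-genome shotgun reads from haplotype sequences
#'
#' Uniform random start positions, each supplied haplotype sequenced at
#' `coverage`, optional iid substitution errors and random strand. Used for
#' the k-mer genome-survey path, which works on shotgun rather than
#' restriction-tag reads.
#'
#' @param haplotypes character vector of haplotype sequences.
#' @param coverage expected depth per haplotype.
#' @param read_length read length (default 100).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed optional integer seed.
#' @return character vector of reads.
#' @export
simulate_shotgun_reads <- function(haplotypes, coverage, read_length = 100L,
                                   error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reads <- unlist(lapply(haplotypes, function(h) {
    L <- nchar(h)
    if (L < read_length) return(character(0))
    n <- round(coverage * L / read_length)
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    substring(h, starts, starts + read_length - 1L)
  }), use.names = FALSE)
  reads <- inject_errors(reads, error_rate)
  if (length(reads) > 0L) {
    flip <- stats::runif(length(reads)) < 0.5
    reads[flip] <- revcomp(reads[flip])
  }
  reads
}

#' Derive a diverged haplotype by planting SNPs at a given per-base rate
#'
#' @param seq a nucleotide string.
#' @param rate per-base substitution probability.
#' @param seed optional seed.
#' @return list with `seq` (the diverged haplotype) and `positions`
#'   (1-based substituted positions).
#' @export
mutate_haplotype <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- which(stats::runif(length(ch)) < rate)
  bases <- c("A", "C", "G", "T")
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  list(seq = paste(ch, collapse = ""), positions = pos)
}

#' Write a complete simulation to disk
#'
#' Emits the reference FASTA (60-column wrapped), one FASTQ per individual
#' (Phred+33, constant 'I'), a sample sheet TSV, the truth-locus TSV and a
#' BED6 of planted sites.
#'
#' @param sim output of [simulate_reference()].
#' @param reads output of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  for (ind in names(reads))
    write_fastq(reads[[ind]], file.path(dir, paste0(ind, ".fastq")),
                ids = paste0(ind, "_read", seq_along(reads[[ind]])))
  write_tsv(sim$truth$sex_by_individual, file.path(dir, "samples.tsv"))
  write_tsv(sim$truth$loci, file.path(dir, "truth_loci.tsv"))
  utils::write.table(sim$truth$sites, file.path(dir, "planted_sites.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}
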