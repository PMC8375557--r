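#' Presence/absence matrix of tag loci across individuals
#'
#' A locus is present in an individual when its total read depth reaches
#' `min_locus_depth` (default 3, the depth below which a tag sequence is
#' precluded from analysis).
#'
#' @param catalog a `tag_catalog` from [build_catalog()], or a depth
#'   data.frame (locus_id, individual, depth).
#' @param samples sample sheet data.frame (individual_id, sex).
#' @param min_locus_depth presence threshold (default 3).
#' @return object of class `presence_matrix`: list with `depth` (loci x
#'   individuals numeric matrix), `present` (logical matrix), `sex` (named
#'   character vector aligned to columns), `min_locus_depth`.
#' @export
presence_matrix <- function(catalog, samples, min_locus_depth = 3L) {
  locus_id <- individual <- depth <- NULL
  d <- if (inherits(catalog, "tag_catalog"))
    catalog$depths[, list(depth = sum(depth)),
                   by = list(locus_id, individual)]
  else data.table::as.data.table(catalog)
  inds <- samples$individual_id
  loci <- sort(unique(d$locus_id))
  m <- matrix(0, nrow = length(loci), ncol = length(inds),
              dimnames = list(paste0("locus", loci), inds))
  keep <- d$individual %in% inds
  d <- d[keep]
  m[cbind(match(d$locus_id, loci), match(d$individual, inds))] <- d$depth
  sex <- structure(samples$sex, names = inds)
  structure(list(depth = m, present = m >= min_locus_depth, sex = sex,
                 locus_id = loci, min_locus_depth = min_locus_depth),
            class = "presence_matrix")
}

#' Screen tag loci for sex-specific presence
#'
#' A tag is called female-specific when present in at least
#' `min_present_fraction` of females and in at most
#' `max_absent_sex_presence` males (and symmetrically male-specific). Every
#' locus also gets a two-sided Fisher exact p-value from its presence 2x2
#' table. With the strict defaults (all of one sex, none of the other) this
#' is the presence criterion used to nominate candidate sex markers.
#'
#' @param pm a [presence_matrix()].
#' @param min_present_fraction minimum fraction of the carrying sex that
#'   must show the tag (default 1.0).
#' @param max_absent_sex_presence maximum individuals of the other sex
#'   allowed to show it (default 0).
#' @return data.frame sorted by p then marker_id: marker_id, marker_type,
#'   pattern (female_specific / male_specific / uninformative), p_value,
#'   p_bonferroni, p_bh, n_female_present, n_female, n_male_present,
#'   n_male.
#' @export
find_sex_specific_tags <- function(pm, min_present_fraction = 1.0,
                                   max_absent_sex_presence = 0L) {
  is_f <- pm$sex == "F"
  n_f <- sum(is_f); n_m <- sum(!is_f)
  if (n_f == 0L || n_m == 0L)
    stop("both sexes must be represented in the sample sheet")
  fp <- rowSums(pm$present[, is_f, drop = FALSE])
  mp <- rowSums(pm$present[, !is_f, drop = FALSE])
  pattern <- rep("uninformative", length(fp))
  pattern[fp >= min_present_fraction * n_f &
            mp <= max_absent_sex_presence] <- "female_specific"
  pattern[mp >= min_present_fraction * n_m &
            fp <= max_absent_sex_presence] <- "male_specific"
  p <- vapply(seq_along(fp), function(i)
    fisher_exact_2x2(matrix(c(fp[i], n_f - fp[i], mp[i], n_m - mp[i]),
                            2, 2, byrow = TRUE)), numeric(1))
  out <- data.frame(marker_id = paste0("locus", pm$locus_id),
                    marker_type = "tag", pattern = pattern, p_value = p,
                    p_bonferroni = stats::p.adjust(p, "bonferroni"),
                    p_bh = stats::p.adjust(p, "BH"),
                    n_female_present = fp, n_female = n_f,
                    n_male_present = mp, n_male = n_m,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$marker_id), ]
  rownames(out) <- NULL
  out
}

#' Classify the joint genotype pattern of a SNP across the sexes
#'
#' female_heterogametic: every non-absent female heterozygous and every
#' non-absent male homozygous for one shared allele (the Z/W gametolog
#' signature of a ZW system); male_heterogametic is the mirror;
#' fixed_difference: both sexes homozygous but for different alleles;
#' anything else is uninformative.
#'
#' @param female_gts,male_gts character vectors of genotype strings
#'   ("A/G"; NA = no call, dropped).
#' @return one of "female_heterogametic", "male_heterogametic",
#'   "fixed_difference", "uninformative".
#' @export
classify_pattern <- function(female_gts, male_gts) {
  fg <- female_gts[!is.na(female_gts)]
  mg <- male_gts[!is.na(male_gts)]
  if (length(fg) == 0L || length(mg) == 0L) return("uninformative")
  split_gt <- function(g) strsplit(g, "/", fixed = TRUE)
  is_het <- function(g) vapply(split_gt(g), function(a)
    length(unique(a)) == 2L, logical(1))
  hom_allele <- function(g) vapply(split_gt(g), `[`, character(1), 1L)
  f_het <- is_het(fg); m_het <- is_het(mg)
  if (all(f_het) && all(!m_het) && length(unique(hom_allele(mg))) == 1L)
    return("female_heterogametic")
  if (all(m_het) && all(!f_het) && length(unique(hom_allele(fg))) == 1L)
    return("male_heterogametic")
  if (all(!f_het) && all(!m_het)) {
    fa <- unique(hom_allele(fg)); ma <- unique(hom_allele(mg))
    if (length(fa) == 1L && length(ma) == 1L && fa != ma)
      return("fixed_difference")
  }
  "uninformative"
}

#' Test every SNP for association with sex
#'
#' The default model dichotomizes each genotype call as heterozygous vs
#' homozygous and tests the 2x2 (het/hom x female/male) table with the
#' two-sided Fisher exact test; the allele_count model tests the 2x2 allele
#' (ref/alt x sex) table instead. Absent calls are dropped per marker.
#' Results are ranked by ascending p with lexicographic marker_id
#' tie-break; monomorphic markers report p = 1.
#'
#' @param snp_table output of [call_snps()] (or any data.frame with
#'   marker_id and one genotype column per individual).
#' @param sexes named character vector individual -> "F"/"M".
#' @param model "genotype_het_vs_hom" (default) or "allele_count".
#' @param top_n optionally return only the best n markers.
#' @return data.frame: marker_id, marker_type, pattern, p_value,
#'   p_bonferroni, p_bh, rank, and the per-sex het/hom counts used.
#' @export
snp_sex_association <- function(snp_table, sexes,
                                model = c("genotype_het_vs_hom",
                                          "allele_count"),
                                top_n = NULL) {
  model <- match.arg(model)
  snp_table <- as.data.frame(snp_table)
  inds <- intersect(names(sexes), names(snp_table))
  if (length(inds) < 2L)
    stop("snp_table has no genotype columns matching names(sexes)")
  f_ind <- inds[sexes[inds] == "F"]
  m_ind <- inds[sexes[inds] == "M"]
  n <- nrow(snp_table)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    fg <- unlist(snp_table[i, f_ind, drop = TRUE], use.names = FALSE)
    mg <- unlist(snp_table[i, m_ind, drop = TRUE], use.names = FALSE)
    fg_ok <- fg[!is.na(fg)]; mg_ok <- mg[!is.na(mg)]
    het <- function(g) vapply(strsplit(g, "/", fixed = TRUE), function(a)
      length(unique(a)) == 2L, logical(1))
    f_het <- sum(het(fg_ok)); m_het <- sum(het(mg_ok))
    f_hom <- length(fg_ok) - f_het; m_hom <- length(mg_ok) - m_het
    all_gt <- c(fg_ok, mg_ok)
    mono <- length(unique(all_gt)) <= 1L
    p <- if (mono) 1 else if (model == "genotype_het_vs_hom")
      fisher_exact_2x2(matrix(c(f_het, f_hom, m_het, m_hom), 2, 2,
                              byrow = TRUE))
    else {
      alleles <- unlist(strsplit(all_gt, "/", fixed = TRUE))
      ref <- snp_table$ref_base[i] %||% names(sort(-table(alleles)))[1]
      cnt <- function(g) {
        a <- unlist(strsplit(g, "/", fixed = TRUE))
        c(sum(a == ref), sum(a != ref))
      }
      fisher_exact_2x2(matrix(c(cnt(fg_ok), cnt(mg_ok)), 2, 2,
                              byrow = TRUE))
    }
    res[[i]] <- data.frame(
      marker_id = snp_table$marker_id[i], marker_type = "snp",
      pattern = if (mono) "uninformative" else classify_pattern(fg, mg),
      p_value = p, f_het = f_het, f_hom = f_hom, m_het = m_het,
      m_hom = m_hom, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_bonferroni <- stats::p.adjust(out$p_value, "bonferroni")
  out$p_bh <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$marker_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Infer the heterogametic system from screened markers
#'
#' ZW requires strictly more female-specific than male-specific tags AND at
#' least as many female-heterogametic as male-heterogametic patterns among
#' the top-ranked SNPs; XY is the mirror; anything else (including no
#' candidates at all) is undetermined.
#'
#' @param tag_results output of [find_sex_specific_tags()].
#' @param snp_results output of [snp_sex_association()].
#' @param top_n SNP ranks considered (default 10).
#' @return object of class `system_inference`: list with `call` ("ZW",
#'   "XY" or "undetermined") and `evidence` (named counts).
#' @export
infer_system <- function(tag_results, snp_results, top_n = 10L) {
  n_fs <- sum(tag_results$pattern == "female_specific")
  n_ms <- sum(tag_results$pattern == "male_specific")
  top <- utils::head(snp_results, top_n)
  n_fh <- sum(top$pattern == "female_heterogametic")
  n_mh <- sum(top$pattern == "male_heterogametic")
  call <- "undetermined"
  if ((n_fs + n_ms + n_fh + n_mh) > 0L) {
    if (n_fs > n_ms && n_fh >= n_mh) call <- "ZW"
    else if (n_ms > n_fs && n_mh >= n_fh) call <- "XY"
  }
  structure(list(call = call,
                 evidence = c(female_specific_tags = n_fs,
                              male_specific_tags = n_ms,
                              female_het_snps = n_fh,
                              male_het_snps = n_mh)),
            class = "system_inference")
}
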