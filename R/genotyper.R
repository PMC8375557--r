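#' Cluster clean tag cores into a locus catalog
#'
#' Exact-identical sequences collapse first; each remaining sequence joins
#' the locus of the nearest more-abundant founder sequence within
#' `max_mismatch` substitutions (ties broken towards the more abundant,
#' earlier-founded locus), or founds a new locus. Assignment order is by
#' descending total abundance across individuals, then lexicographic
#' sequence, so the catalog is invariant to input order. Candidate loci are
#' found with a pigeonhole chunk index (a sequence within m mismatches of a
#' founder must share at least one of m+1 equal-length chunks exactly), so
#' clustering stays near-linear in the number of distinct sequences.
#'
#' @param cores_by_individual named list: individual -> character vector of
#'   canonical core sequences (one entry per read).
#' @param max_mismatch maximum substitutions between an allele and its locus
#'   consensus (default 2).
#' @param core_length core length (default 27).
#' @return object of class `tag_catalog`: list with
#'   `loci` (data.table: locus_id, consensus, n_alleles, total_depth,
#'   multiallelic), `alleles` (data.table: locus_id, allele_seq, depth,
#'   mismatches), and `depths` (data.table: locus_id, individual,
#'   allele_seq, depth).
#' @export
build_catalog <- function(cores_by_individual, max_mismatch = 2L,
                          core_length = 27L) {
  individual <- allele_seq <- depth <- locus_id <- NULL  # R CMD check
  dt <- data.table::rbindlist(lapply(names(cores_by_individual), function(i)
    data.table::data.table(individual = i,
                           allele_seq = cores_by_individual[[i]])))
  if (is.null(dt) || nrow(dt) == 0L) {
    return(structure(list(
      loci = data.table::data.table(locus_id = integer(0),
                                    consensus = character(0),
                                    n_alleles = integer(0),
                                    total_depth = integer(0),
                                    multiallelic = logical(0)),
      alleles = data.table::data.table(locus_id = integer(0),
                                       allele_seq = character(0),
                                       depth = integer(0),
                                       mismatches = integer(0)),
      depths = data.table::data.table(locus_id = integer(0),
                                      individual = character(0),
                                      allele_seq = character(0),
                                      depth = integer(0)),
      max_mismatch = max_mismatch), class = "tag_catalog"))
  }
  agg <- dt[, list(depth = .N), by = allele_seq]
  data.table::setorder(agg, -depth, allele_seq)
  seqs <- agg$allele_seq
  n_chunks <- max_mismatch + 1L
  chunk_w <- core_length %/% n_chunks
  chunk_starts <- (seq_len(n_chunks) - 1L) * chunk_w + 1L
  chunk_ends <- c(chunk_starts[-1L] - 1L, core_length)

  # tags are double-stranded: a variant can flip the lexicographic
  # canonical orientation, so each sequence is compared to the founder in
  # both orientations and stored in the founder's frame
  seqs_rc <- revcomp(seqs)
  codes <- matrix(seq_to_codes(paste(seqs, collapse = "")),
                  nrow = core_length)
  codes_rc <- matrix(seq_to_codes(paste(seqs_rc, collapse = "")),
                     nrow = core_length)
  # consensus matrix grows column-wise; index chunks in a hashed env
  consmat <- matrix(0L, nrow = core_length, ncol = 0L)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  assign_locus <- integer(length(seqs))
  oriented <- character(length(seqs))
  mism <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    q <- codes[, i]; qr <- codes_rc[, i]
    keys <- unique(c(
      paste0(seq_len(n_chunks), ":",
             substring(seqs[i], chunk_starts, chunk_ends)),
      paste0(seq_len(n_chunks), ":",
             substring(seqs_rc[i], chunk_starts, chunk_ends))))
    cand <- unique(unlist(lapply(keys, function(k)
      get0(k, envir = idx, ifnotfound = NULL)), use.names = FALSE))
    loc <- 0L
    if (length(cand) > 0L) {
      d_f <- hamming_to_all(q, consmat[, cand, drop = FALSE])
      d_r <- hamming_to_all(qr, consmat[, cand, drop = FALSE])
      d <- pmin(d_f, d_r)
      ok <- d <= max_mismatch
      if (any(ok)) {
        pick <- which(ok)[order(d[ok], cand[ok])][1]
        loc <- cand[pick]
        if (d_f[pick] <= d_r[pick]) {
          oriented[i] <- seqs[i]; mism[i] <- d_f[pick]
        } else {
          oriented[i] <- seqs_rc[i]; mism[i] <- d_r[pick]
        }
      }
    }
    if (loc == 0L) {
      consmat <- cbind(consmat, q)
      loc <- ncol(consmat)
      oriented[i] <- seqs[i]; mism[i] <- 0L
      for (k in paste0(seq_len(n_chunks), ":",
                       substring(seqs[i], chunk_starts, chunk_ends)))
        assign(k, c(get0(k, envir = idx, ifnotfound = integer(0)), loc),
               envir = idx)
    }
    assign_locus[i] <- loc
  }
  agg$locus_id <- assign_locus
  agg$oriented_seq <- oriented
  agg$mismatches <- mism

  dt <- merge(dt, agg[, c("allele_seq", "locus_id", "oriented_seq")],
              by = "allele_seq", sort = FALSE)
  dt$allele_seq <- dt$oriented_seq
  depths <- dt[, list(depth = .N), by = list(locus_id, individual,
                                             allele_seq)]
  data.table::setorder(depths, locus_id, individual, -depth, allele_seq)
  alleles <- data.table::data.table(locus_id = agg$locus_id,
                                    allele_seq = agg$oriented_seq,
                                    depth = agg$depth,
                                    mismatches = agg$mismatches)
  data.table::setorder(alleles, locus_id, -depth, allele_seq)
  loci <- alleles[, list(consensus = allele_seq[1L], n_alleles = .N,
                         total_depth = sum(depth)), by = locus_id]
  loci$multiallelic <- FALSE  # set during SNP calling from called alleles
  data.table::setorder(loci, locus_id)
  structure(list(loci = loci, alleles = alleles, depths = depths,
                 max_mismatch = max_mismatch), class = "tag_catalog")
}

#' Call one genotype from per-allele read depths
#'
#' Depth-threshold caller: absent below `min_locus_depth` total reads; a
#' heterozygote requires the second allele to reach `min_allele_depth` reads
#' and a minor-allele fraction strictly above `max_hom_minor_fraction`;
#' otherwise homozygous for the major allele. Ties in depth break
#' lexicographically, so the call is deterministic.
#'
#' @param allele_depths named integer vector: allele sequence (or base) ->
#'   read depth.
#' @param min_locus_depth minimum total reads to call a locus present
#'   (default 3).
#' @param min_allele_depth minimum reads supporting a second allele
#'   (default 2).
#' @param max_hom_minor_fraction minor fractions at or below this are
#'   treated as noise within a homozygote (default 0.1).
#' @return list with `call` ("absent", "hom" or "het"), `alleles`
#'   (character, length 0/1/2), `total_depth`, `allele_depths`.
#' @export
call_genotype <- function(allele_depths, min_locus_depth = 3L,
                          min_allele_depth = 2L,
                          max_hom_minor_fraction = 0.1) {
  total <- sum(allele_depths)
  if (total < min_locus_depth)
    return(list(call = "absent", alleles = character(0), total_depth = total,
                allele_depths = allele_depths))
  ord <- order(-allele_depths, names(allele_depths))
  ad <- allele_depths[ord]
  if (length(ad) >= 2L && ad[2] >= min_allele_depth &&
      ad[2] / total > max_hom_minor_fraction) {
    al <- sort(names(ad)[1:2])
    return(list(call = "het", alleles = al, total_depth = total,
                allele_depths = allele_depths))
  }
  list(call = "hom", alleles = names(ad)[1], total_depth = total,
       allele_depths = allele_depths)
}

#' Genotype every locus in every individual
#'
#' Applies [call_genotype()] across the catalog depth table. Individuals
#' with no reads at a locus are reported absent with depth 0.
#'
#' @param catalog a `tag_catalog` from [build_catalog()].
#' @param individuals character vector of all individuals to report
#'   (defaults to those seen in the catalog).
#' @inheritParams call_genotype
#' @return data.table: locus_id, individual, call, allele1, allele2 (NA
#'   unless het), total_depth.
#' @export
genotype_catalog <- function(catalog, individuals = NULL,
                             min_locus_depth = 3L, min_allele_depth = 2L,
                             max_hom_minor_fraction = 0.1) {
  locus_id <- individual <- allele_seq <- depth <- NULL
  d <- catalog$depths
  if (is.null(individuals))
    individuals <- sort(unique(d$individual))
  calls <- d[, {
    dep <- depth; names(dep) <- allele_seq
    g <- call_genotype(dep, min_locus_depth, min_allele_depth,
                       max_hom_minor_fraction)
    list(call = g$call,
         allele1 = if (length(g$alleles) >= 1L) g$alleles[1] else NA_character_,
         allele2 = if (length(g$alleles) == 2L) g$alleles[2] else NA_character_,
         total_depth = g$total_depth)
  }, by = list(locus_id, individual)]
  # absent individuals (no reads at all at the locus)
  grid <- data.table::CJ(locus_id = catalog$loci$locus_id,
                         individual = individuals)
  calls <- merge(grid, calls, by = c("locus_id", "individual"),
                 all.x = TRUE)
  calls[is.na(calls$call), `:=`(call = "absent", total_depth = 0L)]
  data.table::setorder(calls, locus_id, individual)
  calls[]
}

#' Build the SNP table from genotyped loci
#'
#' For each locus, alleles supported by at least one hom or het call define
#' the polymorphism. Loci with exactly two called alleles yield one row per
#' position at which the alleles differ; loci with more than two called
#' alleles are flagged multiallelic and excluded. Positions are reported
#' 1-based; the reference base is that of the deeper (major) allele.
#'
#' @param catalog a `tag_catalog`.
#' @param genotypes output of [genotype_catalog()].
#' @return data.table: marker_id (locus:pos), locus_id, snp_position
#'   (1-based), ref_base, alt_base, and one genotype column per individual
#'   ("A/G" style, NA when absent). The excluded multiallelic locus ids are
#'   in attribute `multiallelic_loci`.
#' @export
call_snps <- function(catalog, genotypes) {
  locus_id <- NULL
  individuals <- sort(unique(genotypes$individual))
  rows <- list()
  multi <- integer(0)
  gt_split <- split(genotypes, genotypes$locus_id)
  allele_depth <- catalog$alleles
  for (loc_chr in names(gt_split)) {
    g <- gt_split[[loc_chr]]
    loc <- as.integer(loc_chr)
    called <- g[g$call != "absent", ]
    if (nrow(called) == 0L) next
    al <- unique(stats::na.omit(c(called$allele1, called$allele2)))
    if (length(al) < 2L) next       # monomorphic
    if (length(al) > 2L) { multi <- c(multi, loc); next }
    ad <- allele_depth[locus_id == loc]
    dep <- structure(ad$depth, names = ad$allele_seq)[al]
    dep[is.na(dep)] <- 0L
    major <- al[order(-dep, al)][1]
    minor <- setdiff(al, major)
    a1 <- strsplit(major, "")[[1]]
    a2 <- strsplit(minor, "")[[1]]
    pos <- which(a1 != a2)
    for (p in pos) {
      gt <- vapply(individuals, function(ind) {
        gi <- called[called$individual == ind, ]
        if (nrow(gi) == 0L) return(NA_character_)
        if (gi$call == "hom") {
          b <- substring(gi$allele1, p, p)
          paste0(b, "/", b)
        } else {
          b1 <- substring(gi$allele1, p, p)
          b2 <- substring(gi$allele2, p, p)
          # emit ref base first when present
          if (b2 == substring(major, p, p)) paste0(b2, "/", b1)
          else paste0(b1, "/", b2)
        }
      }, character(1))
      row <- data.table::data.table(
        marker_id = sprintf("locus%d:%d", loc, p),
        locus_id = loc, snp_position = p,
        ref_base = substring(major, p, p),
        alt_base = substring(minor, p, p))
      for (ind in individuals) row[[ind]] <- gt[[ind]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows) > 0L) data.table::rbindlist(rows) else
    data.table::data.table(marker_id = character(0), locus_id = integer(0),
                           snp_position = integer(0), ref_base = character(0),
                           alt_base = character(0))
  data.table::setorder(out, locus_id, snp_position)
  attr(out, "multiallelic_loci") <- multi
  out
}
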