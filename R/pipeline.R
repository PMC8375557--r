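#' Run the full sex-marker discovery pipeline on a simulated population
#'
#' Chains the synthetic-data generator and every analysis stage: simulate a
#' population, QC and trim the reads, cluster the tag catalog, genotype,
#' call SNPs, build the presence matrix, screen tags and SNPs for sex
#' association, and infer the heterogametic system.
#'
#' @param config a [sim_config()].
#' @param spec a [recognition_spec()].
#' @param qc a [qc_params()].
#' @param min_locus_depth,min_allele_depth,max_hom_minor_fraction genotype
#'   caller thresholds (see [call_genotype()]).
#' @param max_mismatch catalog clustering radius (see [build_catalog()]).
#' @param top_n SNP ranks used for system inference.
#' @return list with every intermediate: sim, genotypes_truth, reads, qc,
#'   catalog, genotypes, snps, pm, tag_results, snp_results, inference,
#'   truth_loci (truth loci annotated with their catalog locus_id).
#' @export
run_sex_pipeline <- function(config, spec = recognition_spec(),
                             qc = qc_params(), min_locus_depth = 3L,
                             min_allele_depth = 2L,
                             max_hom_minor_fraction = 0.1,
                             max_mismatch = 2L, top_n = 10L) {
  sim <- simulate_reference(config, spec)
  genotypes_truth <- simulate_individuals(sim)
  reads <- simulate_reads(sim, genotypes_truth)
  samples <- sim$truth$sex_by_individual
  qcres <- run_qc(reads, samples, qc, spec)
  catalog <- build_catalog(qcres$cores, max_mismatch = max_mismatch,
                           core_length = spec$core_length)
  genotypes <- genotype_catalog(catalog,
                                individuals = samples$individual_id,
                                min_locus_depth = min_locus_depth,
                                min_allele_depth = min_allele_depth,
                                max_hom_minor_fraction =
                                  max_hom_minor_fraction)
  snps <- call_snps(catalog, genotypes)
  pm <- presence_matrix(catalog, samples, min_locus_depth)
  tag_results <- find_sex_specific_tags(pm)
  sexes <- structure(samples$sex, names = samples$individual_id)
  snp_results <- if (nrow(snps) > 0L)
    snp_sex_association(snps, sexes) else NULL
  inference <- infer_system(tag_results,
                            snp_results %||%
                              data.frame(pattern = character(0)), top_n)
  truth_loci <- match_truth_loci(sim$truth$loci, catalog,
                                 spec$core_length)
  list(sim = sim, genotypes_truth = genotypes_truth, reads = reads,
       qc = qcres, catalog = catalog, genotypes = genotypes, snps = snps,
       pm = pm, tag_results = tag_results, snp_results = snp_results,
       inference = inference, truth_loci = truth_loci)
}

#' Match planted truth loci to catalog loci by canonical core sequence
#'
#' @param truth_loci truth loci data.frame from [simulate_reference()].
#' @param catalog a `tag_catalog`.
#' @param core_length core length (default 27).
#' @return the truth table with a `catalog_locus_id` column (NA when the
#'   planted core was never sequenced/retained).
#' @export
match_truth_loci <- function(truth_loci, catalog, core_length = 27L) {
  if (nrow(truth_loci) == 0L) {
    truth_loci$catalog_locus_id <- integer(0)
    return(truth_loci)
  }
  canon <- canonicalize(truth_loci$core_seq, core_length)
  al <- catalog$alleles
  al_canon <- canonicalize(al$allele_seq, core_length)
  truth_loci$catalog_locus_id <- al$locus_id[match(canon, al_canon)]
  truth_loci
}

#' Compare called genotypes with simulation truth
#'
#' Scores calls at planted loci only: a call is correct when its allele
#' content matches the planted genotype (ref/ref, ref/alt, alt/alt, or
#' absent for loci the individual does not carry).
#'
#' @param pipeline output of [run_sex_pipeline()].
#' @return list with `accuracy` (fraction correct over individuals x
#'   planted loci) and `calls` (the merged per-call table).
#' @export
genotype_accuracy <- function(pipeline) {
  truth <- pipeline$truth_loci
  gt <- pipeline$genotypes_truth
  calls <- pipeline$genotypes
  m <- merge(
    data.table::as.data.table(gt)[, c("individual", "locus_id",
                                      "truth_genotype")],
    data.table::data.table(locus_id = truth$locus_id,
                           catalog_locus_id = truth$catalog_locus_id,
                           ref_core = truth$core_seq,
                           alt_core = truth$alt_core),
    by = "locus_id")
  m <- merge(m, calls, by.x = c("catalog_locus_id", "individual"),
             by.y = c("locus_id", "individual"), all.x = TRUE)
  m$call[is.na(m$call)] <- "absent"
  w <- nchar(m$ref_core[1])
  canon_na <- function(x) {
    out <- x
    out[!is.na(x)] <- canonicalize(x[!is.na(x)], w)
    out
  }
  ref_c <- canon_na(m$ref_core)
  alt_c <- canon_na(m$alt_core)
  a1 <- canon_na(m$allele1)
  a2 <- canon_na(m$allele2)
  called_gt <- ifelse(
    m$call == "absent", "absent",
    ifelse(m$call == "hom",
           ifelse(a1 == ref_c, "ref/ref",
                  ifelse(!is.na(alt_c) & a1 == alt_c, "alt/alt", "other")),
           ifelse(!is.na(alt_c) &
                    ((a1 == ref_c & a2 == alt_c) |
                       (a1 == alt_c & a2 == ref_c)),
                  "ref/alt", "other")))
  ok <- called_gt == m$truth_genotype
  list(accuracy = mean(ok), calls = cbind(m, called_gt = called_gt,
                                          correct = ok))
}
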