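# Shared, lazily-built pipeline runs so several test files can interrogate
# the same simulation without paying for it repeatedly.

.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(key, config) {
  if (!exists(key, envir = .pipeline_cache))
    assign(key, run_sex_pipeline(config), envir = .pipeline_cache)
  get(key, envir = .pipeline_cache)
}

# the reference ZW study-design run: 10 F + 10 M, 100 kb, 3 W tags,
# 10 gametolog SNPs, 200 autosomal SNP loci, 30x per copy, 1% error
zw_study_pipeline <- function() {
  cached_pipeline("zw", sim_config(
    seed = 42L, genome_length = 100000L, n_females = 10L, n_males = 10L,
    system = "ZW", n_sex_limited_tags = 3L, n_gametolog_snps = 10L,
    n_autosomal_snps = 200L, coverage_mean = 30, error_rate = 0.01))
}

xy_study_pipeline <- function() {
  cached_pipeline("xy", sim_config(
    seed = 42L, genome_length = 100000L, n_females = 10L, n_males = 10L,
    system = "XY", n_sex_limited_tags = 3L, n_gametolog_snps = 10L,
    n_autosomal_snps = 200L, coverage_mean = 30, error_rate = 0.01))
}

# small error-free ZW run for exact-recovery checks
zw_clean_pipeline <- function() {
  cached_pipeline("zw_clean", sim_config(
    seed = 7L, genome_length = 30000L, n_females = 6L, n_males = 6L,
    system = "ZW", n_sex_limited_tags = 2L, n_gametolog_snps = 4L,
    n_autosomal_snps = 30L, coverage_mean = 20, error_rate = 0))
}

# helper: catalog locus ids of truth loci of a class
truth_catalog_ids <- function(pl, cls) {
  pl$truth_loci$catalog_locus_id[pl$truth_loci$class == cls]
}

# 38 F + 57 M breeding/wild-analog population with 3 W-linked tags, used
# for the in-silico sexing concordance checks
concordance_population <- function() {
  if (!exists("conc_pop", envir = .pipeline_cache)) {
    cfg <- sim_config(seed = 12L, genome_length = 15000L, n_females = 38L,
                      n_males = 57L, system = "ZW", n_sex_limited_tags = 3L,
                      n_gametolog_snps = 0L, n_autosomal_snps = 20L,
                      coverage_mean = 20, error_rate = 0.01)
    sim <- simulate_reference(cfg)
    gt <- simulate_individuals(sim)
    reads <- simulate_reads(sim, gt)
    qcres <- run_qc(reads, sim$truth$sex_by_individual)
    cat_ <- build_catalog(qcres$cores)
    pm <- presence_matrix(cat_, sim$truth$sex_by_individual)
    truth <- match_truth_loci(sim$truth$loci, cat_)
    w <- truth[truth$class == "sex_limited", ]
    assays <- lapply(seq_len(nrow(w)), function(i)
      extract_flanks(sim$reference, w$core_seq[i],
                     marker_id = paste0("locus", w$catalog_locus_id[i]),
                     amplicon_min = 100L, amplicon_max = 600L))
    conc <- insilico_pcr_concordance(assays, pm)
    assign("conc_pop", list(sim = sim, pm = pm, truth = truth,
                            assays = assays, conc = conc),
           envir = .pipeline_cache)
  }
  get("conc_pop", envir = .pipeline_cache)
}
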