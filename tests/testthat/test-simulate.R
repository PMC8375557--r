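small_cfg <- function(...) {
  args <- list(seed = 5L, genome_length = 20000L, n_females = 4L,
               n_males = 4L, system = "ZW", n_sex_limited_tags = 2L,
               n_gametolog_snps = 3L, n_autosomal_snps = 20L,
               coverage_mean = 15, error_rate = 0)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(core_length = 40, read_length = 33),
               "core_length")
  expect_error(sim_config(n_females = -1), "n_females")
  expect_error(sim_config(system = "NONE", n_sex_limited_tags = 3), "NONE")
  # capacity: too many tags for the genome
  expect_error(simulate_reference(small_cfg(genome_length = 2000L,
                                            n_autosomal_snps = 100L)),
               "capacity")
})

test_that("a fixed seed reproduces byte-identical outputs", {
  cfg <- small_cfg()
  s1 <- simulate_reference(cfg)
  s2 <- simulate_reference(cfg)
  expect_identical(s1$reference, s2$reference)
  g1 <- simulate_individuals(s1)
  g2 <- simulate_individuals(s2)
  expect_identical(g1, g2)
  r1 <- simulate_reads(s1, g1)
  r2 <- simulate_reads(s2, g2)
  expect_identical(r1, r2)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_output(s1, r1, d1)
  write_sim_output(s2, r2, d2)
  expect_identical(readLines(file.path(d1, "reference.fa")),
                   readLines(file.path(d2, "reference.fa")))
  expect_identical(readLines(file.path(d1, "F1.fastq")),
                   readLines(file.path(d2, "F1.fastq")))
})

test_that("a null system produces no sex-limited truth", {
  cfg <- small_cfg(system = "NONE", n_sex_limited_tags = 0L,
                   n_gametolog_snps = 0L)
  sim <- simulate_reference(cfg)
  expect_equal(names(sim$reference), "autosome")
  expect_equal(sum(sim$truth$loci$class != "autosomal"), 0L)
})

test_that("planted motif occurrences are exactly the truth sites", {
  cfg <- small_cfg(genome_length = 100000L, n_autosomal_snps = 50L,
                   n_gametolog_snps = 0L, n_sex_limited_tags = 0L,
                   system = "NONE")
  sim <- simulate_reference(cfg)
  hits <- oracle_scan_sites_only(sim$reference[["autosome"]])
  expect_equal(nrow(hits), 50L)
  expect_true(all(hits$strand == "+"))
  # every truth coordinate extracts to the recorded, motif-bearing core
  loci <- sim$truth$loci
  for (i in seq_len(nrow(loci))) {
    core <- substr(sim$reference[[loci$contig[i]]],
                   loci$core_start[i] + 1L, loci$core_start[i] + 27L)
    expect_equal(core, loci$core_seq[i])
    expect_equal(nrow(scan_motif(core)), 1L)
  }
})

test_that("gametolog heterozygosity follows the heterogametic sex", {
  sim <- simulate_reference(small_cfg())
  gt <- simulate_individuals(sim)
  gam <- gt[gt$class == "gametolog", ]
  expect_true(all(gam$truth_genotype[gam$sex == "F"] == "ref/alt"))
  expect_true(all(gam$truth_genotype[gam$sex == "M"] == "ref/ref"))
  sl <- gt[gt$class == "sex_limited", ]
  expect_true(all(sl$truth_genotype[sl$sex == "F"] == "ref/ref"))
  expect_true(all(sl$truth_genotype[sl$sex == "M"] == "absent"))
  # XY mirror
  simxy <- simulate_reference(small_cfg(system = "XY"))
  gtxy <- simulate_individuals(simxy)
  gamxy <- gtxy[gtxy$class == "gametolog", ]
  expect_true(all(gamxy$truth_genotype[gamxy$sex == "M"] == "ref/alt"))
  expect_true(all(gamxy$truth_genotype[gamxy$sex == "F"] == "ref/ref"))
})

test_that("autosomal genotypes follow Hardy-Weinberg at f = 0.5", {
  cfg <- small_cfg(genome_length = 60000L, n_autosomal_snps = 250L,
                   n_gametolog_snps = 0L, n_sex_limited_tags = 0L,
                   system = "NONE", n_females = 20L, n_males = 20L)
  gt <- simulate_individuals(simulate_reference(cfg))
  het <- mean(gt$truth_genotype == "ref/alt")
  n <- nrow(gt)                       # 10,000 genotype draws
  expect_equal(n, 10000L)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("error-free reads are exact copies of the tag window", {
  cfg <- small_cfg(n_autosomal_snps = 1L, n_gametolog_snps = 0L,
                   n_sex_limited_tags = 0L, system = "NONE",
                   n_females = 1L, n_males = 1L, coverage_mean = 30)
  sim <- simulate_reference(cfg)
  gt <- simulate_individuals(sim)
  # force a homozygous-reference individual for exactness
  hom <- gt[gt$truth_genotype == "ref/ref", ]
  if (nrow(hom) > 0L) {
    reads <- simulate_reads(sim, hom)
    r <- reads[[hom$individual[1]]]
    expect_gt(length(r), 0L)
    loci <- sim$truth$loci
    window <- substr(sim$reference[["autosome"]],
                     loci$core_start + 1L - 3L, loci$core_start + 27L + 3L)
    expect_true(all(r == window | r == oracle_revcomp(window)))
  }
})

test_that("read totals follow the Poisson sum and error rate is honored", {
  cfg <- small_cfg(n_autosomal_snps = 8L, n_gametolog_snps = 0L,
                   n_sex_limited_tags = 0L, system = "NONE",
                   n_females = 4L, n_males = 4L, coverage_mean = 20,
                   error_rate = 0.01)
  sim <- simulate_reference(cfg)
  gt <- simulate_individuals(sim)
  reads <- simulate_reads(sim, gt)
  for (ind in names(reads)) {
    g <- gt[gt$individual == ind, ]
    lambda <- sum(g$n_ref + g$n_alt) * cfg$coverage_mean
    expect_lt(abs(length(reads[[ind]]) - lambda), 4 * sqrt(lambda))
  }
  # mismatch fraction vs the nearest true allele window (ref or alt allele,
  # either strand)
  loci <- sim$truth$loci
  win_ref <- substring(sim$reference[["autosome"]], loci$core_start + 1L - 3L,
                    loci$core_start + 27L + 3L)
  win_alt <- win_ref
  for (i in seq_len(nrow(loci)))
    substr(win_alt[i], 3L + loci$snp_offset[i] + 1L,
           3L + loci$snp_offset[i] + 1L) <- loci$alt_base[i]
  cands <- unique(c(win_ref, win_alt, vapply(c(win_ref, win_alt),
                                             oracle_revcomp, character(1),
                                             USE.NAMES = FALSE)))
  cand_mat <- t(vapply(cands, function(w) strsplit(w, "")[[1]],
                       character(33), USE.NAMES = FALSE))
  all_reads <- unlist(reads, use.names = FALSE)
  mism <- vapply(all_reads, function(r) {
    rc <- strsplit(r, "")[[1]]
    min(rowSums(cand_mat != matrix(rc, nrow(cand_mat), 33, byrow = TRUE)))
  }, numeric(1), USE.NAMES = FALSE)
  phat <- sum(mism) / (length(all_reads) * 33)
  se <- sqrt(0.01 * 0.99 / (length(all_reads) * 33))
  expect_lt(abs(phat - 0.01), 3 * se + 1e-9)
})
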