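#!/usr/bin/env Rscript
# Simulate the study population: 10 females + 10 males of a ZW species,
# 100 kb autosomal/Z contig plus a female-limited W contig carrying 3 extra
# BsaXI tags, 10 Z/W gametolog SNPs, 200 autosomal Hardy-Weinberg SNP loci,
# ~30 reads per tag copy, 1% sequencing error. Writes the reference FASTA,
# per-individual FASTQ, sample sheet and truth tables.

suppressPackageStartupMessages(library(rad2b))

outdir <- "results/sim"
cfg <- sim_config(seed = 42L, genome_length = 100000L, n_females = 10L,
                  n_males = 10L, system = "ZW", n_sex_limited_tags = 3L,
                  n_gametolog_snps = 10L, n_autosomal_snps = 200L,
                  coverage_mean = 30, error_rate = 0.01)
sim <- simulate_reference(cfg)
gt <- simulate_individuals(sim)
reads <- simulate_reads(sim, gt)
write_sim_output(sim, reads, outdir)

n_reads <- vapply(reads, length, integer(1))
cat("Simulated", length(reads), "individuals;",
    "reads per individual:", min(n_reads), "-", max(n_reads), "\n")
cat("Planted loci:", nrow(sim$truth$loci), "(",
    sum(sim$truth$loci$class == "sex_limited"), "W-limited,",
    sum(sim$truth$loci$class == "gametolog"), "gametolog,",
    sum(sim$truth$loci$class == "autosomal"), "autosomal )\n")
cat("Outputs in", outdir, "\n")
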