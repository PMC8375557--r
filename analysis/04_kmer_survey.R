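#!/usr/bin/env Rscript
# K-mer genome survey (k = 17, canonical) on simulated whole-genome shotgun
# reads: one haploid run for genome size, one diploid run with 1% planted
# divergence for heterozygosity recovery.

suppressPackageStartupMessages(library(rad2b))

outdir <- "results/survey"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

set.seed(1042)
g <- paste(sample(c("A", "C", "G", "T"), 100000L, TRUE), collapse = "")

reads <- simulate_shotgun_reads(g, coverage = 30, read_length = 100,
                                seed = 1043)
hist1 <- count_kmers(reads, k = 17)
write_kmer_histogram(hist1, file.path(outdir, "haploid.histo"))
est1 <- estimate_genome_size(hist1)
cat(sprintf("Haploid survey: genome size %.0f bp (truth 100000, %.1f%% off), peak depth %dx\n",
            est1$genome_size_bp, 100 * abs(est1$genome_size_bp - 1e5) / 1e5,
            est1$homozygous_peak_depth))

mut <- mutate_haplotype(g, 0.01, seed = 1044)
reads2 <- simulate_shotgun_reads(c(g, mut$seq), coverage = 15,
                                 read_length = 100, seed = 1045)
hist2 <- count_kmers(reads2, k = 17)
write_kmer_histogram(hist2, file.path(outdir, "diploid.histo"))
est2 <- estimate_genome_size(hist2)
cat(sprintf("Diploid survey: heterozygosity %.2f%% (planted 1.00%%), genome size %.0f bp\n",
            100 * est2$heterozygosity, est2$genome_size_bp))

jsonlite::write_json(list(haploid = unclass(est1), diploid = unclass(est2)),
                     file.path(outdir, "survey_estimates.json"),
                     auto_unbox = TRUE, digits = NA)
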