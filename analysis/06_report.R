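#!/usr/bin/env Rscript
# Reporting: published run-table arithmetic, candidate fixture validation,
# in-silico PCR assays for the recovered W tags on a fresh 38 F + 57 M
# population, scaffold statistics and an ORF scan of the W contig.

suppressPackageStartupMessages(library(rad2b))

outdir <- "results/report"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

## published-table summaries
s <- summarize_run_table(load_run_table())
cat(sprintf("Run table: %d raw reads (%d F / %d M), %d tags, mean depth %s\n",
            s$total$raw_reads, s$by_sex$F$raw_reads, s$by_sex$M$raw_reads,
            s$total$tags, s$total$mean_depth_2dp))
tags <- load_candidate_tags()
snps <- load_candidate_snps()
pat <- mapply(classify_pattern, snps$female_genotype, snps$male_genotype)
cat("Fixtures:", nrow(tags), "candidate tags,", nrow(snps),
    "candidate SNPs ->", sum(pat == "female_heterogametic"),
    "female-heterogametic,", sum(pat == "male_heterogametic"),
    "male-heterogametic,", sum(pat == "fixed_difference"),
    "fixed-difference\n")

## in-silico PCR sexing of an independent population
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
write.table(conc$per_marker, file.path(outdir, "pcr_concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("In-silico PCR: %d/%d band calls concordant with gonadal sex (%.1f%%)\n",
            sum(conc$per_marker$n_correct), sum(conc$per_marker$n),
            100 * sum(conc$per_marker$n_correct) / sum(conc$per_marker$n)))

## scaffold stats and ORF scan of the sex-limited contig
stats <- scaffold_stats(sim$reference)
cat(sprintf("Scaffolds: n=%d, max=%d bp, total=%d bp, N50=%d bp, >2kb: %d\n",
            stats$n_scaffolds, stats$max_length, stats$total_length,
            stats$n50, stats$n_over_2kb))
orfs <- find_orfs(sim$reference[["W"]], min_aa = 50)
write.table(orfs, file.path(outdir, "w_contig_orfs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ORFs (>= 50 codons) on the W contig:", nrow(orfs), "\n")
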