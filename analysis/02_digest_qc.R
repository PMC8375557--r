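#!/usr/bin/env Rscript
# In-silico BsaXI digestion of the simulated reference (tag catalog as
# BED + core FASTA) and read quality control: N-fraction <= 8%, mean
# Phred >= 20, recognition site required; survivors trimmed to canonical
# 27-nt cores.

suppressPackageStartupMessages(library(rad2b))

simdir <- "results/sim"
outdir <- "results/qc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ref <- read_fasta(file.path(simdir, "reference.fa"))
sites <- extract_tag_catalog(ref)
write_bed(sites, file.path(outdir, "digest_sites.bed"))
write_core_fasta(sites, file.path(outdir, "digest_cores.fa"))
cat("Reference digestion:", nrow(sites), "BsaXI tag sites on",
    length(ref), "contigs\n")

samples <- read_sample_sheet(file.path(simdir, "samples.tsv"))
fq <- file.path(simdir, paste0(samples$individual_id, ".fastq"))
names(fq) <- samples$individual_id
qcres <- run_qc(fq, samples)
write.table(qcres$report, file.path(outdir, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(qcres$cores, file.path(outdir, "clean_cores.rds"))

rp <- qcres$report
cat("QC:", sum(rp$raw_reads), "raw reads ->", sum(rp$clean_reads),
    "clean cores (", sum(rp$no_motif), "no-motif,", sum(rp$n_excess),
    "N-excess,", sum(rp$low_quality), "low-quality )\n")
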