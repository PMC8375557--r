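#!/usr/bin/env Rscript
# Cluster the clean tag cores into a locus catalog (<= 2 mismatches to the
# founder), call depth-threshold genotypes (absent < 3 reads; het needs >= 2
# reads and > 10% minor fraction) and emit the SNP table.

suppressPackageStartupMessages(library(rad2b))

outdir <- "results/genotype"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cores <- readRDS("results/qc/clean_cores.rds")
samples <- read_sample_sheet("results/sim/samples.tsv")

catalog <- build_catalog(cores)
genotypes <- genotype_catalog(catalog, individuals = samples$individual_id)
snps <- call_snps(catalog, genotypes)

write.table(catalog$loci, file.path(outdir, "catalog_loci.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(genotypes, file.path(outdir, "genotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(snps, file.path(outdir, "snps.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(catalog = catalog, genotypes = genotypes, snps = snps),
        file.path(outdir, "genotype_state.rds"))

cat("Catalog:", nrow(catalog$loci), "loci,", nrow(catalog$alleles),
    "alleles\n")
cat("Calls:", nrow(genotypes), "locus x individual genotypes;",
    sum(genotypes$call == "het"), "heterozygous\n")
cat("SNP table:", nrow(snps), "biallelic positions (",
    length(attr(snps, "multiallelic_loci")), "multiallelic loci excluded)\n")
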