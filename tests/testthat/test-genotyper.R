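tagA <- "GCCTGGAGCACTGAATCTCCGTGCAAA"

mutate_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

test_that("near-identical sequences cluster into one locus with a SNP", {
  a <- canonicalize(tagA)
  b <- mutate_at(a, 25, ifelse(substr(a, 25, 25) == "A", "G", "A"))
  cores <- list(i1 = c(rep(a, 60), rep(b, 40)),
                i2 = rep(a, 50))
  cat_ <- build_catalog(cores)
  expect_equal(nrow(cat_$loci), 1L)
  expect_equal(nrow(cat_$alleles), 2L)
  expect_equal(cat_$loci$consensus, a)   # more abundant founder
  gt <- genotype_catalog(cat_)
  snps <- call_snps(cat_, gt)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$snp_position, 25L)
})

test_that("sequences beyond max_mismatch form separate loci", {
  a <- canonicalize(tagA)
  b <- a
  for (p in c(3, 5, 21, 23, 25))
    b <- mutate_at(b, p, ifelse(substr(b, p, p) == "A", "G", "A"))
  cat_ <- build_catalog(list(i1 = c(rep(a, 10), rep(b, 10))))
  expect_equal(nrow(cat_$loci), 2L)
})

test_that("catalog construction is invariant to input order", {
  set.seed(51)
  seqs <- replicate(30, random_seq(27))
  seqs <- canonicalize(seqs)
  reps <- rep(seqs, times = sample(1:20, 30, TRUE))
  c1 <- build_catalog(list(i1 = reps))
  c2 <- build_catalog(list(i1 = rev(reps)))
  expect_equal(c1$loci$consensus, c2$loci$consensus)
  expect_equal(c1$alleles$allele_seq, c2$alleles$allele_seq)
})

test_that("depth is conserved: every clean read lands in one locus", {
  set.seed(52)
  reads <- canonicalize(replicate(40, random_seq(27)))
  cores <- list(a = sample(reads, 200, TRUE), b = sample(reads, 150, TRUE))
  cat_ <- build_catalog(cores)
  expect_equal(sum(cat_$depths$depth), 350L)
  expect_equal(sum(cat_$alleles$depth), 350L)
})

test_that("the depth-threshold caller follows the published min-depth rule", {
  expect_equal(call_genotype(c(A = 2L))$call, "absent")
  g <- call_genotype(c(A = 20L, G = 18L))
  expect_equal(g$call, "het")
  expect_equal(g$alleles, c("A", "G"))
  g2 <- call_genotype(c(A = 30L, G = 1L))
  expect_equal(g2$call, "hom")
  expect_equal(g2$alleles, "A")
  # minor fraction at the boundary is homozygous (strict inequality)
  expect_equal(call_genotype(c(A = 27L, G = 3L))$call, "hom")
})

test_that("error-free simulation recovers planted loci, SNPs and genotypes", {
  pl <- zw_clean_pipeline()
  truth <- pl$truth_loci
  # every planted locus appears in the catalog exactly once
  expect_false(any(is.na(truth$catalog_locus_id)))
  expect_equal(nrow(pl$catalog$loci), nrow(truth))
  # recovered SNP set matches the planted set (error-free, 20x)
  planted <- truth[truth$class %in% c("autosomal", "gametolog"), ]
  snps <- pl$snps
  expect_equal(nrow(snps), nrow(planted))
  # genotype accuracy is perfect without sequencing error at >= 20x
  expect_equal(genotype_accuracy(pl)$accuracy, 1)
})

test_that("the published SNP-record schema round-trips through the caller", {
  # construct a two-allele locus mirroring the top published SNP:
  # ref A at position 24, alt G, female het A/G, male hom A/A
  a <- canonicalize("AACTCTGGAACCTTCCCTCCATCTTCC")
  pos <- 24L
  alt <- mutate_at(a, pos, ifelse(substr(a, pos, pos) == "G", "A", "G"))
  cores <- list(F1 = c(rep(a, 20), rep(alt, 18)), M1 = rep(a, 30))
  cat_ <- build_catalog(cores)
  gt <- genotype_catalog(cat_)
  snps <- as.data.frame(call_snps(cat_, gt))
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$snp_position, pos)
  expect_equal(snps$ref_base, substr(a, pos, pos))
  expect_equal(snps$alt_base, substr(alt, pos, pos))
  fg <- strsplit(snps$F1, "/")[[1]]
  expect_setequal(fg, c(substr(a, pos, pos), substr(alt, pos, pos)))
  mb <- substr(a, pos, pos)
  expect_equal(snps$M1, paste0(mb, "/", mb))
})
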