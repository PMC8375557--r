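test_that("run-table totals reproduce the published summary arithmetic", {
  rt <- load_run_table()
  s <- summarize_run_table(rt)
  expect_equal(s$total$raw_reads, 137684505)
  expect_equal(s$by_sex$F$raw_reads, 76661950)
  expect_equal(s$by_sex$M$raw_reads, 61022555)
  expect_equal(s$by_sex$F$clean_reads, 72125643)
  expect_equal(s$by_sex$M$clean_reads, 56991085)
  expect_equal(s$total$tags, 2384989)
  expect_equal(s$total$mean_depth, 36.7975)
  expect_equal(s$total$mean_depth_2dp, "36.80")
})

test_that("run-table summaries conserve over subsets", {
  rt <- load_run_table()
  one <- summarize_run_table(rt[1, ])
  expect_equal(one$total$raw_reads, rt$raw_reads[1])
  expect_equal(one$total$mean_depth, rt$depth[1])
  set.seed(81)
  idx <- sample(nrow(rt), 7)
  sub <- summarize_run_table(rt[idx, ])
  expect_equal(sub$total$tags, sum(rt$tags[idx]))
  bad <- rt; bad$tags[1] <- -5
  expect_error(summarize_run_table(bad), "negative")
})

test_that("fixture transcriptions are frozen by checksum", {
  md5 <- function(f) unname(tools::md5sum(system.file(
    "extdata", f, package = "rad2b")))
  expect_equal(md5("table1.tsv"), "6bb4cbe2584951b586919d3792aa65c8")
  expect_equal(md5("table3.tsv"), "154097fb665bd4aac716990bad6484c4")
  expect_equal(md5("table4.tsv"), "39a642957cb866e035c51a48360bbb9c")
})

test_that("candidate fixtures parse, validate and classify", {
  tags <- load_candidate_tags()
  expect_equal(nrow(tags), 13L)
  expect_true(all(nchar(tags$sequence) == 27L))
  snps <- load_candidate_snps()
  expect_equal(nrow(snps), 10L)
  pat <- mapply(classify_pattern, snps$female_genotype, snps$male_genotype)
  expect_equal(sum(pat == "female_heterogametic"), 7L)
  expect_equal(sum(pat == "male_heterogametic"), 2L)
  expect_equal(sum(pat == "fixed_difference"), 1L)
  # corrupted fixture: truncated sequence
  bad <- tags; bad$sequence[1] <- substr(bad$sequence[1], 1, 26)
  tf <- tempfile(fileext = ".tsv")
  write.table(bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_candidate_tags(tf), "length")
})

test_that("flank extraction centers the amplicon and enforces uniqueness", {
  set.seed(82)
  tag <- load_candidate_tags()$sequence[7]
  scaf <- c(s1 = embed_in_motif_free(tag, 2500))
  assay <- extract_flanks(scaf, tag, marker_id = "m1")
  expect_equal(assay$scaffold_id, "s1")
  expect_lte(assay$end - assay$start, 1000L)
  expect_gte(assay$end - assay$start, 100L)
  mid <- (assay$start + assay$end) / 2
  expect_lt(abs(mid - (2500 + 13.5)), 2)
  # too close to the scaffold end for the minimum amplicon
  short <- c(s1 = paste0(substr(scaf[[1]], 2471, 2530), ""))
  expect_error(extract_flanks(short, tag, amplicon_min = 100L), "shorter")
  # multi-mapping tag
  dup <- c(s1 = scaf[[1]], s2 = scaf[[1]])
  expect_error(extract_flanks(dup, tag), "uniquely")
})

test_that("in-silico PCR concordance is perfect for W-linked assays", {
  pl <- zw_clean_pipeline()
  w_ids <- truth_catalog_ids(pl, "sex_limited")
  assays <- lapply(w_ids, function(id) {
    structure(list(marker_id = paste0("locus", id), scaffold_id = "W",
                   start = 0L, end = 500L,
                   expected_presence = c(F = "band", M = "no_band")),
              class = "marker_assay")
  })
  conc <- insilico_pcr_concordance(assays, pl$pm)
  expect_equal(conc$per_marker$concordance, rep(1, length(w_ids)))
  expect_equal(sum(conc$confusion), length(w_ids) * ncol(pl$pm$present))
  # an autosomal tag is uninformative: band in everyone
  auto_id <- truth_catalog_ids(pl, "autosomal")[1]
  a2 <- list(structure(list(marker_id = paste0("locus", auto_id),
                            scaffold_id = "autosome", start = 0L,
                            end = 500L,
                            expected_presence = c(F = "band",
                                                  M = "no_band")),
                       class = "marker_assay"))
  c2 <- insilico_pcr_concordance(a2, pl$pm)
  expect_equal(c2$per_marker$concordance, 0.5)
  # empty assay list
  c0 <- insilico_pcr_concordance(list(), pl$pm)
  expect_equal(nrow(c0$per_marker), 0L)
})

test_that("scaffold statistics match the cumulative-sum oracle", {
  expect_equal(scaffold_stats(c(10, 10, 10, 10, 60))$n50, 60)
  expect_equal(scaffold_stats(c(5, 5, 5, 5))$n50, 5)
  one <- scaffold_stats(1234)
  expect_equal(one$n50, 1234)
  expect_equal(one$max_length, 1234)
  expect_equal(one$total_length, 1234)
  set.seed(83)
  for (i in 1:20) {
    lens <- sample(50:5000, sample(3:40, 1))
    expect_equal(scaffold_stats(lens)$n50, oracle_n50(lens))
  }
  s <- scaffold_stats(c(100, 2500, 3000, 1999, 2001))
  expect_equal(s$n_over_2kb, 3)
})

test_that("ORF scanning requires a full start-to-stop span", {
  set.seed(84)
  body <- paste(rep("GCT", 60), collapse = "")   # 60 Ala codons, no stop
  orf <- paste0("ATG", body, "TAA")
  s <- paste0(strrep("C", 10), orf, strrep("C", 10))
  got <- find_orfs(s, min_aa = 50)
  fwd <- got[got$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 10L)
  expect_equal(fwd$end, 10L + nchar(orf))
  expect_equal(fwd$n_aa, 61L)
  # the same ORF is seen on the minus strand of the reverse complement
  rc <- find_orfs(oracle_revcomp(s), min_aa = 50)
  rev_hit <- rc[rc$strand == "-", ]
  expect_equal(nrow(rev_hit), 1L)
  expect_equal(rev_hit$n_aa, 61L)
  # too-short input
  expect_equal(nrow(find_orfs("ATGTAA", min_aa = 50)), 0L)
  # a 717 bp random scaffold typically has no 100-codon ORF
  set.seed(85)
  scaf <- random_seq(717)
  expect_equal(nrow(find_orfs(scaf, min_aa = 100)), 0L)
})
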