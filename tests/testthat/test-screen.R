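mk_pm <- function(depth, sexes, min_depth = 3L) {
  samples <- data.frame(individual_id = colnames(depth), sex = sexes,
                        stringsAsFactors = FALSE)
  d <- data.frame(locus_id = rep(seq_len(nrow(depth)), ncol(depth)),
                  individual = rep(colnames(depth), each = nrow(depth)),
                  depth = as.vector(depth))
  presence_matrix(d[d$depth > 0, ], samples, min_depth)
}

test_that("presence is a pure function of depth and the threshold", {
  depth <- matrix(c(0, 2, 3, 10), 1, 4,
                  dimnames = list(NULL, c("F1", "F2", "M1", "M2")))
  pm <- mk_pm(depth, c("F", "F", "M", "M"))
  expect_equal(as.vector(pm$present), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("strict screening nominates the perfect split with the extreme p", {
  depth <- matrix(0, 2, 20,
                  dimnames = list(NULL, c(paste0("F", 1:10),
                                          paste0("M", 1:10))))
  depth[1, 1:10] <- 30          # female-limited tag
  depth[2, ] <- 25              # uninformative tag
  pm <- mk_pm(depth, rep(c("F", "M"), each = 10))
  res <- find_sex_specific_tags(pm)
  expect_equal(res$pattern[res$marker_id == "locus1"], "female_specific")
  expect_equal(res$p_value[res$marker_id == "locus1"], 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(res$pattern[res$marker_id == "locus2"], "uninformative")
  expect_error(find_sex_specific_tags(
    mk_pm(depth[, 1:10, drop = FALSE], rep("F", 10))), "both sexes")
})

test_that("swapping sex labels mirrors every screening call", {
  set.seed(71)
  depth <- matrix(rbinom(20 * 12, 1, 0.6) * 30, 20, 12,
                  dimnames = list(NULL, paste0("i", 1:12)))
  depth[1, ] <- c(rep(30, 6), rep(0, 6))
  sexes <- rep(c("F", "M"), each = 6)
  a <- find_sex_specific_tags(mk_pm(depth, sexes))
  b <- find_sex_specific_tags(mk_pm(depth, rev(sexes)))
  swap <- c(female_specific = "male_specific",
            male_specific = "female_specific",
            uninformative = "uninformative")
  a <- a[order(a$marker_id), ]; b <- b[order(b$marker_id), ]
  expect_equal(unname(swap[a$pattern]), b$pattern)
  expect_equal(a$p_value, b$p_value)
})

test_that("p-values are invariant under individual reordering", {
  set.seed(72)
  depth <- matrix(rbinom(10 * 8, 1, 0.5) * 20, 10, 8,
                  dimnames = list(NULL, paste0("i", 1:8)))
  sexes <- c("F", "F", "F", "F", "M", "M", "M", "M")
  perm <- sample(8)
  a <- find_sex_specific_tags(mk_pm(depth, sexes))
  b <- find_sex_specific_tags(mk_pm(depth[, perm], sexes[perm]))
  expect_equal(a[order(a$marker_id), "p_value"],
               b[order(b$marker_id), "p_value"])
})

test_that("genotype patterns classify as in the published SNP table", {
  expect_equal(classify_pattern("A/G", "A/A"), "female_heterogametic")
  expect_equal(classify_pattern("T/T", "T/A"), "male_heterogametic")
  expect_equal(classify_pattern("C/C", "A/A"), "fixed_difference")
  expect_equal(classify_pattern(c("A/G", "A/A"), "A/A"), "uninformative")
  expect_equal(classify_pattern(c("A/G", NA), c("A/A", NA)),
               "female_heterogametic")
  expect_equal(classify_pattern(NA_character_, "A/A"), "uninformative")
})

test_that("SNP association ranks the perfect pattern first", {
  snp <- data.frame(marker_id = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  for (i in 1:10) snp[[paste0("F", i)]] <- c("A/G", "A/G", "A/A")
  for (i in 1:10) snp[[paste0("M", i)]] <- c("A/A", "A/A", "A/A")
  # s2: only half the females het
  for (i in 1:5) snp[2, paste0("F", i)] <- "A/A"
  sexes <- structure(rep(c("F", "M"), each = 10),
                     names = c(paste0("F", 1:10), paste0("M", 1:10)))
  res <- snp_sex_association(snp, sexes)
  expect_equal(res$marker_id[1], "s1")
  expect_equal(res$p_value[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$pattern[1], "female_heterogametic")
  expect_gt(res$p_value[res$marker_id == "s2"], res$p_value[1])
  # monomorphic marker is uninformative with p = 1
  expect_equal(res$p_value[res$marker_id == "s3"], 1)
  expect_equal(res$pattern[res$marker_id == "s3"], "uninformative")
})

test_that("Fisher p-values are conservative under the null", {
  set.seed(73)
  n_seeds <- 50; n_snps <- 40
  pvals <- numeric(0)
  sexes <- structure(rep(c("F", "M"), each = 10),
                     names = paste0("i", 1:20))
  for (s in seq_len(n_seeds)) {
    gt <- matrix(ifelse(runif(20 * n_snps) < 0.5, "A/G", "A/A"),
                 n_snps, 20, dimnames = list(NULL, names(sexes)))
    snp <- cbind(data.frame(marker_id = paste0("s", seq_len(n_snps)),
                            stringsAsFactors = FALSE),
                 as.data.frame(gt, stringsAsFactors = FALSE))
    res <- snp_sex_association(snp, sexes)
    pvals <- c(pvals, res$p_value)
  }
  frac05 <- mean(pvals <= 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lte(frac05, 0.05 + 3 * se)
  expect_gte(min(pvals), 2 / choose(20, 10))
})

test_that("system inference needs dominant one-sided evidence", {
  tags <- data.frame(pattern = c(rep("female_specific", 3),
                                 rep("uninformative", 5)))
  snps <- data.frame(pattern = c(rep("female_heterogametic", 7),
                                 rep("male_heterogametic", 2),
                                 "fixed_difference"))
  expect_equal(infer_system(tags, snps)$call, "ZW")
  mirror <- function(d) {
    swap <- c(female_specific = "male_specific",
              male_specific = "female_specific",
              female_heterogametic = "male_heterogametic",
              male_heterogametic = "female_heterogametic",
              fixed_difference = "fixed_difference",
              uninformative = "uninformative")
    d$pattern <- unname(swap[d$pattern])
    d
  }
  expect_equal(infer_system(mirror(tags), mirror(snps))$call, "XY")
  none <- data.frame(pattern = character(0))
  expect_equal(infer_system(none, none)$call, "undetermined")
  conflicted <- data.frame(pattern = c("female_specific", "male_specific"))
  expect_equal(infer_system(conflicted, none)$call, "undetermined")
})
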