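test_that("peak-SNP counting respects the half-open boundary convention", {
  pk <- data.frame(chrom = "chr1", start = 100L, end = 200L, name = "p1")
  cat0 <- data.frame(chrom = character(), pos = integer(),
                     snp_id = character(), trait_category = character())
  expect_equal(count_peaks_with_snp(pk, cat0), 0)
  at <- function(p) data.frame(chrom = "chr1", pos = p, snp_id = "rs1",
                               trait_category = "t")
  expect_equal(count_peaks_with_snp(pk, at(150L)), 1)
  expect_equal(count_peaks_with_snp(pk, at(100L)), 0)  # pos == start excluded
  expect_equal(count_peaks_with_snp(pk, at(200L)), 1)  # pos == end included
  # a peak counts once no matter how many SNPs it holds
  many <- data.frame(chrom = "chr1", pos = c(120L, 130L, 140L),
                     snp_id = paste0("rs", 1:3), trait_category = "t")
  expect_equal(count_peaks_with_snp(pk, many), 1)
})

test_that("peak-SNP counting equals the all-pairs brute force", {
  set.seed(13)
  pk <- random_peak_universe(100)
  snp <- data.frame(chrom = "chrU",
                    pos = sample.int(max(pk$end) + 1000, 500),
                    snp_id = sprintf("rs%03d", 1:500), trait_category = "t")
  expect_equal(count_peaks_with_snp(pk, snp), brute_peaks_with_snp(pk, snp))
})

test_that("matched background sampling preserves stratum counts", {
  set.seed(17)
  u <- random_peak_universe(400)
  target <- u[1:100, ]
  background <- u[101:400, ]
  strata <- make_strata(target)
  idx <- sample_matched_background(target, background, strata, seed = 3)
  expect_equal(length(idx), nrow(target))
  ts <- restim:::stratum_of(target, strata)
  bs <- restim:::stratum_of(background[idx, ], strata)
  expect_equal(table(bs), table(ts), ignore_attr = TRUE)
  # background identical to target in every stratum -> identical counts trivially
  idx2 <- sample_matched_background(target, target, strata, seed = 4)
  expect_equal(length(idx2), nrow(target))
  # empty stratum errors with the stratum name
  bg_small <- background[(background$end - background$start) <
                           quantile(target$end - target$start, 0.2), ]
  expect_error(sample_matched_background(target, bg_small, strata),
               "empty background stratum")
})

test_that("per-stratum selection frequencies are uniform", {
  set.seed(19)
  u <- random_peak_universe(120)
  target <- u[1:20, ]
  background <- u[21:120, ]
  strata <- make_strata(target, n_width_bins = 1)
  counts <- integer(nrow(background))
  set.seed(23)
  for (i in 1:1000) {
    idx <- sample_matched_background(target, background, strata)
    counts[idx] <- counts[idx] + 1L
  }
  p <- 20 / 100  # each of 100 background peaks drawn w.p. 0.2 per replicate
  freq <- counts / 1000
  expect_true(all(abs(freq - p) < 4 * sqrt(p * (1 - p) / 1000)))
})

test_that("empirical p-values are floored, deterministic and order-invariant", {
  set.seed(29)
  u <- random_peak_universe(300)
  target <- u[1:60, ]
  background <- u[61:300, ]
  # plant SNPs in every target peak and none in the background
  snp <- data.frame(chrom = "chrU", pos = target$start + 5L,
                    snp_id = sprintf("rs%02d", 1:60), trait_category = "t")
  r <- permutation_enrichment(target, background, snp, n_perm = 1000, seed = 7)
  expect_equal(r$observed, 60)
  expect_equal(r$empirical_p, 1 / 1001)
  expect_gte(r$empirical_p, 1 / (r$n_perm + 1))

  r2 <- permutation_enrichment(target, background, snp, n_perm = 1000, seed = 7)
  expect_identical(r, r2)
  # shuffling peak and SNP row order changes nothing
  r3 <- permutation_enrichment(target[sample(60), ],
                               background[sample(240), ],
                               snp[sample(60), ], n_perm = 1000, seed = 7)
  expect_equal(r3$observed, r$observed)
  expect_equal(r3$empirical_p, r$empirical_p)
})

test_that("per-trait enrichment shares nulls and handles empty categories", {
  set.seed(31)
  u <- random_peak_universe(250)
  target <- u[1:50, ]
  background <- u[51:250, ]
  snpA <- data.frame(chrom = "chrU", pos = target$start[1:30] + 10L,
                     snp_id = sprintf("a%02d", 1:30), trait_category = "A")
  snpB <- snpA
  snpB$snp_id <- sprintf("b%02d", 1:30)
  snpB$trait_category <- "B"
  both <- rbind(snpA, snpB)
  r <- enrichment_by_trait(target, background, both, n_perm = 200, seed = 5)
  # identical SNP positions -> identical results across categories
  expect_equal(r$observed[r$trait_category == "A"],
               r$observed[r$trait_category == "B"])
  expect_equal(r$empirical_p[r$trait_category == "A"],
               r$empirical_p[r$trait_category == "B"])

  onlyA <- both[both$trait_category == "A", ]
  onlyA$trait_category[1] <- "C"
  onlyA$pos[1] <- max(background$end) + 500L  # SNP outside every peak
  r2 <- enrichment_by_trait(target, background, onlyA, n_perm = 200, seed = 5)
  expect_equal(r2$observed[r2$trait_category == "C"], 0)
  expect_equal(r2$empirical_p[r2$trait_category == "C"], 1)
  expect_error(enrichment_by_trait(target, background, both[0, ], 10, 1),
               "no SNPs")
})

test_that("planted enrichment in one category is detected, others stay calibrated", {
  set.seed(37)
  u <- random_peak_universe(400, target_class_frac = 0.2)
  tgt <- u$peak_class == "SINGLE_ONLY"
  target <- u[tgt, ]
  background <- u[!tgt, ]
  catA <- simulate_snp_catalog(u, snp_enrich_spec(4e-4, planted_fold = 5,
                                                  trait_categories = "A"),
                               seed = 11)
  catB <- simulate_snp_catalog(u[, c("chrom", "start", "end", "name",
                                     "peak_class")],
                               snp_enrich_spec(4e-4, planted_fold = 1,
                                               trait_categories = "B",
                                               target_classes = character()),
                               seed = 12)
  r <- enrichment_by_trait(target, background, rbind(catA, catB),
                           n_perm = 300, seed = 13)
  expect_lt(r$empirical_p[r$trait_category == "A"], 0.05)
  expect_gt(r$enrichment_score[r$trait_category == "A"], 1.5)
  expect_gt(r$empirical_p[r$trait_category == "B"], 0.05)
})
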