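test_that("low-count filter implements the >=20-in->=3-samples rule", {
  m <- matrix(0L, 4, 20, dimnames = list(paste0("g", 1:4), paste0("s", 1:20)))
  m[1, 1:3] <- 25L            # >= 20 in exactly 3 samples -> retained
  m[2, ] <- 19L               # 19 everywhere -> removed
  m[3, 1:2] <- 100L           # >= 20 in only 2 samples -> removed
  m[4, ] <- 50L               # comfortably expressed -> retained
  out <- filter_low_counts(m)
  expect_identical(rownames(out), c("g1", "g4"))
  expect_error(filter_low_counts(m[2, , drop = FALSE]), "all features removed")
})

test_that("size factors reproduce the median-of-ratios hand computation", {
  m0 <- matrix(c(5L, 9L, 5L, 9L), 2, 2)
  expect_equal(unname(estimate_size_factors(m0)), c(1, 1))

  # genes x samples [[10,20],[30,60]]: geometric means (sqrt(200), sqrt(1800)),
  # column ratio medians 1/sqrt(2) and sqrt(2)
  m1 <- matrix(c(10L, 30L, 20L, 60L), 2, 2)
  expect_equal(unname(estimate_size_factors(m1)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  m2 <- cbind(a = c(10L, 30L, 17L), b = c(20L, 60L, 34L))
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  m3 <- matrix(c(0L, 5L, 7L, 0L), 2, 2)
  expect_warning(estimate_size_factors(m3), "total-count")
})

test_that("dispersion estimator hits the floor for Poisson-like data and recovers planted alpha", {
  d <- build_design(5, "TNFA")
  sf <- setNames(rep(1, 20), d$sample_id)

  cm <- matrix(40L, 3, 20, dimnames = list(paste0("c", 1:3), d$sample_id))
  expect_true(all(estimate_dispersion(cm, sf, d) == 1e-8))

  set.seed(8)
  pois <- matrix(rpois(300 * 20, 500), 300, 20,
                 dimnames = list(paste0("p", 1:300), d$sample_id))
  a_pois <- estimate_dispersion(pois, sf, d)
  expect_lt(median(a_pois), 1e-3)

  nb <- matrix(rnbinom(1500 * 20, mu = 100, size = 2), 1500, 20,
               dimnames = list(paste0("n", 1:1500), d$sample_id))
  a_nb <- estimate_dispersion(nb, sf, d, blend = 0)
  expect_lt(abs(median(a_nb) - 0.5) / 0.5, 0.2)
})

test_that("paired NB IRLS matches an independent GLM oracle to 1e-6", {
  skip_if_not_installed("MASS")
  d <- build_design(4, "IFNG")
  truth <- assign_gene_classes(10, seed = 31)
  sim <- simulate_counts(d, truth, sim_params(n_donors = 4, seed = 32))
  sf <- sim$size_factors
  for (i in seq_len(10)) {
    y <- sim$counts[i, ]
    f <- fit_paired_glm(y, d, sf, alpha = 0.1, tol = 1e-13, maxit = 200)
    # epsilon at machine precision: glm warns that its deviance criterion
    # cannot shrink further even though the score is ~1e-12 at the optimum
    g <- suppressWarnings(stats::glm(y ~ donor + condition,
                    data = cbind(d, y = y), offset = log(sf),
                    family = MASS::negative.binomial(theta = 10),
                    control = stats::glm.control(epsilon = 1e-14, maxit = 200)))
    # relative to the coefficient scale: near-zero donor effects make
    # per-coefficient ratios ill-conditioned at solver precision
    expect_lt(max(abs(coef(f) - coef(g))) / max(abs(coef(g))), 1e-6)
  }
})

test_that("contrasts recover the planted template arithmetic", {
  d <- build_design(5, "TNFA")
  mk_truth <- function(mult) {
    data.frame(gene_id = sprintf("g%d", 1:40), memory_class = "X",
               base_mean = 5e4, mult_CTRL1 = mult[1], mult_HIT1 = mult[2],
               mult_CTRL2 = mult[3], mult_HIT2 = mult[4])
  }
  p <- sim_params(nb_dispersion = 1e-8, donor_effect_sd = 0,
                  library_size_range = c(1, 1), seed = 7)
  fit_for <- function(mult) {
    sim <- simulate_counts(d, mk_truth(mult), p)
    restim_fit(sim$counts, d, size_factors = sim$size_factors)
  }
  # equal condition means -> all effects ~ 0
  f0 <- fit_for(c(1, 1, 1, 1))
  expect_lt(max(abs(coef(f0))), 0.02)
  # same elevation in both hits relative to own baselines -> interaction ~ 0
  fsym <- fit_for(c(1, 4, 4, 16))
  expect_lt(max(abs(results(fsym, "INTERACTION")$log2fc)), 0.05)
  # trained template 8 vs 4 -> interaction log2fc ~ 1
  ftr <- fit_for(c(1, 4, 1, 8))
  expect_equal(median(results(ftr, "INTERACTION")$log2fc), 1, tolerance = 0.05)
  expect_equal(median(results(ftr, "HIT1vCTRL1")$log2fc), 2, tolerance = 0.05)
})

test_that("zero contrasts and broken fits are handled", {
  d <- build_design(3, "TNFA")
  sf <- setNames(rep(1, 12), d$sample_id)
  f <- fit_paired_glm(rpois(12, 50), d, sf, 0.1)
  expect_error(test_contrast(f, rep(0, 8)), "invalid contrast")
  broken <- structure(list(coefficients = rep(NA_real_, 8), vcov = NULL,
                           fitted = NULL, converged = FALSE, df_residual = 4),
                      class = "nbpair_fit")
  r <- test_contrast(broken, c(rep(0, 7), 1))
  expect_equal(r$pvalue, 1)
  expect_true(r$flagged)
})

test_that("BH adjustment matches the step-up hand computation and dominates p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(2)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in input ranks
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_warning(q2 <- bh_adjust(c(0.01, NaN)), "non-finite")
  expect_equal(q2[2], 1)
})

test_that("the suite is deterministic and overlap percentages follow pct()", {
  d <- build_design(3, "TNFA")
  truth <- assign_gene_classes(60, seed = 21)
  sim <- simulate_counts(d, truth, sim_params(n_donors = 3, seed = 22))
  s1 <- run_contrast_suite(sim$counts, d, restim_config(min_count = 5))
  s2 <- run_contrast_suite(sim$counts, d, restim_config(min_count = 5))
  expect_identical(s1, s2)
  expect_setequal(unique(s1$contrast),
                  c("HIT1vCTRL1", "HIT2vCTRL2", "HIT2vHIT1",
                    "CTRL2vCTRL1", "INTERACTION"))

  a <- data.frame(feature_id = sprintf("g%d", 1:10),
                  significant = c(rep(TRUE, 6), rep(FALSE, 4)))
  b <- data.frame(feature_id = sprintf("g%d", 1:10),
                  significant = c(rep(TRUE, 3), rep(FALSE, 5), TRUE, TRUE))
  ov <- deg_overlap(a, b)
  expect_equal(ov$n_shared, 3)
  expect_equal(ov$n_a_only, 3)
  expect_equal(ov$pct_shared_of_a, pct(3, 6))
  empty <- data.frame(feature_id = a$feature_id, significant = FALSE)
  expect_true(is.na(deg_overlap(empty, empty)$pct_shared_of_a))
})

test_that("pct rounds half away from zero and handles zero denominators", {
  expect_equal(pct(1, 8), 13)       # 12.5 -> 13
  expect_equal(pct(0, 10), 0)
  expect_equal(pct(-1, 8), -13)
  expect_true(is.na(pct(5, 0)))
})
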