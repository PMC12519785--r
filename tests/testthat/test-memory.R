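test_that("condition profiles z-score correctly and flag flat genes", {
  d <- build_design(3, "TNFA")
  m <- matrix(0L, 3, 12, dimnames = list(c("flat", "osc", "big"), d$sample_id))
  m["flat", ] <- 50L
  m["osc", ] <- ifelse(d$condition %in% c("HIT1", "HIT2"), 400L, 100L)
  m["big", ] <- ifelse(d$condition %in% c("HIT1", "HIT2"), 800L, 200L)
  sf <- setNames(rep(1, 12), d$sample_id)
  pr <- condition_profiles(m, d, sf)
  zc <- paste0("z_", c("CTRL1", "HIT1", "CTRL2", "HIT2"))

  expect_true(pr$flat[pr$gene_id == "flat"])
  expect_equal(unlist(pr[pr$gene_id == "flat", zc]), setNames(rep(0, 4), zc))

  z <- unlist(pr[pr$gene_id == "osc", zc])
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_equal(z[[2]], z[[4]], tolerance = 1e-12)
  expect_equal(z[[1]], -z[[2]] * 1, tolerance = 1e-9)

  # scaling a gene leaves its z-profile (nearly) unchanged at high counts
  z_big <- unlist(pr[pr$gene_id == "big", zc])
  m2 <- m; m2["big", ] <- m["big", ] * 2L
  z_big2 <- unlist(condition_profiles(m2, d, sf)[3, zc])
  expect_equal(unname(z_big), unname(z_big2), tolerance = 0.01)
})

test_that("trajectory clustering separates anticorrelated shapes deterministically", {
  base <- rbind(c(0, 2, 0, 2), c(0, 2, 0, 2), c(2, 0, 2, 0), c(2, 0, 2, 0))
  set.seed(1)
  mat <- base[rep(1:4, each = 10), ] + matrix(rnorm(160, 0, 0.05), 40, 4)
  pr <- profiles_from_matrix(mat)
  cl <- cluster_trajectories(pr, min_cluster_size = 5, cut_height = 0.5)
  up <- cl$cluster_id[1:20]
  dn <- cl$cluster_id[21:40]
  expect_equal(length(unique(up)), 1)
  expect_equal(length(unique(dn)), 1)
  expect_false(unique(up) == unique(dn))
  # identical input -> identical assignment
  expect_identical(cl, cluster_trajectories(pr, min_cluster_size = 5, cut_height = 0.5))
  # all-flat input errors
  flat <- profiles_from_matrix(matrix(1, 5, 4))
  expect_error(cluster_trajectories(flat), "non-flat")
})

test_that("clustering is invariant to per-gene affine transforms of raw profiles", {
  set.seed(3)
  tmpl <- rbind(c(0, 2, 0, 2), c(0, 2, 1, 2), c(0, 0, 2, 0))
  mat <- tmpl[rep(1:3, each = 12), ] + matrix(rnorm(144, 0, 0.1), 36, 4)
  aff <- mat * runif(36, 0.5, 3) + runif(36, -5, 5)
  c1 <- cluster_trajectories(profiles_from_matrix(mat), min_cluster_size = 5)
  c2 <- cluster_trajectories(profiles_from_matrix(aff), min_cluster_size = 5)
  expect_identical(c1$cluster_id, c2$cluster_id)
})

test_that("archetype labelling follows the delta rule table", {
  expect_equal(label_archetype(c(0, 0, 0, 0)), "NONRESPONSIVE")
  z <- function(p) (p - mean(p)) / sd(p)
  expect_equal(label_archetype(z(c(1, 4, 2.5, 4))), "PRIMED")
  expect_equal(label_archetype(z(c(1, 4, 1, 8))), "TRAINED")
  # the eight generator templates map to their own archetypes
  templates <- list(
    TRANSIENT = c(1, 4, 1, 4), PRIMED = c(1, 4, 2, 4),
    TRAINED = c(1, 4, 1, 8), TOLERIZED = c(1, 4, 1, 1.5),
    PERSISTENT = c(1, 4, 4, 4), DELAYED = c(1, 1, 4, 1),
    SUPPRESSED = c(1, 0.25, 1, 0.25))
  for (nm in names(templates)) {
    expect_equal(label_archetype(z(log2(templates[[nm]]))), nm,
                 label = paste("template", nm))
  }
})

test_that("memory calls follow the documented precedence", {
  cns <- c("HIT1vCTRL1", "HIT2vCTRL2", "HIT2vHIT1", "CTRL2vCTRL1", "INTERACTION")
  sig <- matrix(FALSE, 7, 5, dimnames = list(NULL, cns))
  lfc <- matrix(0, 7, 5, dimnames = list(NULL, cns))
  # 1: nothing significant             -> NONRESPONSIVE
  # 2: only HIT1vCTRL1                 -> TRANSIENT
  # 3: CTRL2vCTRL1 & HIT2vHIT1 same +  -> PERSISTENT
  # 4: CTRL2vCTRL1 & HIT2vCTRL2       -> PRIMED
  # 5: interaction positive            -> TRAINED (outranks everything)
  # 6: interaction negative            -> TOLERIZED
  # 7: CTRL2vCTRL1 & HIT2vHIT1 opposite signs -> not PERSISTENT
  sig[2, "HIT1vCTRL1"] <- TRUE; lfc[2, "HIT1vCTRL1"] <- 2
  sig[3, c("CTRL2vCTRL1", "HIT2vHIT1")] <- TRUE; lfc[3, c("CTRL2vCTRL1", "HIT2vHIT1")] <- 1
  sig[4, c("CTRL2vCTRL1", "HIT2vCTRL2")] <- TRUE; lfc[4, c("CTRL2vCTRL1", "HIT2vCTRL2")] <- 1
  sig[5, c("CTRL2vCTRL1", "HIT2vCTRL2", "INTERACTION")] <- TRUE
  lfc[5, "INTERACTION"] <- 1.5
  sig[6, "INTERACTION"] <- TRUE; lfc[6, "INTERACTION"] <- -1.5
  sig[7, c("CTRL2vCTRL1", "HIT2vHIT1")] <- TRUE
  lfc[7, "CTRL2vCTRL1"] <- 1; lfc[7, "HIT2vHIT1"] <- -1
  suite <- suite_from_flags(sig, lfc)
  mc <- classify_memory(suite)
  expect_equal(mc$memory_call,
               c("NONRESPONSIVE", "TRANSIENT", "PERSISTENT", "PRIMED",
                 "TRAINED", "TOLERIZED", "NONRESPONSIVE"))
  # permuting gene order permutes calls identically
  perm <- sample(seq_len(7))
  suite_p <- do.call(rbind, lapply(split(suite, suite$contrast),
                                   function(x) x[perm, ]))
  mc_p <- classify_memory(suite_p)
  expect_equal(mc_p$memory_call, mc$memory_call[perm])
  # missing contrast errors
  expect_error(classify_memory(suite[suite$contrast != "INTERACTION", ]),
               "missing contrast")
})

test_that("planted TRAINED genes are recovered without tolerized confusions", {
  d <- build_design(5, "TNFA")
  truth <- assign_gene_classes(300, c(TRAINED = 1), seed = 21,
                               base_mean_meanlog = log(500),
                               base_mean_sdlog = 0.3)
  sim <- simulate_counts(d, truth, sim_params(seed = 42))
  fit <- restim_fit(sim$counts, d, size_factors = sim$size_factors)
  mc <- classify_memory(fit)
  expect_gt(mean(mc$memory_call == "TRAINED"), 0.5)
  expect_lt(mean(mc$memory_call == "TOLERIZED"), 0.05)
})
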