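# Paired negative-binomial differential testing over the five-contrast suite.
#
# One log-link NB GLM per feature with donor indicators + condition indicators
# and a log(size factor) offset; Wald tests of linear contrasts of the
# condition effects; BH adjustment within each contrast across all features.

CONTRAST_NAMES <- c("HIT1vCTRL1", "HIT2vCTRL2", "HIT2vHIT1",
                    "CTRL2vCTRL1", "INTERACTION")

#' Analysis configuration
#'
#' Thresholds of the differential analysis. Defaults follow the standard
#' two-hit study settings: features need a count of at least `min_count` in at
#' least `min_samples` samples; a feature is significant in a contrast when
#' `padj <= padj_threshold` and `|log2FC| >= lfc_threshold`; peaks map to genes
#' within `tss_window_bp` of a TSS; consensus peaks need `min_consensus_support`
#' supporting samples; the SNP permutation null uses `n_permutations` draws.
#'
#' @param min_count,min_samples Low-count filter (defaults 20 and 3).
#' @param padj_threshold BH-adjusted p cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 0.5).
#' @param tss_window_bp TSS window for peak-to-gene mapping (default 10000).
#' @param min_consensus_support Consensus-peak replicate support (default 5).
#' @param n_permutations Permutations for SNP enrichment (default 1000).
#' @return A list of class `restim_config`.
#' @export
restim_config <- function(min_count = 20, min_samples = 3,
                          padj_threshold = 0.05, lfc_threshold = 0.5,
                          tss_window_bp = 10000, min_consensus_support = 5,
                          n_permutations = 1000) {
  stopifnot(min_count > 0, min_samples > 0, lfc_threshold > 0,
            tss_window_bp >= 0, min_consensus_support > 0, n_permutations > 0,
            padj_threshold > 0, padj_threshold < 1)
  structure(list(min_count = min_count, min_samples = min_samples,
                 padj_threshold = padj_threshold, lfc_threshold = lfc_threshold,
                 tss_window_bp = tss_window_bp,
                 min_consensus_support = min_consensus_support,
                 n_permutations = n_permutations),
            class = "restim_config")
}

#' Remove low-count features
#'
#' Retains features with a count of at least `min_count` in at least
#' `min_samples` samples, preserving order.
#'
#' @param m Count matrix (features x samples).
#' @param config A [restim_config()].
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(m, config = restim_config()) {
  stopifnot(is.matrix(m), nrow(m) > 0)
  keep <- rowSums(m >= config$min_count) >= config$min_samples
  if (!any(keep)) stop("all features removed by the low-count filter")
  m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for features with nonzero counts in all
#' samples, each sample's factor is the median ratio of its counts to the
#' feature-wise geometric means. Falls back to total-count scaling (normalized
#' to geometric mean 1) with a warning when no feature is all-nonzero.
#'
#' @param m Count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(m) {
  stopifnot(is.matrix(m), nrow(m) > 0)
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) {
    warning("no feature with nonzero counts in all samples; using total-count scaling")
    tot <- colSums(m)
    if (any(tot == 0)) stop("sample with zero total count")
    sf <- tot / exp(mean(log(tot)))
    return(setNames(sf, colnames(m)))
  }
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  setNames(sf, colnames(m))
}

#' Per-feature dispersion by Pearson moment matching
#'
#' For each feature the NB dispersion `alpha` in `Var = mu + alpha * mu^2` is
#' chosen so that the Pearson chi-square statistic of the paired GLM fit
#' (donor + condition effects, log size factor offset) matches its residual
#' degrees of freedom: starting from a Poisson-fit moment estimate, the
#' fixed-point update `alpha <- alpha * X2(alpha) / (n - p)` is iterated with
#' the model refit at each alpha. Because the donor covariate is in the model,
#' the gene-shared donor effect does not leak into the dispersion and the
#' paired Wald test stays calibrated. Estimates are blended on the log scale
#' toward a pooled trend (the common dispersion solving total Pearson
#' chi-square = total residual df across features) to tame the noise of small
#' per-feature degrees of freedom; features with no excess variance stay at
#' the floor.
#'
#' @param m Count matrix.
#' @param size_factors Per-sample size factors.
#' @param design Design table.
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param blend Weight in `[0,1]` toward the pooled trend (default 0.8).
#' @return Named numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(m, size_factors, design, alpha_min = 1e-8,
                                blend = 0.8) {
  design <- check_design(design)
  stopifnot(ncol(m) >= 3, ncol(m) == nrow(design))
  X <- restim_model_matrix(design)
  off <- log(size_factors)
  n <- ncol(m); p <- ncol(X); df <- max(n - p, 1)
  ests <- apply(m, 1, function(y) alpha_pearson(X, y, off, alpha_min),
                simplify = FALSE)
  raw <- vapply(ests, `[[`, numeric(1), "alpha")
  if (blend > 0 && length(ests) >= 10) {
    # pooled (common-dispersion) trend: total Pearson chi-square = total df,
    # solved on the stored per-feature residuals and fitted means
    r2 <- unlist(lapply(ests, `[[`, "r2"))
    mu <- unlist(lapply(ests, `[[`, "mu"))
    Fn <- function(a) sum(r2 / (mu * (1 + a * mu))) - length(ests) * df
    trend <- if (Fn(alpha_min) <= 0) alpha_min else {
      stats::uniroot(Fn, c(alpha_min, 10), tol = 1e-8)$root
    }
    shrunk <- exp((1 - blend) * log(pmax(raw, alpha_min)) +
                    blend * log(max(trend, alpha_min)))
    # features with no excess variance stay at the floor
    shrunk[raw <= alpha_min] <- alpha_min
    raw <- shrunk
  }
  setNames(pmax(raw, alpha_min), rownames(m))
}

# Pearson-matching dispersion for one feature; returns the estimate plus the
# final squared residuals and fitted means (reused by the pooled trend)
alpha_pearson <- function(X, y, off, alpha_min = 1e-8, max_alpha = 10) {
  n <- length(y); p <- ncol(X); df <- max(n - p, 1)
  fit0 <- suppressWarnings(glm.fit(X, y, family = poisson(), offset = off))
  mu <- pmax(fit0$fitted.values, 1e-8)
  chi2_pois <- sum((y - mu)^2 / mu)
  if (chi2_pois <= df) {
    return(list(alpha = alpha_min, r2 = (y - mu)^2, mu = mu))
  }
  alpha <- min(max((n / df) * sum((y - mu)^2 - mu) / sum(mu^2), alpha_min * 10),
               max_alpha)
  beta <- fit0$coefficients
  for (it in 1:10) {
    f <- nb_irls(X, y, off, alpha, beta_init = beta, tol = 1e-8, maxit = 25)
    if (!f$ok) break
    beta <- f$beta
    mu <- f$mu
    chi2 <- sum((y - mu)^2 / (mu * (1 + alpha * mu)))
    alpha_new <- min(max(alpha * chi2 / df, alpha_min), max_alpha)
    done <- abs(log(alpha_new / alpha)) < 0.01
    alpha <- alpha_new
    if (done) break
  }
  list(alpha = alpha, r2 = (y - mu)^2, mu = mu)
}

# design matrix: intercept + donor indicators + condition indicators
restim_model_matrix <- function(design) {
  design$donor <- factor(design$donor)
  design$condition <- factor(as.character(design$condition), levels = RESTIM_CONDITIONS)
  model.matrix(~ donor + condition, data = design)
}

#' Fit the paired negative-binomial GLM for one feature
#'
#' Log-link NB regression of counts on donor + condition with a log size
#' factor offset and fixed dispersion, by iteratively reweighted least squares
#' (weights `mu / (1 + alpha * mu)`). Returns natural-log coefficients and
#' their covariance; contrast results are reported on the log2 scale by
#' [test_contrast()].
#'
#' @param y Integer counts, one per sample.
#' @param design Design table.
#' @param size_factors Per-sample size factors.
#' @param alpha NB dispersion for this feature.
#' @param tol,maxit IRLS convergence control.
#' @return A list of class `nbpair_fit`: `coefficients`, `vcov`, `fitted`,
#'   `converged`, `df_residual`.
#' @export
fit_paired_glm <- function(y, design, size_factors, alpha,
                           tol = 1e-10, maxit = 100) {
  design <- check_design(design)
  stopifnot(length(y) == nrow(design), length(size_factors) == length(y),
            alpha >= 0)
  X <- restim_model_matrix(design)
  f <- nb_irls(X, y, log(size_factors), alpha, tol = tol, maxit = maxit)
  as_nbpair_fit(f, X)
}

# package the internal IRLS result as the exported fit object
as_nbpair_fit <- function(f, X) {
  n <- nrow(X); p <- ncol(X)
  if (!f$ok) {
    return(structure(list(coefficients = setNames(rep(NA_real_, p), colnames(X)),
                          vcov = NULL, fitted = NULL, converged = FALSE,
                          df_residual = n - p), class = "nbpair_fit"))
  }
  structure(list(coefficients = setNames(f$beta, colnames(X)),
                 vcov = f$vcov, fitted = f$mu,
                 converged = f$converged && !is.null(f$vcov),
                 df_residual = n - p), class = "nbpair_fit")
}

# IRLS core for the log-link NB GLM with fixed dispersion.
# Returns beta (natural log scale), vcov, mu, convergence flags.
nb_irls <- function(X, y, off, alpha, beta_init = NULL, tol = 1e-10,
                    maxit = 100) {
  if (!is.null(beta_init) && all(is.finite(beta_init))) {
    eta <- pmin(pmax(drop(X %*% beta_init) + off, -30), 30)
    mu <- exp(eta)
    beta <- beta_init
  } else {
    mu <- pmax(y, 0.5)
    eta <- log(mu)
    beta <- NULL
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new) || any(!is.finite(beta_new))) {
      return(list(ok = FALSE))
    }
    eta <- pmin(pmax(drop(X %*% beta_new) + off, -30), 30)
    mu <- exp(eta)
    if (!is.null(beta) && max(abs(beta_new - beta)) <
        tol * (1 + max(abs(beta_new)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  w <- mu / (1 + alpha * mu)
  V <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  list(ok = TRUE, beta = beta, vcov = V, mu = mu, converged = converged)
}

#' Contrast vectors of the five-contrast suite
#'
#' Builds the coefficient vectors (over the model's condition effects, with
#' zeros on donor terms) for the five named comparisons: the single-hit
#' response (`HIT1vCTRL1`), the repeated-hit response against its own rested
#' baseline (`HIT2vCTRL2`), the direct restimulation comparison (`HIT2vHIT1`),
#' the residual/rested-baseline comparison (`CTRL2vCTRL1`) and the
#' baseline-controlled interaction `(HIT2-CTRL2)-(HIT1-CTRL1)` isolating
#' restimulation-specific response changes.
#'
#' @param coef_names Coefficient names of the fitted model.
#' @return Named list of numeric contrast vectors.
#' @export
contrast_specs <- function(coef_names) {
  zero <- setNames(numeric(length(coef_names)), coef_names)
  mk <- function(plus = character(), minus = character()) {
    v <- zero
    v[plus] <- v[plus] + 1
    v[minus] <- v[minus] - 1
    v
  }
  h1 <- "conditionHIT1"; h2 <- "conditionHIT2"; c2 <- "conditionCTRL2"
  stopifnot(all(c(h1, h2, c2) %in% coef_names))
  list(
    HIT1vCTRL1  = mk(h1),
    HIT2vCTRL2  = mk(h2, c2),
    HIT2vHIT1   = mk(h2, h1),
    CTRL2vCTRL1 = mk(c2),
    INTERACTION = mk(h2, c(c2, h1))
  )
}

#' Wald test of a linear contrast
#'
#' Computes `log2FC = c'beta / log(2)`, its standard error from the coefficient
#' covariance, the Wald statistic `c'beta / sqrt(c' Sigma c)` and a two-sided
#' normal p-value. Non-converged or singular fits yield `p = 1` with a flag.
#'
#' @param fit A fit from [fit_paired_glm()].
#' @param cvec Numeric contrast vector conformable with the coefficients.
#' @return One-row `data.frame`: `log2fc`, `se`, `stat`, `pvalue`, `flagged`.
#' @export
test_contrast <- function(fit, cvec) {
  stopifnot(inherits(fit, "nbpair_fit"))
  if (all(cvec == 0)) stop("invalid contrast: zero vector")
  if (!isTRUE(fit$converged) || is.null(fit$vcov) || anyNA(fit$coefficients)) {
    return(data.frame(log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                      pvalue = 1, flagged = TRUE))
  }
  est <- sum(cvec * fit$coefficients)
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  if (!is.finite(v) || v <= 0) {
    return(data.frame(log2fc = est / log(2), se = NA_real_, stat = NA_real_,
                      pvalue = 1, flagged = TRUE))
  }
  stat <- est / sqrt(v)
  data.frame(log2fc = est / log(2), se = sqrt(v) / log(2), stat = stat,
             pvalue = 2 * pnorm(-abs(stat)), flagged = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity, capped at 1 (via [stats::p.adjust()]).
#' Non-finite input p-values are treated as 1 with a warning.
#'
#' @param p Numeric vector of p-values in `[0,1]`.
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p))) {
    warning("non-finite p-values treated as 1")
    p[!is.finite(p)] <- 1
  }
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}
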