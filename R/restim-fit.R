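# The central model object: one paired NB fit per feature, five contrasts.

#' Fit the paired restimulation model to a count matrix
#'
#' The main fitting function. Applies the low-count filter, estimates
#' median-of-ratios size factors and per-feature dispersions, fits one paired
#' negative-binomial GLM per feature (donor + condition effects, log size
#' factor offset) and computes Wald tests for the five-contrast suite with BH
#' adjustment within each contrast across all features. Works identically for
#' gene and peak count matrices.
#'
#' @param counts Integer count matrix, features x samples. Column names must
#'   match `design$sample_id`.
#' @param design Design table from [build_design()].
#' @param config A [restim_config()].
#' @param size_factors Optional known size factors (else estimated).
#' @param dispersion Optional known per-feature dispersions (else estimated).
#' @param filter Apply the low-count filter first (default `TRUE`).
#' @return An object of class `restim_fit` with components `coefficients`
#'   (features x condition effects, log2 scale), `results` (named list of
#'   per-contrast data.frames), `size_factors`, `dispersion`, `base_mean`,
#'   `design`, `config`, `converged`.
#' @seealso [results.restim_fit()], [run_contrast_suite()]
#' @examples
#' design <- build_design(3, "TNFA")
#' truth <- assign_gene_classes(50, seed = 1)
#' sim <- simulate_counts(design, truth, sim_params(n_donors = 3, seed = 1))
#' fit <- restim_fit(sim$counts, design, restim_config(min_count = 5))
#' head(results(fit, "HIT1vCTRL1"))
#' @export
restim_fit <- function(counts, design, config = restim_config(),
                       size_factors = NULL, dispersion = NULL, filter = TRUE) {
  design <- check_design(design)
  stopifnot(is.matrix(counts), ncol(counts) == nrow(design))
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), design$sample_id)) {
    stopifnot(setequal(colnames(counts), design$sample_id))
    counts <- counts[, design$sample_id, drop = FALSE]
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (filter) counts <- filter_low_counts(counts, config)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, size_factors, design)
  } else if (length(dispersion) == 1L) {
    dispersion <- setNames(rep(dispersion, nrow(counts)), rownames(counts))
  }
  X <- restim_model_matrix(design)
  specs <- contrast_specs(colnames(X))
  cond_cols <- paste0("condition", RESTIM_CONDITIONS[-1])

  nf <- nrow(counts)
  coefs <- matrix(NA_real_, nf, length(cond_cols),
                  dimnames = list(rownames(counts), cond_cols))
  converged <- logical(nf)
  per_contrast <- lapply(specs, function(s) {
    data.frame(log2fc = rep(NA_real_, nf), se = NA_real_, stat = NA_real_,
               pvalue = rep(1, nf), flagged = FALSE,
               row.names = rownames(counts))
  })
  off <- log(size_factors)
  for (i in seq_len(nf)) {
    f <- as_nbpair_fit(nb_irls(X, counts[i, ], off, dispersion[i]), X)
    converged[i] <- isTRUE(f$converged)
    if (converged[i]) coefs[i, ] <- f$coefficients[cond_cols] / log(2)
    for (cn in names(specs)) {
      per_contrast[[cn]][i, ] <- test_contrast(f, specs[[cn]])
    }
  }
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  results <- lapply(per_contrast, function(tab) {
    tab$padj <- bh_adjust(tab$pvalue)
    tab$padj[tab$flagged] <- 1
    tab$significant <- !tab$flagged &
      tab$padj <= config$padj_threshold &
      !is.na(tab$log2fc) & abs(tab$log2fc) >= config$lfc_threshold
    data.frame(feature_id = rownames(tab), baseMean = base_mean,
               tab, row.names = NULL)
  })
  structure(list(coefficients = coefs, results = results,
                 size_factors = size_factors, dispersion = dispersion,
                 base_mean = base_mean, design = design, config = config,
                 converged = converged, n_samples = ncol(counts)),
            class = "restim_fit")
}

#' Extract contrast results from a fitted restimulation model
#'
#' @param object A `restim_fit`.
#' @param contrast One of `HIT1vCTRL1`, `HIT2vCTRL2`, `HIT2vHIT1`,
#'   `CTRL2vCTRL1`, `INTERACTION`.
#' @param ... Unused.
#' @return A `data.frame` with `feature_id`, `baseMean`, `log2fc`, `se`,
#'   `stat`, `pvalue`, `padj`, `significant`, `flagged`.
#' @export
results <- function(object, ...) UseMethod("results")

#' @rdname results
#' @export
results.restim_fit <- function(object, contrast = CONTRAST_NAMES, ...) {
  contrast <- match.arg(contrast)
  object$results[[contrast]]
}

#' @export
print.restim_fit <- function(x, ...) {
  cat("Paired negative-binomial restimulation model\n")
  cat(sprintf("  %d features, %d samples (%d donors, stimulus %s)\n",
              nrow(x$coefficients), x$n_samples,
              length(unique(x$design$donor)), x$design$stimulus[1]))
  nsig <- vapply(x$results, function(r) sum(r$significant), integer(1))
  cat(sprintf("  significant at padj<=%g, |log2FC|>=%g:\n",
              x$config$padj_threshold, x$config$lfc_threshold))
  for (cn in names(nsig)) cat(sprintf("    %-12s %d\n", cn, nsig[cn]))
  invisible(x)
}

#' @export
summary.restim_fit <- function(object, ...) {
  nsig <- vapply(object$results, function(r) sum(r$significant), integer(1))
  up <- vapply(object$results,
               function(r) sum(r$significant & r$log2fc > 0), integer(1))
  out <- data.frame(contrast = names(nsig), n_significant = as.integer(nsig),
                    n_up = as.integer(up), n_down = as.integer(nsig - up),
                    row.names = NULL)
  class(out) <- c("summary.restim_fit", "data.frame")
  out
}

#' @export
coef.restim_fit <- function(object, ...) object$coefficients

#' @export
plot.restim_fit <- function(x, contrast = CONTRAST_NAMES, ...) {
  contrast <- match.arg(contrast)
  r <- x$results[[contrast]]
  graphics::plot(r$log2fc, -log10(pmax(r$pvalue, 1e-300)),
                 pch = 20, cex = 0.4,
                 col = ifelse(r$significant, "firebrick", "grey50"),
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(p)),
                 main = contrast, ...)
  graphics::abline(v = c(-1, 1) * x$config$lfc_threshold, lty = 3)
  invisible(x)
}

#' Run the five-contrast differential suite
#'
#' Convenience wrapper over [restim_fit()] returning one long table with the
#' five contrasts stacked, BH-adjusted within each contrast.
#'
#' @inheritParams restim_fit
#' @return A `data.frame` with a `contrast` column plus the per-feature
#'   statistics of [results.restim_fit()].
#' @export
run_contrast_suite <- function(counts, design, config = restim_config(), ...) {
  fit <- restim_fit(counts, design, config, ...)
  out <- do.call(rbind, lapply(names(fit$results), function(cn) {
    cbind(contrast = cn, fit$results[[cn]])
  }))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Overlap of significant feature sets between two contrasts
#'
#' Set algebra over the `significant` flags of two contrast results on the same
#' feature universe, with integer percentages via [pct()] (e.g. the share of
#' single-hit features that remain responsive after restimulation).
#'
#' @param a,b Contrast result data.frames (same feature universe).
#' @return A list: `n_a`, `n_b`, `n_shared`, `n_a_only`, `n_b_only`,
#'   `pct_shared_of_a`, `pct_shared_of_b` (percentages `NA` when a set is
#'   empty).
#' @export
deg_overlap <- function(a, b) {
  stopifnot(setequal(a$feature_id, b$feature_id))
  sa <- a$feature_id[a$significant]
  sb <- b$feature_id[b$significant]
  shared <- length(intersect(sa, sb))
  list(n_a = length(sa), n_b = length(sb), n_shared = shared,
       n_a_only = length(sa) - shared, n_b_only = length(sb) - shared,
       pct_shared_of_a = pct(shared, length(sa)),
       pct_shared_of_b = pct(shared, length(sb)))
}
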