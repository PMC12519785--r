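# Matched-background permutation test for disease-SNP enrichment in
# differential chromatin regions.
#
# A SNP at 1-based position p overlaps a 0-based half-open peak [s, e)
# iff s < p <= e; the statistic is the number of peaks containing >= 1 SNP
# (a peak counts once regardless of its SNP count).

#' Count peaks containing at least one SNP
#'
#' @param peaks Peak data.frame (`chrom,start,end`, 0-based half-open).
#' @param catalog SNP catalog (`chrom,pos`, 1-based).
#' @param per_peak Return the per-peak logical indicator instead of its sum.
#' @return Integer count (or logical vector when `per_peak = TRUE`).
#' @export
count_peaks_with_snp <- function(peaks, catalog, per_peak = FALSE) {
  ind <- peak_snp_indicator(peaks, catalog)
  if (per_peak) ind else sum(ind)
}

peak_snp_indicator <- function(peaks, catalog) {
  if (nrow(peaks) == 0) return(logical())
  if (nrow(catalog) == 0) return(rep(FALSE, nrow(peaks)))
  gr <- peaks_to_granges(peaks)
  sgr <- GenomicRanges::GRanges(catalog$chrom,
                                IRanges::IRanges(catalog$pos, catalog$pos))
  GenomicRanges::countOverlaps(gr, sgr) > 0
}

#' Matching strata for background sampling
#'
#' Strata are the cross of target width quantile bins (default quintiles of
#' the target peak widths) and genomic feature classes (when a
#' `feature_class` column is present). Every target peak maps to exactly one
#' stratum; background peaks are assigned with the same edges.
#'
#' @param target Target peak data.frame.
#' @param n_width_bins Number of width quantile bins (default 5).
#' @return A list of class `matching_strata` with `width_edges` and `classes`.
#' @export
make_strata <- function(target, n_width_bins = 5) {
  w <- target$end - target$start
  edges <- unique(quantile(w, probs = seq(0, 1, length.out = n_width_bins + 1)))
  classes <- if ("feature_class" %in% names(target)) {
    sort(unique(target$feature_class))
  } else "ALL"
  structure(list(width_edges = edges, classes = classes),
            class = "matching_strata")
}

#' Choose matching strata that the background can support
#'
#' Tries progressively coarser matching schemes — width quintiles x feature
#' class, width tertiles x class, width-only quintiles/tertiles, then a single
#' stratum — and returns the first whose every target stratum has at least one
#' background candidate. Useful for small peak sets where the full
#' quintile-by-class cross would leave empty background strata.
#'
#' @inheritParams sample_matched_background
#' @return A `matching_strata` object.
#' @export
auto_strata <- function(target, background) {
  candidates <- list(
    make_strata(target, 5), make_strata(target, 3),
    { s <- make_strata(target, 5); s$classes <- "ALL"; s },
    { s <- make_strata(target, 3); s$classes <- "ALL"; s },
    { s <- make_strata(target, 1); s$classes <- "ALL"; s })
  for (s in candidates) {
    need <- table(stratum_of(target, s))
    have <- table(stratum_of(background, s))
    if (all(names(need) %in% names(have)) &&
        all(as.integer(have[names(need)]) >= as.integer(need))) {
      return(s)
    }
  }
  stop("background cannot cover the target under any matching scheme")
}

stratum_of <- function(peaks, strata) {
  w <- peaks$end - peaks$start
  bin <- findInterval(w, strata$width_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cls <- if ("feature_class" %in% names(peaks) &&
             !identical(strata$classes, "ALL")) {
    peaks$feature_class
  } else rep("ALL", nrow(peaks))
  paste(cls, bin, sep = ":")
}

#' Sample a size- and feature-matched background peak set
#'
#' For each stratum (width bin x feature class) of the target set, draws the
#' same number of background peaks uniformly without replacement; when a
#' stratum's background is exhausted the draw falls back to sampling with
#' replacement (with a warning). An empty background stratum is an error
#' naming the stratum.
#'
#' @param target,background Peak data.frames (disjoint sets).
#' @param strata A [make_strata()] object (built from `target` if `NULL`).
#' @param seed Optional integer seed.
#' @return Row indices into `background` of the sampled matched set.
#' @export
sample_matched_background <- function(target, background, strata = NULL,
                                      seed = NULL) {
  if (is.null(strata)) strata <- make_strata(target)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  ts <- stratum_of(target, strata)
  bs <- stratum_of(background, strata)
  need <- table(ts)
  idx <- integer(0)
  for (s in names(need)) {
    pool <- which(bs == s)
    k <- need[[s]]
    if (!length(pool)) stop(sprintf("empty background stratum '%s'", s))
    if (length(pool) >= k) {
      idx <- c(idx, pool[sample.int(length(pool), k)])
    } else {
      warning(sprintf("background stratum '%s' exhausted; sampling with replacement", s))
      idx <- c(idx, pool[sample.int(length(pool), k, replace = TRUE)])
    }
  }
  idx
}

#' Matched-background permutation test for SNP enrichment
#'
#' Tests whether catalog SNPs are over-represented in the target peak set.
#' The observed statistic is the number of target peaks containing at least
#' one SNP. The null distribution is built by repeatedly sampling matched
#' background peak sets (same stratum counts as the target) and recomputing
#' the statistic; the one-sided upper-tail empirical p-value uses a
#' pseudo-count, `p = (1 + #\{null_i >= observed\}) / (n_perm + 1)`, so it is
#' never zero. The enrichment score is `observed / mean(null)`.
#'
#' @param target,background Disjoint peak data.frames.
#' @param catalog SNP catalog (`chrom,pos,snp_id,trait_category`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param strata Optional [make_strata()] object.
#' @param stat `"peaks"` (peaks with >= 1 SNP, default) or `"snps"` (total
#'   SNPs falling in the set).
#' @return A one-row `data.frame` of class `enrichment_result`:
#'   `trait_category, observed, null_mean, null_sd, empirical_p,
#'   enrichment_score, n_perm`.
#' @export
permutation_enrichment <- function(target, background, catalog, n_perm = 1000,
                                   seed = 1L, strata = NULL,
                                   stat = c("peaks", "snps")) {
  stat <- match.arg(stat)
  if (is.null(strata)) strata <- make_strata(target)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- perm_enrich_engine(target, background, list(ALL = catalog),
                            n_perm, strata, stat)
  res$trait_category <- "ALL"
  class(res) <- c("enrichment_result", "data.frame")
  res[, c("trait_category", "observed", "null_mean", "null_sd",
          "empirical_p", "enrichment_score", "n_perm")]
}

# shared engine: one set of matched null draws reused across catalogs
perm_enrich_engine <- function(target, background, catalogs, n_perm, strata,
                               stat = "peaks") {
  value_of <- function(peaks, catalog) {
    if (stat == "peaks") {
      sum(peak_snp_indicator(peaks, catalog))
    } else {
      if (nrow(catalog) == 0 || nrow(peaks) == 0) return(0L)
      gr <- peaks_to_granges(peaks)
      sgr <- GenomicRanges::GRanges(catalog$chrom,
                                    IRanges::IRanges(catalog$pos, catalog$pos))
      sum(GenomicRanges::countOverlaps(sgr, gr) > 0)
    }
  }
  # pre-compute per-background-peak statistics per catalog for fast null sums
  bg_val <- lapply(catalogs, function(cat) {
    if (stat == "peaks") {
      as.integer(peak_snp_indicator(background, cat))
    } else {
      if (nrow(cat) == 0) rep(0L, nrow(background)) else {
        gr <- peaks_to_granges(background)
        sgr <- GenomicRanges::GRanges(cat$chrom, IRanges::IRanges(cat$pos, cat$pos))
        GenomicRanges::countOverlaps(gr, sgr)
      }
    }
  })
  draws <- replicate(n_perm,
                     sample_matched_background(target, background, strata),
                     simplify = FALSE)
  out <- lapply(names(catalogs), function(nm) {
    obs <- value_of(target, catalogs[[nm]])
    nulls <- vapply(draws, function(ix) sum(bg_val[[nm]][ix]), numeric(1))
    data.frame(observed = as.integer(obs), null_mean = mean(nulls),
               null_sd = sd(nulls),
               empirical_p = (1 + sum(nulls >= obs)) / (n_perm + 1),
               enrichment_score = if (mean(nulls) > 0) obs / mean(nulls) else NA_real_,
               n_perm = as.integer(n_perm))
  })
  do.call(rbind, out)
}

#' Per-trait-category SNP enrichment
#'
#' Runs the matched-background permutation test once per trait category using
#' only that category's SNPs. The matched null peak draws are shared across
#' categories for a given seed (coherent and cheaper). No multiplicity
#' adjustment is applied by default (set `adjust = TRUE` for BH across
#' categories).
#'
#' @inheritParams permutation_enrichment
#' @param adjust Add a BH-adjusted column across categories.
#' @return An `enrichment_result` data.frame, one row per trait category.
#' @export
enrichment_by_trait <- function(target, background, catalog, n_perm = 1000,
                                seed = 1L, strata = NULL, adjust = FALSE,
                                stat = c("peaks", "snps")) {
  stat <- match.arg(stat)
  if (!nrow(catalog)) stop("catalog has no SNPs")
  if (is.null(strata)) strata <- make_strata(target)
  cats <- sort(unique(catalog$trait_category))
  catalogs <- lapply(cats, function(tc) catalog[catalog$trait_category == tc, ])
  names(catalogs) <- cats
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- perm_enrich_engine(target, background, catalogs, n_perm, strata, stat)
  res <- cbind(trait_category = cats, res)
  res$empirical_p[res$observed == 0] <- 1
  if (adjust) res$padj <- bh_adjust(res$empirical_p)
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
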