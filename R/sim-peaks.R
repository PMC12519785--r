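# Synthetic chromatin-accessibility generator: per-sample peak calls (BED),
# a peak count matrix driven by condition multipliers, and a SNP catalog with
# optional planted excess density in a target peak class.

PEAK_CLASSES <- c("BACKGROUND", "SHARED_RESPONSIVE", "SINGLE_ONLY",
                  "REPEAT_ONLY", "PERSISTENT")

# accessibility multiplier templates (CTRL1, HIT1, CTRL2, HIT2)
PEAK_TEMPLATES <- list(
  BACKGROUND        = c(1, 1, 1, 1),
  SHARED_RESPONSIVE = c(1, 4, 1, 4),
  SINGLE_ONLY       = c(1, 4, 1, 1),
  REPEAT_ONLY       = c(1, 1, 1, 4),
  PERSISTENT        = c(1, 4, 4, 4)
)

default_peak_proportions <- function() {
  c(BACKGROUND = 0.70, SHARED_RESPONSIVE = 0.10, SINGLE_ONLY = 0.10,
    REPEAT_ONLY = 0.05, PERSISTENT = 0.05)
}

#' Genome specification for the synthetic generator
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#'   Default: two 10 Mb chromosomes.
#' @return Named numeric vector (class `genome_spec`).
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7)) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)))
  structure(chrom_lengths, class = "genome_spec")
}

# place n non-overlapping intervals of the given widths on one chromosome,
# keeping at least min_gap bp between neighbours (0-based half-open)
place_intervals <- function(n, widths, chrom_len, min_gap = 100) {
  need <- sum(widths) + (n + 1) * min_gap
  if (need > chrom_len) stop("genome too small to place peaks without overlap")
  slack <- chrom_len - need
  # random extra gaps: break slack at n+1 points via sorted uniforms
  cuts <- sort(runif(n, 0, slack))
  extra <- diff(c(0, cuts, slack))
  gaps <- min_gap + extra[seq_len(n)]
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(n)]
  data.frame(start = floor(starts), end = floor(starts) + widths)
}

#' Simulate per-sample peak calls, a peak count matrix and a peak truth table
#'
#' True consensus peaks are placed without overlap on the synthetic genome
#' (widths log-normal, median 500 bp, sigma 0.5 log-units), assigned an
#' accessibility class that drives condition multipliers of the NB counts
#' (same count model as [simulate_counts()]), and emitted in at least
#' `min_support` per-sample BED interval sets with +/- 25 bp edge jitter.
#' Decoy peaks appear in fewer than `min_support` samples so the consensus
#' rule has something to reject.
#'
#' @param n_peaks Number of true consensus peaks.
#' @param genome A [genome_spec()].
#' @param peak_class_proportions Named simplex over peak classes.
#' @param design Design table ([build_design()]).
#' @param params A [sim_params()] object (dispersion, donor effect, seed).
#' @param min_support Minimum number of samples every true peak appears in.
#' @param decoy_frac Decoy peaks as a fraction of `n_peaks`.
#' @return A list with `sample_beds` (named list of BED data.frames:
#'   `chrom,start,end,name`), `counts` (peaks x samples), `truth`
#'   (peak_id, chrom, start, end, peak_class), `size_factors`.
#' @export
simulate_peaks <- function(n_peaks, genome = genome_spec(),
                           peak_class_proportions = default_peak_proportions(),
                           design = build_design(), params = sim_params(),
                           min_support = 5, decoy_frac = 0.2) {
  design <- check_design(design)
  if (abs(sum(peak_class_proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  stopifnot(all(names(peak_class_proportions) %in% PEAK_CLASSES))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  n_decoy <- round(decoy_frac * n_peaks)
  n_all <- n_peaks + n_decoy
  # allot intervals to chromosomes proportionally to length
  alloc <- round(n_all * as.numeric(genome) / sum(as.numeric(genome)))
  alloc[1] <- n_all - sum(alloc[-1])
  widths <- pmax(50, round(rlnorm(n_all, log(500), 0.5)))
  pieces <- list(); k <- 0
  for (i in seq_along(genome)) {
    ni <- alloc[i]
    if (ni == 0) next
    w <- widths[(k + 1):(k + ni)]
    pl <- place_intervals(ni, w, as.numeric(genome)[i], min_gap = 100)
    pieces[[length(pieces) + 1]] <- data.frame(chrom = names(genome)[i], pl)
    k <- k + ni
  }
  iv <- do.call(rbind, pieces)
  # shuffle so true/decoy peaks are interleaved across the genome
  perm <- sample.int(n_all)
  iv <- iv[perm, , drop = FALSE]
  is_true <- seq_len(n_all) <= n_peaks  # after shuffle rows are random anyway
  truth <- data.frame(peak_id = sprintf("P%05d", seq_len(n_all)),
                      chrom = iv$chrom, start = iv$start, end = iv$end,
                      is_consensus_truth = is_true, stringsAsFactors = FALSE)
  truth$peak_class <- NA_character_
  truth$peak_class[is_true] <- sample(names(peak_class_proportions), n_peaks,
                                      replace = TRUE, prob = peak_class_proportions)
  truth$peak_class[!is_true] <- "DECOY"
  truth <- truth[order(truth$chrom, truth$start), ]
  rownames(truth) <- NULL

  n_s <- nrow(design)
  if (min_support > n_s) stop("min_support exceeds number of samples")
  # per-peak support: true peaks >= min_support, decoys 1..(min_support-1)
  support <- integer(nrow(truth))
  tr <- truth$peak_class != "DECOY"
  support[tr] <- sample(min_support:n_s, sum(tr), replace = TRUE)
  support[!tr] <- sample(seq_len(max(1, min_support - 1)), sum(!tr), replace = TRUE)
  member <- matrix(FALSE, nrow(truth), n_s)
  for (i in seq_len(nrow(truth))) {
    member[i, sample.int(n_s, support[i])] <- TRUE
  }
  truth$support_truth <- support

  sample_beds <- lapply(seq_len(n_s), function(s) {
    sel <- which(member[, s])
    if (!length(sel)) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character()))
    }
    jit_s <- pmin(pmax(round(rnorm(length(sel), 0, 10)), -25), 25)
    jit_e <- pmin(pmax(round(rnorm(length(sel), 0, 10)), -25), 25)
    st <- pmax(0, truth$start[sel] + jit_s)
    en <- pmax(st + 50, truth$end[sel] + jit_e)
    b <- data.frame(chrom = truth$chrom[sel], start = st, end = en,
                    name = truth$peak_id[sel], stringsAsFactors = FALSE)
    b[order(b$chrom, b$start), ]
  })
  names(sample_beds) <- design$sample_id

  # counts over true consensus peaks only (what the DE stage will see)
  ptruth <- truth[tr, ]
  mult <- t(vapply(ptruth$peak_class, function(k) PEAK_TEMPLATES[[k]], numeric(4)))
  base_mean <- pmax(rlnorm(nrow(ptruth), log(100), 0.6), 5)
  donors <- sort(unique(design$donor))
  donor_eff <- setNames(exp(rnorm(length(donors), 0, params$donor_effect_sd)), donors)
  sf <- runif(n_s, params$library_size_range[1], params$library_size_range[2])
  names(sf) <- design$sample_id
  cond_idx <- as.integer(design$condition)
  mu <- outer(base_mean, rep(1, n_s)) * mult[, cond_idx, drop = FALSE] *
    matrix(rep(donor_eff[design$donor] * sf, each = nrow(ptruth)), nrow = nrow(ptruth))
  alpha <- params$nb_dispersion
  counts <- if (alpha < 1e-12) {
    matrix(rpois(length(mu), mu), nrow = nrow(ptruth))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha), nrow = nrow(ptruth))
  }
  dimnames(counts) <- list(ptruth$peak_id, design$sample_id)
  storage.mode(counts) <- "integer"

  list(sample_beds = sample_beds, counts = counts, truth = truth,
       size_factors = sf)
}

#' Specification of the synthetic disease-SNP catalog
#'
#' @param background_density Expected SNPs per bp in non-target peaks (>= 0).
#' @param planted_fold Density multiplier (>= 1) inside target-class peaks;
#'   1 means the null holds.
#' @param trait_categories Character vector of trait labels assigned uniformly.
#' @param target_classes Peak classes receiving the planted excess (default:
#'   the dynamic classes).
#' @return A list of class `snp_enrich_spec`.
#' @export
snp_enrich_spec <- function(background_density = 2e-4, planted_fold = 1,
                            trait_categories = c("vascular_disease",
                                                 "immune_disease",
                                                 "metabolic_trait"),
                            target_classes = c("SINGLE_ONLY", "REPEAT_ONLY")) {
  if (background_density < 0) stop("background_density must be non-negative")
  if (planted_fold < 1) stop("planted_fold must be >= 1")
  structure(list(background_density = background_density,
                 planted_fold = planted_fold,
                 trait_categories = trait_categories,
                 target_classes = target_classes),
            class = "snp_enrich_spec")
}

#' Simulate a disease-SNP catalog over a peak set
#'
#' SNP counts per peak are Poisson with mean `background_density * width`,
#' multiplied by `planted_fold` for peaks whose truth class is in
#' `target_classes`. Positions are 1-based, uniform within the peak, unique
#' per peak; trait categories are assigned uniformly.
#'
#' @param peaks Peak data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and a `peak_class` column.
#' @param spec A [snp_enrich_spec()].
#' @param seed Integer seed.
#' @return A `data.frame` with `chrom`, `pos` (1-based), `snp_id`,
#'   `trait_category`.
#' @export
simulate_snp_catalog <- function(peaks, spec = snp_enrich_spec(), seed = 1L) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end", "peak_class") %in% names(peaks)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  width <- peaks$end - peaks$start
  dens <- spec$background_density *
    ifelse(peaks$peak_class %in% spec$target_classes, spec$planted_fold, 1)
  n_snp <- rpois(nrow(peaks), dens * width)
  n_snp <- pmin(n_snp, width)  # unique positions within a peak
  rows <- which(n_snp > 0)
  if (!length(rows)) {
    return(data.frame(chrom = character(), pos = integer(),
                      snp_id = character(), trait_category = character()))
  }
  pieces <- lapply(rows, function(i) {
    pos <- sort(sample.int(width[i], n_snp[i])) + peaks$start[i]  # 1-based
    data.frame(chrom = peaks$chrom[i], pos = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$snp_id <- sprintf("rs%06d", seq_len(nrow(out)))
  out$trait_category <- sample(spec$trait_categories, nrow(out), replace = TRUE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
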