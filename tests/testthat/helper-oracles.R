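# Independent oracles and small fixture builders used across the suite.

# base-resolution brute-force consensus: for every bp position, how many
# distinct samples cover it; regions are maximal runs of coverage >= 1 and
# support is the max per-sample presence over the region (region-level:
# a sample supports a region if it contributes >= 1 bp)
brute_consensus <- function(sample_beds, min_support, genome_len = 2000,
                            chrom = "chrZ") {
  covered <- rep(FALSE, genome_len)
  for (b in sample_beds) {
    for (i in seq_len(nrow(b))) {
      if (b$chrom[i] != chrom) next
      covered[(b$start[i] + 1):b$end[i]] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  if (!nrow(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer()))
  }
  out$chrom <- chrom
  out$support <- vapply(seq_len(nrow(out)), function(i) {
    sum(vapply(sample_beds, function(b) {
      any(b$chrom == chrom & b$start < out$end[i] & b$end > out$start[i])
    }, logical(1)))
  }, integer(1))
  out <- out[out$support >= min_support, c("chrom", "start", "end", "support")]
  rownames(out) <- NULL
  out
}

# random per-sample interval sets on one small chromosome
random_interval_sets <- function(n_samples, max_intervals = 10,
                                 genome_len = 2000, chrom = "chrZ") {
  lapply(seq_len(n_samples), function(s) {
    k <- sample.int(max_intervals, 1)
    start <- sample.int(genome_len - 60, k)
    width <- sample(5:50, k, replace = TRUE)
    data.frame(chrom = chrom, start = start,
               end = pmin(start + width, genome_len),
               name = sprintf("s%d_p%d", s, seq_len(k)))
  })
}

# all-pairs brute-force count of peaks containing >= 1 SNP
# (SNP pos p, 1-based, is inside 0-based half-open [s, e) iff s < p <= e)
brute_peaks_with_snp <- function(peaks, catalog) {
  sum(vapply(seq_len(nrow(peaks)), function(i) {
    any(catalog$chrom == peaks$chrom[i] &
          catalog$pos > peaks$start[i] & catalog$pos <= peaks$end[i])
  }, logical(1)))
}

# brute-force feature-class annotation with explicit windows; class precedence
# applies across the whole annotation set (any promoter hit beats any TTS hit)
brute_annotate <- function(peaks, anno) {
  ov <- function(ps, pe, ws, we) ps + 1 <= we & pe >= ws  # 1-based closed vs peak
  vapply(seq_len(nrow(peaks)), function(i) {
    hit_prom <- hit_tts <- hit_gen <- FALSE
    for (j in seq_len(nrow(anno))) {
      if (anno$chrom[j] != peaks$chrom[i]) next
      plus <- anno$strand[j] == "+"
      pr <- if (plus) c(anno$tss[j] - 1000, anno$tss[j] + 100)
            else c(anno$tss[j] - 100, anno$tss[j] + 1000)
      tt <- if (plus) c(anno$tts[j] - 100, anno$tts[j] + 1000)
            else c(anno$tts[j] - 1000, anno$tts[j] + 100)
      gb <- c(min(anno$tss[j], anno$tts[j]), max(anno$tss[j], anno$tts[j]))
      hit_prom <- hit_prom || ov(peaks$start[i], peaks$end[i], max(pr[1], 1), pr[2])
      hit_tts <- hit_tts || ov(peaks$start[i], peaks$end[i], max(tt[1], 1), tt[2])
      hit_gen <- hit_gen || ov(peaks$start[i], peaks$end[i], gb[1], gb[2])
    }
    if (hit_prom) "PROMOTER_TSS" else if (hit_tts) "TTS"
    else if (hit_gen) "GENIC" else "INTERGENIC"
  }, character(1))
}

# build a condition_profiles()-shaped frame from a raw profile matrix
# (rows = genes, columns = CTRL1, HIT1, CTRL2, HIT2)
profiles_from_matrix <- function(mat, gene_ids = sprintf("G%05d", seq_len(nrow(mat)))) {
  s <- apply(mat, 1, sd)
  mu <- rowMeans(mat)
  flat <- s < 1e-12
  z <- (mat - mu) / ifelse(flat, 1, s)
  z[flat, ] <- 0
  out <- data.frame(gene_id = gene_ids, mat, z, flat = flat, row.names = NULL)
  names(out) <- c("gene_id", paste0("mean_", c("CTRL1", "HIT1", "CTRL2", "HIT2")),
                  paste0("z_", c("CTRL1", "HIT1", "CTRL2", "HIT2")), "flat")
  out
}

# non-overlapping random peak universe on one chromosome, with classes
random_peak_universe <- function(n_peaks, target_class_frac = 0.25,
                                 chrom = "chrU") {
  widths <- pmax(100, round(rlnorm(n_peaks, log(500), 0.5)))
  gaps <- 200 + rpois(n_peaks, 300)
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_peaks)]
  cls <- ifelse(runif(n_peaks) < target_class_frac, "SINGLE_ONLY", "BACKGROUND")
  data.frame(chrom = chrom, start = starts, end = starts + widths,
             name = sprintf("u%05d", seq_len(n_peaks)),
             peak_class = cls, stringsAsFactors = FALSE)
}

# a small suite table (classify_memory input) built from explicit flags
suite_from_flags <- function(sig, lfc) {
  ids <- sprintf("G%03d", seq_len(nrow(sig)))
  do.call(rbind, lapply(colnames(sig), function(cn) {
    data.frame(contrast = cn, feature_id = ids, baseMean = 100,
               log2fc = lfc[, cn], se = 0.1, stat = lfc[, cn] / 0.1,
               pvalue = ifelse(sig[, cn], 1e-6, 0.9),
               flagged = FALSE, padj = ifelse(sig[, cn], 1e-5, 0.95),
               significant = sig[, cn])
  }))
}
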