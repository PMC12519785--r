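# Consensus accessibility peaks, DOR categorization, genomic-feature
# annotation and TSS-window peak-to-gene mapping.
#
# Coordinates are 0-based half-open internally (BED convention); GRanges
# conversion (+1 on start) happens at the boundary.

#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

peaks_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Read / write BED intervals
#'
#' `read_bed()` parses a 3+ column tab-delimited BED file (0-based half-open)
#' into a data.frame `chrom,start,end,name`; malformed lines raise an error
#' naming the line. `write_bed()` writes intervals sorted by (chrom, start),
#' without header, so a round trip is lossless for BED3+name.
#'
#' @param path File path.
#' @param intervals Data.frame with `chrom`, `start`, `end` and optional `name`.
#' @return `read_bed()` returns the interval data.frame; `write_bed()` the path.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e)) stop(sprintf("malformed BED line %d: non-integer coordinates", i))
    if (s < 0 || e <= s) stop(sprintf("malformed BED line %d: need 0 <= start < end", i))
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end = as.integer(vapply(parts, `[`, "", 3)),
    name = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""),
    stringsAsFactors = FALSE)
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  df <- intervals[order(intervals$chrom, intervals$start),
                  intersect(c("chrom", "start", "end", "name"), names(intervals)),
                  drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build consensus peaks from per-sample peak calls
#'
#' Merges the union of all per-sample intervals into maximal connected
#' regions, counts for each region the number of distinct samples contributing
#' at least 1 bp of overlapping call, and retains regions supported by at
#' least `min_support` samples (e.g. "present in a minimum of 5 biological
#' replicates"). Merged bounds are reported.
#'
#' @param sample_beds List of interval data.frames (`chrom,start,end`), one
#'   per sample.
#' @param min_support Minimum replicate support.
#' @return A `data.frame` `chrom,start,end,name,support` sorted by position;
#'   empty input yields an empty frame.
#' @export
consensus_peaks <- function(sample_beds, min_support = 5) {
  stopifnot(is.list(sample_beds))
  nonempty <- Filter(function(b) nrow(b) > 0, sample_beds)
  if (!length(nonempty)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), support = integer()))
  }
  if (length(sample_beds) < min_support) {
    stop("fewer sample sets than min_support")
  }
  all_gr <- do.call(c, lapply(nonempty, peaks_to_granges))
  merged <- GenomicRanges::reduce(all_gr)
  support <- integer(length(merged))
  for (b in nonempty) {
    hits <- GenomicRanges::findOverlaps(merged, peaks_to_granges(b))
    support[unique(S4Vectors::queryHits(hits))] <-
      support[unique(S4Vectors::queryHits(hits))] + 1L
  }
  keep <- support >= min_support
  merged <- merged[keep]; support <- support[keep]
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    support = support, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  out$name <- sprintf("consensus_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "support")]
}

#' Categorize differential open regions as shared or dynamic
#'
#' Given differential results for the single-stimulation contrast
#' (`HIT1vCTRL1`) and the repeated-stimulation contrast (`HIT2vCTRL2`) on the
#' same peak universe, assigns each peak `SHARED` (significant in both),
#' `SINGLE_ONLY`, `REPEAT_ONLY` or `NONDIFFERENTIAL`. Dynamic regions are the
#' symmetric difference (`SINGLE_ONLY` or `REPEAT_ONLY`). Summaries include
#' the shared set as an integer percentage of each total.
#'
#' @param single_res,repeat_res Contrast result data.frames.
#' @return A list with `table` (peak_id, category, dynamic) and `summary`
#'   (counts plus `pct_shared_of_single`, `pct_shared_of_repeat`).
#' @export
categorize_dors <- function(single_res, repeat_res) {
  if (!setequal(single_res$feature_id, repeat_res$feature_id)) {
    stop("peak universes differ between the two contrasts")
  }
  repeat_res <- repeat_res[match(single_res$feature_id, repeat_res$feature_id), ]
  s1 <- single_res$significant
  s2 <- repeat_res$significant
  category <- ifelse(s1 & s2, "SHARED",
                     ifelse(s1, "SINGLE_ONLY",
                            ifelse(s2, "REPEAT_ONLY", "NONDIFFERENTIAL")))
  tab <- data.frame(peak_id = single_res$feature_id, category = category,
                    dynamic = category %in% c("SINGLE_ONLY", "REPEAT_ONLY"),
                    stringsAsFactors = FALSE)
  n_shared <- sum(s1 & s2)
  summary <- list(
    n_single = sum(s1), n_repeat = sum(s2), n_shared = n_shared,
    n_single_only = sum(s1 & !s2), n_repeat_only = sum(!s1 & s2),
    n_dynamic = sum(xor(s1, s2)),
    pct_shared_of_single = pct(n_shared, sum(s1)),
    pct_shared_of_repeat = pct(n_shared, sum(s2)))
  list(table = tab, summary = summary)
}

# strand-oriented promoter/TTS windows (HOMER convention: -1 kb / +100 bp
# around the TSS in the direction of transcription, mirrored for the TTS)
gene_windows <- function(annotation) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tts") %in% names(annotation)))
  plus <- annotation$strand == "+"
  prom_s <- ifelse(plus, annotation$tss - 1000, annotation$tss - 100)
  prom_e <- ifelse(plus, annotation$tss + 100, annotation$tss + 1000)
  tts_s <- ifelse(plus, annotation$tts - 100, annotation$tts - 1000)
  tts_e <- ifelse(plus, annotation$tts + 1000, annotation$tts + 100)
  list(promoter = data.frame(chrom = annotation$chrom, start = pmax(prom_s, 1), end = prom_e),
       tts = data.frame(chrom = annotation$chrom, start = pmax(tts_s, 1), end = tts_e),
       genic = data.frame(chrom = annotation$chrom,
                          start = pmin(annotation$tss, annotation$tts),
                          end = pmax(annotation$tss, annotation$tts)))
}

#' Annotate peaks to genomic feature classes
#'
#' Assigns each peak the first matching class in the precedence
#' `PROMOTER_TSS` (overlap with the strand-oriented -1 kb/+100 bp TSS window),
#' `TTS` (mirrored window at the termination site), `GENIC` (gene body),
#' else `INTERGENIC`.
#'
#' @param peaks Peak data.frame (`chrom,start,end`, 0-based half-open).
#' @param annotation Gene annotation data.frame (`gene_id, chrom, strand, tss,
#'   tts`; positions 1-based).
#' @return Character vector of feature classes, one per peak.
#' @export
annotate_features <- function(peaks, annotation) {
  if (nrow(peaks) == 0) return(character())
  gr <- peaks_to_granges(peaks)
  win <- gene_windows(annotation)
  ov <- function(w) {
    wgr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end))
    unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, wgr)))
  }
  cls <- rep("INTERGENIC", nrow(peaks))
  cls[ov(win$genic)] <- "GENIC"
  cls[ov(win$tts)] <- "TTS"
  cls[ov(win$promoter)] <- "PROMOTER_TSS"
  cls
}

#' Map peaks to genes by TSS window
#'
#' Emits a (peak, gene) link whenever the peak interval overlaps
#' `[tss - window_bp, tss + window_bp]` (default +/- 10 kb). A peak can link
#' to several genes and vice versa.
#'
#' @param peaks Peak data.frame with a `name` column (0-based half-open).
#' @param annotation Gene annotation (`gene_id, chrom, tss`; 1-based).
#' @param window_bp Window half-width in bp (>= 0).
#' @return A `data.frame` with `peak_id`, `gene_id`, `distance_bp` (peak edge
#'   to TSS, 0 when the peak covers the TSS).
#' @export
map_dor_to_genes <- function(peaks, annotation, window_bp = 10000) {
  stopifnot(window_bp >= 0)
  if (nrow(peaks) == 0 || nrow(annotation) == 0) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance_bp = integer()))
  }
  gr <- peaks_to_granges(peaks)
  wgr <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(pmax(annotation$tss - window_bp, 1),
                                                 annotation$tss + window_bp))
  hits <- GenomicRanges::findOverlaps(gr, wgr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  tss <- annotation$tss[si]
  dist <- pmax(0, pmax(peaks$start[qi] + 1 - tss, tss - peaks$end[qi]))
  out <- data.frame(peak_id = peaks$name[qi], gene_id = annotation$gene_id[si],
                    distance_bp = as.integer(dist), stringsAsFactors = FALSE)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

#' Simulate a gene annotation table for the synthetic genome
#'
#' Places genes uniformly with random strand; gene lengths log-normal
#' (median 20 kb). TSS/TTS follow strand orientation.
#'
#' @param n_genes Number of genes.
#' @param genome A [genome_spec()].
#' @param seed Integer seed.
#' @return A `data.frame` `gene_id, chrom, strand, tss, tts` (1-based).
#' @export
simulate_annotation <- function(n_genes, genome = genome_spec(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chrom <- sample(names(genome), n_genes, replace = TRUE,
                  prob = as.numeric(genome))
  len <- pmax(500, round(rlnorm(n_genes, log(2e4), 0.8)))
  maxpos <- as.numeric(genome)[match(chrom, names(genome))]
  start <- floor(runif(n_genes, 1, pmax(2, maxpos - len)))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- ifelse(strand == "+", start, start + len)
  tts <- ifelse(strand == "+", start + len, start)
  out <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                    chrom = chrom, strand = strand,
                    tss = as.integer(tss), tts = as.integer(tts),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, pmin(out$tss, out$tts)), ]
}
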