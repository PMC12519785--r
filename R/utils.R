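#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rnorm runif rpois rbinom median quantile sd cor
#'   hclust cutree as.dist pnorm p.adjust model.matrix lm.wfit glm.fit poisson
#'   rlnorm setNames aggregate complete.cases ks.test
#' @importFrom utils read.delim write.table head modifyList
NULL

# condition levels, in experimental order
RESTIM_CONDITIONS <- c("CTRL1", "HIT1", "CTRL2", "HIT2")
RESTIM_STIMULI <- c("TNFA", "IFNG")

#' Integer percentage with round-half-away-from-zero
#'
#' Computes `100 * x / n` rounded to the nearest integer, rounding halves away
#' from zero (the convention used throughout reported overlap summaries, e.g.
#' 52 of 113 shared genes is 46%). Returns `NA` when `n` is zero.
#'
#' @param x Numerator count (non-negative).
#' @param n Denominator count.
#' @return Integer percentage, or `NA_real_` if `n == 0`.
#' @examples
#' pct(52, 113)   # 46
#' pct(61, 113)   # 54
#' @export
pct <- function(x, n) {
  stopifnot(length(x) == length(n))
  out <- ifelse(n == 0, NA_real_, {
    r <- 100 * x / n
    sign(r) * floor(abs(r) + 0.5)
  })
  as.numeric(out)
}

#' Derive a per-stage random seed from a global seed
#'
#' Stages of the pipeline draw from deterministic substreams so that each stage
#' is reproducible in isolation. The stage name is hashed (polynomial rolling
#' hash over UTF-8 code points) and mixed with the global seed modulo a prime
#' below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name, a character scalar.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483629  # prime < 2^31
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m + 1)
}

# write a data.frame as UTF-8 TSV with '.' for missing
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    if (anyNA(v)) {
      v <- as.character(v)
      v[is.na(v)] <- "."
      df2[[j]] <- v
    }
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = ".", ...)
}

# counts matrix TSV: feature ids in first column, sample ids as header
write_counts_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

read_counts_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
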