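#' Build a two-hit stimulation design table
#'
#' Constructs the sample sheet for a repeated-stimulation experiment: each donor
#' contributes one sample per condition, where the four conditions are the
#' never-stimulated control (`CTRL1`), a single acute stimulation (`HIT1`), a
#' stimulated-then-rested control (`CTRL2`) and a restimulation after rest
#' (`HIT2`). The paired layout is what lets the negative-binomial model absorb
#' donor-to-donor baseline differences.
#'
#' @param n_donors Number of donors (at least 2; the default study uses 5).
#' @param stimulus Stimulus label, `"TNFA"` or `"IFNG"`.
#' @return A `data.frame` with columns `sample_id`, `donor`, `condition`
#'   (factor with levels `CTRL1, HIT1, CTRL2, HIT2`) and `stimulus`, one row
#'   per donor x condition.
#' @examples
#' d <- build_design(5, "TNFA")
#' nrow(d)  # 20
#' @export
build_design <- function(n_donors = 5, stimulus = c("TNFA", "IFNG")) {
  stimulus <- match.arg(stimulus)
  if (!is.numeric(n_donors) || n_donors < 2) {
    stop("n_donors must be >= 2: a paired model is unfittable with one donor")
  }
  n_donors <- as.integer(n_donors)
  donors <- sprintf("D%02d", seq_len(n_donors))
  df <- expand.grid(donor = donors, condition = RESTIM_CONDITIONS,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$condition <- factor(df$condition, levels = RESTIM_CONDITIONS)
  df$stimulus <- stimulus
  df$sample_id <- paste(df$donor, df$condition, stimulus, sep = "_")
  df <- df[order(df$condition, df$donor), c("sample_id", "donor", "condition", "stimulus")]
  rownames(df) <- NULL
  df
}

# validate a design table (from build_design or read from file)
check_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "donor", "condition") %in% names(design)))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_ids in design")
  design$condition <- factor(as.character(design$condition), levels = RESTIM_CONDITIONS)
  if (anyNA(design$condition)) stop("unknown condition label in design")
  tab <- table(design$donor, design$condition)
  if (!all(tab == 1L)) stop("each donor must appear exactly once per condition")
  if (nrow(tab) < 2L) stop("need >= 2 donors")
  design
}
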