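# Synthetic gene-expression generator with planted memory classes.
#
# The generator emulates the structure of a two-hit cytokine restimulation
# RNA-seq study: 5 donors x 4 conditions per stimulus, negative-binomial
# counts with a gene-shared multiplicative donor effect, and per-gene
# condition-multiplier templates encoding memory-like trajectory archetypes.

MEMORY_CLASSES <- c("NONRESPONSIVE", "TRANSIENT", "PRIMED", "TRAINED",
                    "TOLERIZED", "PERSISTENT", "DELAYED", "SUPPRESSED")

# multiplier templates (CTRL1, HIT1, CTRL2, HIT2) per archetype
MEMORY_TEMPLATES <- list(
  NONRESPONSIVE = c(1, 1,    1, 1),
  TRANSIENT     = c(1, 4,    1, 4),
  PRIMED        = c(1, 4,    2, 4),
  TRAINED       = c(1, 4,    1, 8),
  TOLERIZED     = c(1, 4,    1, 1.5),
  PERSISTENT    = c(1, 4,    4, 4),
  DELAYED       = c(1, 1,    4, 1),
  SUPPRESSED    = c(1, 0.25, 1, 0.25)
)

default_class_proportions <- function() {
  c(NONRESPONSIVE = 0.65, TRANSIENT = 0.10, PRIMED = 0.05, TRAINED = 0.05,
    TOLERIZED = 0.05, PERSISTENT = 0.04, DELAYED = 0.03, SUPPRESSED = 0.03)
}

#' Simulation parameters for synthetic restimulation counts
#'
#' Bundles the knobs of the negative-binomial count generator. Defaults are the
#' package's canonical study conditions: 5 donors, dispersion `alpha = 0.1`
#' (Var = mu + alpha * mu^2), a gene-shared log-normal donor effect with
#' sd 0.3 log-units, and per-sample library size factors drawn uniformly from
#' `library_size_range`.
#'
#' @param n_donors Number of donors.
#' @param n_genes Number of genes to simulate.
#' @param nb_dispersion NB dispersion alpha (>= 0).
#' @param donor_effect_sd SD of the donor log-effect (>= 0).
#' @param library_size_range Length-2 positive range for sample size factors.
#' @param class_proportions Named simplex over memory classes (sums to 1).
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_donors = 5, n_genes = 2000, nb_dispersion = 0.1,
                       donor_effect_sd = 0.3, library_size_range = c(0.7, 1.3),
                       class_proportions = default_class_proportions(),
                       seed = 1L) {
  stopifnot(nb_dispersion >= 0, donor_effect_sd >= 0,
            length(library_size_range) == 2, all(library_size_range > 0))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (!all(names(class_proportions) %in% MEMORY_CLASSES)) {
    stop("unknown memory class in class_proportions")
  }
  structure(list(n_donors = n_donors, n_genes = n_genes,
                 nb_dispersion = nb_dispersion, donor_effect_sd = donor_effect_sd,
                 library_size_range = library_size_range,
                 class_proportions = class_proportions, seed = as.integer(seed)),
            class = "sim_params")
}

#' Assign planted memory classes and expression templates to genes
#'
#' Draws a memory class per gene from `class_proportions`, attaches the class's
#' condition-multiplier template and a log-normal baseline expression level.
#' The returned truth table is what downstream recovery tests score against.
#'
#' @param n_genes Number of genes (> 0).
#' @param class_proportions Named simplex over memory classes.
#' @param seed Integer seed; the same seed yields an identical table.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-gene baseline expected count (defaults: median 200, sdlog 1).
#' @return A `data.frame` with `gene_id`, `memory_class`, `base_mean` and the
#'   four multiplier columns `mult_CTRL1 .. mult_HIT2`.
#' @export
assign_gene_classes <- function(n_genes, class_proportions = default_class_proportions(),
                                seed = 1L, base_mean_meanlog = log(200),
                                base_mean_sdlog = 1) {
  if (!is.numeric(n_genes) || n_genes <= 0) stop("n_genes must be positive")
  n_genes <- as.integer(n_genes)
  if (abs(sum(class_proportions) - 1) > 1e-9) stop("class_proportions must sum to 1")
  cls <- names(class_proportions)
  if (!all(cls %in% MEMORY_CLASSES)) stop("unknown memory class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  klass <- sample(cls, n_genes, replace = TRUE, prob = class_proportions)
  base_mean <- pmax(rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog), 1)
  mult <- t(vapply(klass, function(k) MEMORY_TEMPLATES[[k]], numeric(4)))
  colnames(mult) <- paste0("mult_", RESTIM_CONDITIONS)
  out <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                    memory_class = klass, base_mean = base_mean,
                    mult, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a negative-binomial count matrix from a design and truth table
#'
#' Counts are drawn as
#' `NB(mean = base_mean * condition_multiplier * donor_effect * size_factor,
#' dispersion alpha)` with `donor_effect = exp(N(0, donor_effect_sd))` shared
#' across genes within a donor, so the paired model has something to absorb.
#'
#' @param design Design table from [build_design()].
#' @param truth Truth table from [assign_gene_classes()].
#' @param params A [sim_params()] object.
#' @return A list with `counts` (integer matrix genes x samples),
#'   `size_factors` and `donor_effects` (both the simulated truth).
#' @export
simulate_counts <- function(design, truth, params = sim_params()) {
  design <- check_design(design)
  if (!is.data.frame(truth) || nrow(truth) == 0) stop("empty truth table")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  n_g <- nrow(truth); n_s <- nrow(design)
  donors <- sort(unique(design$donor))
  donor_eff <- setNames(exp(rnorm(length(donors), 0, params$donor_effect_sd)), donors)
  sf <- runif(n_s, params$library_size_range[1], params$library_size_range[2])
  names(sf) <- design$sample_id
  mult <- as.matrix(truth[, paste0("mult_", RESTIM_CONDITIONS)])
  cond_idx <- as.integer(design$condition)
  mu <- outer(truth$base_mean, rep(1, n_s)) * mult[, cond_idx, drop = FALSE] *
    matrix(rep(donor_eff[design$donor] * sf, each = n_g), nrow = n_g)
  alpha <- params$nb_dispersion
  if (alpha < 1e-12) {
    counts <- matrix(rpois(n_g * n_s, lambda = mu), nrow = n_g)
  } else {
    counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = 1 / alpha), nrow = n_g)
  }
  dimnames(counts) <- list(truth$gene_id, design$sample_id)
  storage.mode(counts) <- "integer"
  list(counts = counts, size_factors = sf, donor_effects = donor_eff)
}

# save/restore the global RNG state so generators are pure in (inputs, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
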