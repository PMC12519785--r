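# End-to-end orchestration: simulate -> differential expression -> memory
# classification -> consensus/differential chromatin -> SNP enrichment,
# with seeded per-stage substreams and a machine-readable report.

#' Write a full set of synthetic inputs to a directory
#'
#' Generates the sample sheet, gene counts, per-sample peak BEDs, peak counts,
#' gene annotation, SNP catalog and truth tables for one stimulus, all seeded
#' via [stage_seed()] so reruns are byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param stimulus `"TNFA"` or `"IFNG"`.
#' @param n_genes,n_peaks Problem sizes.
#' @param params A [sim_params()] template (its seed field is overridden by
#'   the stage substream).
#' @param snp_spec A [snp_enrich_spec()].
#' @param config A [restim_config()].
#' @return Invisibly, a manifest list of written files with md5 checksums.
#' @export
simulate_inputs <- function(outdir, seed = 42L, stimulus = "TNFA",
                            n_genes = 2000, n_peaks = 1000,
                            params = sim_params(),
                            snp_spec = snp_enrich_spec(),
                            config = restim_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- build_design(params$n_donors, stimulus)
  gtruth <- assign_gene_classes(n_genes, params$class_proportions,
                                seed = stage_seed(seed, "gene_truth"))
  p_genes <- params; p_genes$seed <- stage_seed(seed, "gene_counts")
  gsim <- simulate_counts(design, gtruth, p_genes)
  p_peaks <- params; p_peaks$seed <- stage_seed(seed, "peaks")
  psim <- simulate_peaks(n_peaks, design = design, params = p_peaks,
                         min_support = config$min_consensus_support)
  anno <- simulate_annotation(round(n_genes / 2),
                              seed = stage_seed(seed, "annotation"))
  snps <- simulate_snp_catalog(psim$truth[psim$truth$peak_class != "DECOY", ],
                               snp_spec, seed = stage_seed(seed, "snps"))

  paths <- list(
    sample_sheet = file.path(outdir, "sample_sheet.tsv"),
    gene_counts = file.path(outdir, "gene_counts.tsv"),
    peak_counts = file.path(outdir, "peak_counts.tsv"),
    gene_truth = file.path(outdir, "gene_truth.tsv"),
    peak_truth = file.path(outdir, "peak_truth.tsv"),
    annotation = file.path(outdir, "gene_annotation.tsv"),
    snp_catalog = file.path(outdir, "snp_catalog.tsv"))
  write_tsv(design, paths$sample_sheet)
  write_counts_tsv(gsim$counts, paths$gene_counts)
  write_counts_tsv(psim$counts, paths$peak_counts)
  write_tsv(gtruth, paths$gene_truth)
  write_tsv(psim$truth, paths$peak_truth)
  write_tsv(anno, paths$annotation)
  write_tsv(snps, paths$snp_catalog)
  bed_dir <- file.path(outdir, "peaks_by_sample")
  dir.create(bed_dir, showWarnings = FALSE)
  for (s in names(psim$sample_beds)) {
    p <- file.path(bed_dir, paste0(s, ".bed"))
    write_bed(psim$sample_beds[[s]], p)
    paths[[paste0("bed_", s)]] <- p
  }
  manifest <- list(seed = seed, stimulus = stimulus,
                   files = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full restimulation analysis pipeline on a directory of inputs
#'
#' Stages: load inputs; gene-level five-contrast differential testing and
#' memory classification; trajectory clustering; consensus-peak construction
#' from the per-sample BEDs; peak-level differential testing restricted to
#' consensus regions; shared/dynamic DOR categorization; feature annotation
#' and TSS-window gene mapping; matched-background SNP enrichment of the
#' dynamic and shared DOR sets. Writes one TSV per stage plus `report.json`
#' (deterministic for a fixed seed: no timestamps in the report).
#'
#' @param indir Directory produced by [simulate_inputs()] (or user data in
#'   the same layout).
#' @param outdir Output directory.
#' @param seed Global integer seed (drives the permutation stage).
#' @param config A [restim_config()].
#' @return The report, invisibly, as a named list.
#' @export
run_pipeline <- function(indir, outdir = file.path(indir, "results"),
                         seed = 42L, config = restim_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- check_design(read_tsv(file.path(indir, "sample_sheet.tsv")))
  gene_counts <- read_counts_tsv(file.path(indir, "gene_counts.tsv"))
  peak_counts <- read_counts_tsv(file.path(indir, "peak_counts.tsv"))
  anno <- read_tsv(file.path(indir, "gene_annotation.tsv"))
  snps <- read_tsv(file.path(indir, "snp_catalog.tsv"))

  message("stage: gene differential testing")
  gfit <- restim_fit(gene_counts, design, config)
  for (cn in CONTRAST_NAMES) {
    write_tsv(results(gfit, cn), file.path(outdir, paste0("genes_", cn, ".tsv")))
  }
  memory <- classify_memory(gfit)
  write_tsv(memory, file.path(outdir, "memory_calls.tsv"))

  message("stage: trajectory clustering")
  deg_any <- unique(unlist(lapply(gfit$results, function(r)
    r$feature_id[r$significant])))
  deg_counts <- gene_counts[rownames(gene_counts) %in% deg_any, , drop = FALSE]
  profiles <- if (nrow(deg_counts)) {
    condition_profiles(deg_counts, design, gfit$size_factors)
  } else {
    data.frame(flat = logical())
  }
  clusters <- if (sum(!profiles$flat) >= 2) {
    cluster_trajectories(profiles)
  } else {
    data.frame(gene_id = character(), cluster_id = integer(),
               archetype = character())
  }
  write_tsv(clusters, file.path(outdir, "clusters.tsv"))

  message("stage: consensus peaks and differential accessibility")
  bed_dir <- file.path(indir, "peaks_by_sample")
  beds <- lapply(list.files(bed_dir, pattern = "\\.bed$", full.names = TRUE),
                 read_bed)
  cons <- consensus_peaks(beds, config$min_consensus_support)
  write_bed(cons, file.path(outdir, "consensus_peaks.bed"))
  pfit <- restim_fit(peak_counts, design, config)
  for (cn in CONTRAST_NAMES) {
    write_tsv(results(pfit, cn), file.path(outdir, paste0("peaks_", cn, ".tsv")))
  }
  dors <- categorize_dors(results(pfit, "HIT1vCTRL1"), results(pfit, "HIT2vCTRL2"))
  write_tsv(dors$table, file.path(outdir, "dor_categories.tsv"))

  message("stage: annotation and peak-to-gene mapping")
  peak_truth <- read_tsv(file.path(indir, "peak_truth.tsv"))
  peak_coords <- peak_truth[match(dors$table$peak_id, peak_truth$peak_id),
                            c("chrom", "start", "end")]
  peak_tab <- cbind(dors$table, peak_coords)
  peak_tab$name <- peak_tab$peak_id
  peak_tab$feature_class <- annotate_features(peak_tab, anno)
  sig_any <- peak_tab$category != "NONDIFFERENTIAL"
  links <- map_dor_to_genes(peak_tab[sig_any, , drop = FALSE], anno,
                            config$tss_window_bp)
  write_tsv(links, file.path(outdir, "dor_gene_links.tsv"))

  message("stage: SNP enrichment")
  background <- peak_tab[peak_tab$category == "NONDIFFERENTIAL", , drop = FALSE]
  enr <- list()
  for (set_name in c("dynamic", "shared")) {
    target <- if (set_name == "dynamic") {
      peak_tab[peak_tab$dynamic, , drop = FALSE]
    } else {
      peak_tab[peak_tab$category == "SHARED", , drop = FALSE]
    }
    enr[[set_name]] <- if (nrow(target) >= 5 && nrow(background) >= nrow(target)) {
      permutation_enrichment(target, background, snps,
                             n_perm = config$n_permutations,
                             seed = stage_seed(seed, paste0("enrich_", set_name)),
                             strata = auto_strata(target, background))
    } else NULL
  }
  enr_tab <- do.call(rbind, lapply(names(enr), function(nm) {
    if (is.null(enr[[nm]])) return(NULL)
    cbind(peak_set = nm, enr[[nm]])
  }))
  if (!is.null(enr_tab)) write_tsv(enr_tab, file.path(outdir, "snp_enrichment.tsv"))

  report <- list(
    seed = seed,
    stimulus = design$stimulus[1],
    n_genes_tested = nrow(coef(gfit)),
    n_peaks_tested = nrow(coef(pfit)),
    genes = list(
      n_significant = lapply(gfit$results, function(r) sum(r$significant)),
      overlap_direct = deg_overlap(results(gfit, "HIT2vHIT1"),
                                   results(gfit, "CTRL2vCTRL1")),
      memory_calls = as.list(table(memory$memory_call))),
    clusters = list(n_clusters = length(unique(stats::na.omit(clusters$cluster_id))),
                    archetypes = as.list(table(clusters$archetype))),
    peaks = list(n_consensus = nrow(cons),
                 dor_summary = dors$summary,
                 n_dor_gene_links = nrow(links)),
    snp_enrichment = lapply(enr, function(e) if (is.null(e)) NULL else
      as.list(e[1, c("observed", "null_mean", "empirical_p", "enrichment_score")]))
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Format overlap percentages the way the result summaries print them
#'
#' @param n_shared Shared count.
#' @param n_total Total counts (vector allowed).
#' @return Named numeric vector of integer percentages ([pct()]).
#' @examples
#' report_percentages(4348, c(single = 7437, repeated = 5348))  # 58, 81
#' @export
report_percentages <- function(n_shared, n_total) {
  setNames(pct(rep(n_shared, length(n_total)), n_total), names(n_total))
}
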