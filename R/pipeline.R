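## End-to-end driver on synthetic data: simulate -> annotate -> classify ->
## associate -> fit -> hotspots -> asymmetry, with a cohort summary table.
## Every stage runs through the same exported functions a user would call
## on real tracks.

#' Run the whole pipeline on a synthetic cohort
#'
#' Simulates a genome with methylation, timing, genes and two mutation
#' cohorts -- a baseline (MSS-like) cohort drawn from the configured
#' logistic law and a hypermutated "POLE-like" cohort with a steeper
#' methylation effect and higher burden -- then runs every analysis stage:
#' per-CpG annotation, sample classification, binned associations with
#' slope comparison, replication-timing stratification, nested logistic
#' model selection with AUC and vertex, per-sample slopes, stop-gain TCG
#' enumeration with methylation ranking, and origin strand asymmetry.
#'
#' @param seed Integer seed controlling every stage.
#' @param outdir Optional directory; when given, inputs, per-stage tables
#'   and a JSON report (including the exact configuration and seed) are
#'   written there.
#' @param config Optional `simulation_config` overriding the default
#'   (its seed is replaced by `seed`).
#' @return List with all stage outputs (see Details in the vignette).
#' @export
reproduce_synthetic <- function(seed, outdir = NULL, config = NULL) {
  cfg <- config %||% simulation_config(seed = seed)
  cfg$seed <- as.integer(seed)
  seeds <- derive_seeds(seed, 6)
  sim <- simulate_genome(cfg)

  ## covariates for the generative draw (M, R per CpG)
  covariates <- build_cpg_table(sim$methylation, sim$timing,
                                mutations = NULL, genome = sim$genome,
                                chroms = names(sim$genome))

  ## two cohorts from the logistic law
  b_base <- cfg$coefficients
  b_pole <- b_base + c(0, 1, 0, 0, 0)     # steeper methylation effect
  mut_base <- simulate_mutations(covariates, b_base,
                                 n_samples = 6L, seed = seeds[1])
  mut_pole <- simulate_mutations(covariates, b_pole, n_samples = 4L,
                                 seed = seeds[2], sample_multiplier = 3)
  mut_pole[, sample_id := sub("^S", "P", sample_id)]
  ## POLE-like genomes are dominated by signature-style T[C>A]T mutations;
  ## these are non-CpG and do not enter the CpG table, but they drive the
  ## spectrum used for classification
  pole_ids <- sort(unique(mut_pole$sample_id))
  mut_sig <- simulate_signature_mutations(
    sim$genome, n_per_sample = 2L * round(nrow(mut_pole) / length(pole_ids)),
    sample_ids = pole_ids, seed = seeds[4])
  mut_pole <- data.table::rbindlist(list(mut_pole, mut_sig))
  data.table::setattr(mut_pole, "class", class(mut_sig))
  mutations <- data.table::rbindlist(list(mut_base, mut_pole))
  data.table::setattr(mutations, "class", class(mut_base))

  tables <- list(
    baseline = build_cpg_table(sim$methylation, sim$timing, mut_base,
                               genome = sim$genome,
                               chroms = names(sim$genome)),
    pole_like = build_cpg_table(sim$methylation, sim$timing, mut_pole,
                                genome = sim$genome,
                                chroms = names(sim$genome)))

  ## sample classification: POLE-like samples carry an exonuclease-domain
  ## mutation, baseline samples are annotated microsatellite stable
  samples <- sort(unique(mutations$sample_id))
  pole_samples <- grep("^P", samples, value = TRUE)
  protein_mutations <- data.table(sample_id = pole_samples, gene = "POLE",
                                  aa_pos = 300L)
  msi_annotations <- setNames(rep("MSS", length(samples)), samples)
  labels <- classify_samples(mutations, sim$genome, protein_mutations,
                             msi_annotations)

  ## binned associations and slope comparison (baseline as reference)
  assocs <- lapply(tables, binned_rate)
  slopes <- compare_slopes(assocs, reference = "baseline")

  ## replication-timing stratification of the baseline cohort
  strata <- stratify_by_timing(tables$baseline)
  strata_slopes <- compare_slopes(strata, reference = "early")

  ## nested model selection on each cohort + summary table
  selection <- lapply(tables, select_model)
  report <- cohort_report(tables)

  ## per-sample slopes in the POLE-like cohort
  sample_slopes <- per_sample_slopes(tables$pole_like)

  ## candidate TCG fractions in the POLE-like cohort
  candidates <- candidate_fraction(tables$pole_like, mutations = mut_pole)

  ## stop-gain TCG candidates on the planted genes
  hotspot_results <- lapply(sim$genes, function(gm) {
    cs <- cds_sequence(sim$genome, gm)
    sites <- enumerate_stop_gain_tcg(cs$cds, cs$flank5, cs$flank3,
                                     gene = gm$gene)
    rank <- if (nrow(sites)) {
      rank_hotspot_methylation(sites, gm, sim$methylation)
    }
    list(sites = sites, rank = rank)
  })

  ## origin strand asymmetry with a planted bias
  origin <- as.list(cfg$origins[1])
  mut_asym <- plant_asymmetry(mutations, origin, ratio = cfg$asym_ratio,
                              flank = 25000, seed = seeds[3])
  asymmetry <- strand_asymmetry(mut_asym, origin, flank = 25000,
                                context_class = NULL)

  out <- list(config = cfg, simulation = sim, covariates = covariates,
              mutations = mutations, tables = tables, labels = labels,
              assocs = assocs, slopes = slopes, strata = strata,
              strata_slopes = strata_slopes, selection = selection,
              report = report, sample_slopes = sample_slopes,
              candidates = candidates, hotspots = hotspot_results,
              asymmetry = asymmetry)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

## Persist the pipeline's inputs and results (TSV + JSON) with the exact
## configuration and seed that produced them.
write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_simulation(out$simulation, file.path(outdir, "inputs"),
                   mutations = out$mutations)
  for (g in names(out$tables)) {
    write_cpg_table(out$tables[[g]],
                    file.path(outdir, sprintf("cpg_table_%s.tsv", g)))
  }
  data.table::fwrite(out$labels, file.path(outdir, "sample_labels.tsv"),
                     sep = "\t")
  data.table::fwrite(out$slopes, file.path(outdir, "slope_comparison.tsv"),
                     sep = "\t")
  data.table::fwrite(out$report, file.path(outdir, "cohort_report.tsv"),
                     sep = "\t")
  cfg <- out$config
  cfg$origins <- as.data.frame(cfg$origins)
  json <- list(
    config = cfg[setdiff(names(cfg), "genes")],
    seed = out$config$seed,
    slopes = as.data.frame(out$slopes),
    vertices = setNames(out$report$vertex, out$report$cohort),
    auc = setNames(out$report$auc, out$report$cohort),
    asymmetry = list(p_value = out$asymmetry$p_value,
                     table = out$asymmetry$table),
    stop_gain_candidates = lapply(out$hotspots,
                                  function(h) as.data.frame(h$sites)))
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
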