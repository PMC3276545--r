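#' Run the full screen analysis pipeline
#'
#' Orchestrates simulate -> phenotype -> rate -> classify -> dominance as one
#' reproducible run. Every artifact is a plain TSV or JSON file under
#' `out_dir`, so each stage can be re-run and inspected independently, and a
#' provenance record (seed, configuration, package version) accompanies the
#' results. Given the same configuration and seed the run is byte-identical.
#'
#' Stages:
#' \describe{
#'   \item{simulate}{a mutant-collection screen ([simulate_screen()]) plus a
#'     treated/control population pair for the rate stage.}
#'   \item{phenotype}{per-culture median-ratio phenotypes and Z-scores for
#'     haploids and diploids (YFP and CFP).}
#'   \item{rate}{tail-excess mutant frequency on the per-cell gated ratios,
#'     Poisson load, and (when `config$fold` is set) the calibrated
#'     spontaneous rate.}
#'   \item{classify}{copy-number calls and functional class per genotype.}
#'   \item{dominance}{the per-class summary table.}
#' }
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of the written artifacts.
#' @export
run_screen_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond_error(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), "mutscreen_stage_error")
    })
  }
  sim <- config$sim

  say("[simulate] screen panel + primary-screen populations (seed %d)", sim$seed)
  ds <- stage("simulate", simulate_screen(sim, class_counts = config$class_counts,
                                          n_mutant_genotypes = config$n_mutant_genotypes))
  ctrl_pop <- stage("simulate", simulate_control_population(sim, seed = sim$seed + 101L))
  trt_pop <- stage("simulate", simulate_treated_population(sim, seed = sim$seed + 202L))

  say("[phenotype] gating %s and scoring cultures",
      paste0(config$gate$fsc_low, ":", config$gate$fsc_high))
  thr <- z_threshold(config$alpha)
  hap <- stage("phenotype", {
    ph <- culture_phenotypes(ds$haploid_events, "yfp", config$gate,
                             config$min_events_used)
    screen_zscores(ph, threshold = thr,
                   min_controls = min(10L, sim$n_control_replicates))
  })
  dip_y <- stage("phenotype", {
    ph <- culture_phenotypes(ds$diploid_events, "yfp", config$gate,
                             config$min_events_used)
    screen_zscores(ph, threshold = thr,
                   min_controls = min(10L, sim$n_control_replicates))
  })
  dip_c <- stage("phenotype", {
    ph <- culture_phenotypes(ds$diploid_events, "cfp", config$gate,
                             config$min_events_used)
    screen_zscores(ph, threshold = thr,
                   min_controls = min(10L, sim$n_control_replicates))
  })

  say("[rate] tail-excess frequency on %d treated / %d control cells",
      nrow(trt_pop$events), nrow(ctrl_pop))
  rate <- stage("rate", {
    tr <- gate_events(trt_pop$events, config$gate)
    co <- gate_events(ctrl_pop, config$gate)
    cmp <- tail_excess_frequency(tr$yfp / tr$fsc, co$yfp / co$fsc,
                                 n_bins = config$n_bins,
                                 spline_df = config$spline_df)
    load <- poisson_mutation_load(cmp$f)
    if (!is.null(config$fold)) load <- spontaneous_rate(load, config$fold)
    list(comparison = cmp, load = load)
  })

  say("[classify] copy number + functional class for %d genotypes", nrow(ds$truth))
  cls <- stage("classify", {
    cn <- call_copy_number(ds$pyro_assays$yfp_reads, ds$pyro_assays$cfp_reads,
                           threshold = config$copy_threshold,
                           guard_se = config$copy_guard_se)
    cn <- cbind(genotype_id = ds$pyro_assays$genotype_id, cn)
    list(copy_calls = cn,
         assignments = classify_mutants(ds$truth$genotype_id,
                                        ds$transgene_mutations, cn))
  })

  say("[dominance] per-class summary (%s regression)", config$regression_method)
  dip_tab <- data.frame(genotype_id = dip_y$genotype_id,
                        z_yfp = dip_y$z_median, z_cfp = dip_c$z_median)
  summary_tab <- stage("dominance", {
    build_summary_table(cls$assignments,
                        data.frame(genotype_id = hap$genotype_id,
                                   z_median = hap$z_median),
                        dip_tab, threshold = thr,
                        regression_method = config$regression_method)
  })

  paths <- list(
    haploid_phenotypes = file.path(out_dir, "haploid_phenotypes.tsv"),
    diploid_phenotypes = file.path(out_dir, "diploid_phenotypes.tsv"),
    classifications = file.path(out_dir, "classifications.tsv"),
    summary = file.path(out_dir, "class_summary.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    rate = file.path(out_dir, "rate_report.json"),
    provenance = file.path(out_dir, "provenance.json"))
  write_screen_tsv(hap, paths$haploid_phenotypes)
  dip_out <- cbind(dip_y[, c("genotype_id", "replicate", "value", "variance",
                             "n_events_used")],
                   z_yfp = dip_y$z_median, z_cfp = dip_c$z_median)
  write_screen_tsv(dip_out, paths$diploid_phenotypes)
  write_screen_tsv(merge(cls$assignments, cls$copy_calls, by = "genotype_id",
                         all.x = TRUE, sort = TRUE),
                   paths$classifications)
  write_screen_tsv(summary_tab, paths$summary)
  write_screen_tsv(ds$truth, paths$truth)
  r <- rate$load
  write_json(list(f = r$f, lambda = r$lam, p0 = r$p0, p1 = r$p1,
                  p_gt1 = r$p_gt1, fold = config$fold,
                  spontaneous_rate = if (is.null(config$fold)) NULL else r$spontaneous_rate,
                  crossings = unname(rate$comparison$crossings),
                  crossing_percentiles = rate$comparison$crossing_percentiles,
                  degenerate = rate$comparison$degenerate),
             paths$rate, auto_unbox = TRUE, digits = NA, null = "null")
  write_json(list(package = "mutscreen",
                  version = as.character(packageVersion("mutscreen")),
                  seed = sim$seed,
                  alpha = config$alpha, n_bins = config$n_bins,
                  gate = c(config$gate$fsc_low, config$gate$fsc_high),
                  regression_method = config$regression_method,
                  class_counts = as.list(config$class_counts),
                  sim = sim[!vapply(sim, is.list, TRUE)]),
             paths$provenance, auto_unbox = TRUE, digits = NA)
  say("[done] artifacts in %s", normalizePath(out_dir))
  invisible(list(dataset = ds, haploid = hap, diploid = dip_tab, rate = rate,
                 classification = cls, summary = summary_tab, paths = paths))
}
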