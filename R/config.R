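#' Simulation configuration for a reporter-gene mutagenesis screen
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode the
#' study conditions of the screen the package models: a mean Poisson load of
#' 0.0303 activity-affecting mutations per genome in the mutagenized
#' population, mutational class weights of 7/10/2/81% for
#' coding/CNV/cis-regulatory/trans-acting mutations, per-class effect-size
#' distributions calibrated so that culture-level median |Z| lands near
#' 48/8/8/5, direction probabilities (fraction of effects that increase
#' activity) of 0, 21/22, 1/2 and 131/179, and dominance coefficients of 1
#' for coding/CNV/cis and 0 for trans.
#'
#' Fluorescence is simulated on a log10 scale: per-event log10 FSC is normal
#' with mean `fsc_mean` and sd `fsc_sd`, and log10 YFP follows the log-linear
#' model `yfp_intercept + yfp_slope * log10(FSC)` plus residual noise.
#' Mutational effects are multiplicative on linear-scale activity, i.e.
#' additive shifts of log10 YFP; `effect_params` gives, per class, the
#' log-normal parameters of the magnitude of the shift in log10 units
#' (`meanlog`, `sdlog`) and the probability `p_positive` that the shift is
#' upward.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_cells_control,n_cells_treated default population sizes for the
#'   primary (mixed-population) screen.
#' @param mean_load mean number of activity-affecting mutations per genome
#'   (Poisson parameter) in the treated population.
#' @param class_weights named probabilities over
#'   `c("coding","cnv","cis","trans")`, summing to 1.
#' @param effect_params named list (same classes) of
#'   `list(meanlog, sdlog, p_positive)` describing the per-mutation
#'   multiplicative effect: `|log10 effect| ~ Lognormal(meanlog, sdlog)`.
#' @param dominance named dominance coefficients in \[0, 1\]; the fraction of
#'   a mutation's haploid effect expressed in a heterozygous diploid
#'   (applied to both channels for trans mutations, to YFP for the rest).
#' @param fsc_mean,fsc_sd log10 forward-scatter distribution.
#' @param yfp_slope,yfp_intercept,yfp_resid_sd log-linear FSC to YFP model.
#' @param cfp_intercept,cfp_resid_sd CFP channel analogues (diploids only;
#'   the slope is shared with YFP).
#' @param culture_noise_sd between-replicate sd of the median-ratio phenotype
#'   for haploid cultures (phenotype units: log10 fluorescence per log10 FSC).
#' @param diploid_culture_noise_sd same, for diploid cultures.
#' @param n_control_replicates replicate control cultures per ploidy.
#' @param events_per_culture,events_per_diploid_culture cytometry events
#'   recorded per clonal culture (screen floor: 5,000 haploid, 9,000 diploid).
#' @param pyro_reads total pyrosequencing reads per copy-number assay.
#' @param cnv_cfp_effect multiplicative effect of a reporter duplication on
#'   the diploid CFP (reference-allele) channel; values below 1 reproduce the
#'   observed CFP decrease accompanying YFP increases in CNV heterozygotes.
#' @param copies_cnv reporter copy number carried by CNV genotypes.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' ev <- simulate_control_population(cfg, n = 1000)
#' cor(ev$fsc, ev$yfp)
#' @export
sim_config <- function(seed = 1L,
                       n_cells_control = 1e5,
                       n_cells_treated = 1e5,
                       mean_load = 0.0303,
                       class_weights = c(coding = 0.07, cnv = 0.10,
                                         cis = 0.02, trans = 0.81),
                       effect_params = list(
                         coding = list(meanlog = log(0.260), sdlog = 0.45, p_positive = 0),
                         cnv    = list(meanlog = log(0.0434), sdlog = 0.40, p_positive = 21 / 22),
                         cis    = list(meanlog = log(0.0434), sdlog = 0.50, p_positive = 0.5),
                         trans  = list(meanlog = log(0.0271), sdlog = 0.60, p_positive = 131 / 179)),
                       dominance = c(coding = 1, cnv = 1, cis = 1, trans = 0),
                       fsc_mean = 5.42, fsc_sd = 0.10,
                       yfp_slope = 1, yfp_intercept = -0.70, yfp_resid_sd = 0.012,
                       cfp_intercept = -0.75, cfp_resid_sd = 0.012,
                       culture_noise_sd = 0.0010,
                       diploid_culture_noise_sd = 0.0008,
                       n_control_replicates = 20L,
                       events_per_culture = 5000L,
                       events_per_diploid_culture = 9000L,
                       pyro_reads = 1000L,
                       cnv_cfp_effect = 0.96,
                       copies_cnv = 2L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

mutation_classes <- c("coding", "cnv", "cis", "trans")

validate_sim_config <- function(cfg) {
  w <- cfg$class_weights
  if (!setequal(names(w), mutation_classes)) {
    cond_error("class_weights must be named coding/cnv/cis/trans",
               "mutscreen_bad_config")
  }
  if (abs(sum(w) - 1) > 1e-12 || any(w < 0)) {
    cond_error("class_weights must be non-negative and sum to 1 (tol 1e-12)",
               "mutscreen_bad_config")
  }
  if (cfg$mean_load < 0) cond_error("mean_load must be >= 0", "mutscreen_bad_config")
  if (cfg$fsc_sd <= 0 || cfg$culture_noise_sd <= 0 ||
      cfg$diploid_culture_noise_sd <= 0) {
    cond_error("fsc_sd and culture noise sds must be > 0", "mutscreen_bad_config")
  }
  if (cfg$yfp_resid_sd < 0 || cfg$cfp_resid_sd < 0) {
    cond_error("residual sds must be >= 0", "mutscreen_bad_config")
  }
  if (any(cfg$dominance < 0 | cfg$dominance > 1)) {
    cond_error("dominance coefficients must lie in [0, 1]", "mutscreen_bad_config")
  }
  if (!setequal(names(cfg$effect_params), mutation_classes)) {
    cond_error("effect_params must cover coding/cnv/cis/trans",
               "mutscreen_bad_config")
  }
  for (cl in mutation_classes) {
    p <- cfg$effect_params[[cl]]
    stopifnot(is.numeric(p$meanlog), p$sdlog >= 0,
              p$p_positive >= 0, p$p_positive <= 1)
  }
  if (cfg$pyro_reads < 1) cond_error("pyro_reads must be >= 1", "mutscreen_bad_config")
  if (cfg$copies_cnv < 1) cond_error("copies_cnv must be >= 1", "mutscreen_bad_config")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Screen simulation configuration\n")
  cat(sprintf("  seed %d; mean load %.4g; class weights %s\n", x$seed,
              x$mean_load,
              paste(sprintf("%s=%.2f", names(x$class_weights), x$class_weights),
                    collapse = " ")))
  cat(sprintf("  FSC ~ N(%.2f, %.2f) [log10]; YFP = %.2f + %.2f*FSC + N(0, %.3f)\n",
              x$fsc_mean, x$fsc_sd, x$yfp_intercept, x$yfp_slope, x$yfp_resid_sd))
  cat(sprintf("  cultures: %d events haploid / %d diploid; %d control replicates\n",
              x$events_per_culture, x$events_per_diploid_culture,
              x$n_control_replicates))
  invisible(x)
}

#' Forward-scatter gate window
#'
#' The fixed log10 FSC window within which events contribute to a culture's
#' phenotype (defaults 5.30--5.55, the dotted-line window used in the screen).
#' Use [gate_window_percentiles()] to derive a window from the data instead,
#' as done on instruments where fixed values are not meaningful.
#'
#' @param fsc_low,fsc_high window bounds, log10 FSC units; closed interval.
#' @return An object of class `gate_window`.
#' @export
gate_window <- function(fsc_low = 5.30, fsc_high = 5.55) {
  if (!is.numeric(fsc_low) || !is.numeric(fsc_high) || fsc_low >= fsc_high) {
    cond_error("gate window requires fsc_low < fsc_high", "mutscreen_bad_gate")
  }
  structure(list(fsc_low = fsc_low, fsc_high = fsc_high), class = "gate_window")
}

#' Data-derived gate window at FSC percentiles
#'
#' @param events event table with an `fsc` column.
#' @param lower,upper FSC percentiles (defaults 0.20 and 0.80) bounding the
#'   window.
#' @return A [gate_window()].
#' @export
gate_window_percentiles <- function(events, lower = 0.20, upper = 0.80) {
  stopifnot(is.data.frame(events), "fsc" %in% names(events),
            lower < upper, lower >= 0, upper <= 1)
  q <- quantile(events$fsc, c(lower, upper), names = FALSE)
  gate_window(q[1], q[2])
}

#' Pipeline run configuration
#'
#' Combines a [sim_config()] with the analysis parameters of every pipeline
#' stage. `class_counts` fixes the per-class composition of the simulated
#' mutant panel (the default reproduces the 16/22/4/179 composition of the
#' screen being modelled); set it to `NULL` and give `n_mutant_genotypes` to
#' draw classes from `sim$class_weights` instead.
#'
#' @param sim a [sim_config()].
#' @param class_counts named integer vector over coding/cnv/cis/trans, or
#'   `NULL`.
#' @param n_mutant_genotypes number of mutant genotypes when `class_counts`
#'   is `NULL`.
#' @param gate a [gate_window()].
#' @param alpha two-sided significance level for mutant calling (0.01 gives
#'   the |Z| > 2.58 rule).
#' @param n_bins histogram bins for the treated-control difference curve.
#' @param spline_df optional fixed spline degrees of freedom (default:
#'   generalized cross-validation).
#' @param copy_threshold,copy_guard_se copy-number decision threshold on the
#'   YFP allele fraction and width (in binomial SEs) of the indeterminate
#'   buffer around it.
#' @param regression_method `"ma"` (major axis) or `"sma"` for the model II
#'   regressions in the dominance stage.
#' @param min_events_used minimum gated events per culture for a valid
#'   phenotype.
#' @param fold optional mutagen calibration factor (treated/spontaneous
#'   marker-rate ratio); when supplied the rate stage also reports a
#'   spontaneous rate.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       class_counts = c(coding = 16L, cnv = 22L, cis = 4L, trans = 179L),
                       n_mutant_genotypes = 221L,
                       gate = gate_window(),
                       alpha = 0.01,
                       n_bins = 256L,
                       spline_df = NULL,
                       copy_threshold = 7 / 12,
                       copy_guard_se = 2,
                       regression_method = c("ma", "sma"),
                       min_events_used = 100L,
                       fold = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(gate, "gate_window"),
            alpha > 0, alpha < 1, n_bins >= 16)
  regression_method <- match.arg(regression_method)
  structure(list(sim = sim, class_counts = class_counts,
                 n_mutant_genotypes = n_mutant_genotypes, gate = gate,
                 alpha = alpha, n_bins = n_bins, spline_df = spline_df,
                 copy_threshold = copy_threshold, copy_guard_se = copy_guard_se,
                 regression_method = regression_method,
                 min_events_used = min_events_used, fold = fold),
            class = "run_config")
}
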