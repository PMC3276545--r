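#' Gate cytometry events on forward scatter
#'
#' Retains events whose log10 FSC lies inside the closed gate window,
#' preserving input order. An empty input errors with class
#' `mutscreen_empty_input`; a window that excludes every event errors with
#' the distinct class `mutscreen_empty_gate`.
#'
#' @param events data.frame with an `fsc` column (log10 units).
#' @param window a [gate_window()].
#' @return The gated subset of `events`.
#' @export
gate_events <- function(events, window = gate_window()) {
  stopifnot(is.data.frame(events), "fsc" %in% names(events),
            inherits(window, "gate_window"))
  if (nrow(events) == 0) {
    cond_error("no events to gate", "mutscreen_empty_input")
  }
  keep <- events$fsc >= window$fsc_low & events$fsc <= window$fsc_high
  if (!any(keep)) {
    cond_error("gate window retains no events", "mutscreen_empty_gate")
  }
  events[keep, , drop = FALSE]
}

#' Median-ratio fluorescence phenotype of one culture
#'
#' The culture phenotype is the median over gated events of the per-event
#' ratio of log10 fluorescence to log10 FSC (`ratio_mode = "ratio_of_logs"`,
#' the default reading of a median YFP/FSC ratio computed after log
#' transformation). The alternative reading, the median of the log of the
#' linear ratio (i.e. the median difference of the log10 values), is
#' available as `ratio_mode = "log_of_ratio"`. The per-culture variance of
#' the same per-event quantity is returned alongside for variance-based
#' calls.
#'
#' @param events gated event table.
#' @param channel fluorescence column, `"yfp"` or `"cfp"`.
#' @param ratio_mode see Description.
#' @return A list of class `phenotype_measurement`: `value`, `variance`,
#'   `n_events_used`, `channel`.
#' @export
median_ratio_phenotype <- function(events, channel = c("yfp", "cfp"),
                                   ratio_mode = c("ratio_of_logs", "log_of_ratio")) {
  channel <- match.arg(channel)
  ratio_mode <- match.arg(ratio_mode)
  if (!channel %in% names(events)) {
    cond_error(sprintf("events lack a '%s' column", channel),
               "mutscreen_missing_channel")
  }
  if (nrow(events) == 0) cond_error("no events", "mutscreen_empty_input")
  r <- event_ratios(events, channel, ratio_mode)
  structure(list(value = median(r),
                 variance = if (length(r) > 1) var(r) else NA_real_,
                 n_events_used = length(r), channel = channel),
            class = "phenotype_measurement")
}

event_ratios <- function(events, channel, ratio_mode) {
  if (ratio_mode == "ratio_of_logs") {
    events[[channel]] / events$fsc
  } else {
    events[[channel]] - events$fsc
  }
}

#' Standardized effect (Z-score) against replicate controls
#'
#' `z = (value - mean(controls)) / sd(controls)` with the sample (n-1)
#' standard deviation; vectorised over `value`.
#'
#' @param value phenotype value(s) to standardize.
#' @param control_values phenotypes of the replicate control cultures
#'   (at least two, with positive spread).
#' @return Z-score(s).
#' @examples
#' zscore(4, c(1, 2, 3))  # 2
#' @export
zscore <- function(value, control_values) {
  if (length(control_values) < 2) {
    cond_error("need at least 2 control values", "mutscreen_few_controls")
  }
  s <- sd(control_values)
  if (!is.finite(s) || s == 0) {
    cond_error("control values have zero standard deviation",
               "mutscreen_zero_sd")
  }
  (value - mean(control_values)) / s
}

#' Standardized variance effect against replicate controls
#'
#' The per-culture variance analogue of [zscore()]: how far a culture's
#' event-to-event variance lies from the control cultures' variances, in
#' control-sd units. Detects mutants that broaden the fluorescence
#' distribution without moving its median.
#'
#' @param variance per-culture variance of the per-event phenotype ratio.
#' @param control_variances the same quantity for replicate controls.
#' @return Z-score(s).
#' @export
variance_zscore <- function(variance, control_variances) {
  zscore(variance, control_variances)
}

#' Two-sided normal critical value for mutant calling
#'
#' @param alpha_two_sided two-sided significance level in (0, 1).
#' @return The standard-normal quantile at `1 - alpha/2` (2.58 for
#'   alpha = 0.01, 1.96 for 0.05, 1.645 for 0.10, at the conventional
#'   rounding).
#' @export
z_threshold <- function(alpha_two_sided) {
  if (!is.numeric(alpha_two_sided) ||
      any(alpha_two_sided <= 0 | alpha_two_sided > 1)) {
    cond_error("alpha must lie in (0, 1]", "mutscreen_bad_alpha")
  }
  qnorm(1 - alpha_two_sided / 2)
}

#' Call a genotype mutant from its Z-score
#'
#' Mutant iff `|z| > threshold`, strictly: a Z-score exactly at the
#' threshold is not a mutant. Direction is the sign of z.
#'
#' @param z Z-score(s), finite.
#' @param threshold critical value (default the |Z| > 2.58 rule).
#' @return data.frame with `z`, `mutant`, `direction`.
#' @export
call_mutant <- function(z, threshold = z_threshold(0.01)) {
  stopifnot(all(is.finite(z)))
  data.frame(z = z, mutant = abs(z) > threshold, direction = sign(z))
}

#' Per-culture phenotypes for a whole event table
#'
#' Gates, computes the median-ratio phenotype and per-culture variance for
#' every `genotype_id` x `replicate` combination.
#'
#' @param events event table with `genotype_id`, optional `replicate`, `fsc`
#'   and channel columns.
#' @inheritParams median_ratio_phenotype
#' @param window a [gate_window()].
#' @param min_events_used minimum gated events per culture; cultures below
#'   it raise an error (growth-failed cultures are excluded upstream in a
#'   real screen).
#' @return data.frame with `genotype_id`, `replicate`, `channel`, `value`,
#'   `variance`, `n_events_used`.
#' @export
culture_phenotypes <- function(events, channel = c("yfp", "cfp"),
                               window = gate_window(), min_events_used = 100L,
                               ratio_mode = c("ratio_of_logs", "log_of_ratio")) {
  channel <- match.arg(channel)
  ratio_mode <- match.arg(ratio_mode)
  gated <- gate_events(events, window)
  if (!"replicate" %in% names(gated)) gated$replicate <- 1L
  r <- event_ratios(gated, channel, ratio_mode)
  key <- paste(gated$genotype_id, gated$replicate, sep = "\r")
  ukey <- unique(key)
  f <- factor(key, levels = ukey)
  value <- as.numeric(tapply(r, f, median))
  variance <- as.numeric(tapply(r, f, var))
  n_used <- as.integer(tabulate(f))
  if (any(n_used < min_events_used)) {
    cond_error(sprintf("%d culture(s) have fewer than %d gated events",
                       sum(n_used < min_events_used), min_events_used),
               "mutscreen_too_few_events")
  }
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  data.frame(genotype_id = parts[, 1], replicate = parts[, 2],
             channel = channel, value = value, variance = variance,
             n_events_used = n_used)
}

#' Z-scores and mutant calls for a phenotype table
#'
#' Standardizes every culture against the replicate control cultures of the
#' same table (rows with `genotype_id == control_id`). Control rows are, by
#' default, standardized leave-one-out against the remaining controls so
#' that their Z-scores are valid null draws.
#'
#' @param phenotypes output of [culture_phenotypes()].
#' @param control_id genotype id of the replicate controls.
#' @param threshold mutant-calling critical value.
#' @param leave_one_out standardize control rows against the other controls.
#' @param min_controls minimum number of replicate controls required.
#' @return `phenotypes` with `z_median`, `z_variance`, `n_controls`,
#'   `mutant`, `direction` columns appended.
#' @export
screen_zscores <- function(phenotypes, control_id = "control",
                           threshold = z_threshold(0.01),
                           leave_one_out = TRUE, min_controls = 10L) {
  is_ctrl <- phenotypes$genotype_id == control_id
  nc <- sum(is_ctrl)
  if (nc < min_controls) {
    cond_error(sprintf("only %d control replicates; >= %d required", nc, min_controls),
               "mutscreen_few_controls")
  }
  cv <- phenotypes$value[is_ctrl]
  cw <- phenotypes$variance[is_ctrl]
  z_med <- z_var <- numeric(nrow(phenotypes))
  z_med[!is_ctrl] <- zscore(phenotypes$value[!is_ctrl], cv)
  z_var[!is_ctrl] <- zscore(phenotypes$variance[!is_ctrl], cw)
  if (leave_one_out) {
    z_med[is_ctrl] <- loo_z(cv)
    z_var[is_ctrl] <- loo_z(cw)
  } else {
    z_med[is_ctrl] <- zscore(cv, cv)
    z_var[is_ctrl] <- zscore(cw, cw)
  }
  call <- call_mutant(z_med, threshold)
  phenotypes$z_median <- z_med
  phenotypes$z_variance <- z_var
  phenotypes$n_controls <- nc
  phenotypes$mutant <- call$mutant
  phenotypes$direction <- call$direction
  phenotypes
}

# leave-one-out z for each element of x against the remaining ones
loo_z <- function(x) {
  n <- length(x)
  s <- sum(x); ss <- sum(x^2)
  m <- (s - x) / (n - 1)
  v <- (ss - x^2 - (n - 1) * m^2) / (n - 2)
  v[v < 0] <- 0
  (x - m) / sqrt(v)
}
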