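#' Mutant frequency from the tail excess of a treated vs control comparison
#'
#' Bins the per-cell fluorescence phenotypes of the treated and control
#' populations on common equal-width bins (control counts scaled to the
#' treated total), fits a cubic smoothing spline to the per-bin count
#' difference (smoothness chosen by generalized cross-validation unless
#' `spline_df` is given), and locates the two zero crossings bracketing the
#' central mass where the treated population is depleted. The mutant
#' frequency `f` is the net excess of treated counts outside the crossings,
#' summed from the raw (unsmoothed) bin differences and divided by the
#' treated total; the spline is used only to locate the crossings. Setting
#' `positive_part = TRUE` sums only positive per-bin differences instead
#' (slightly upward-biased by counting noise).
#'
#' When no crossing exists on one or both sides of the control median (e.g.
#' identical samples) the comparison is degenerate: the function warns,
#' flags it, and returns `f = 0`.
#'
#' @param treated,control numeric vectors of per-cell phenotypes (e.g.
#'   gated log10 YFP / log10 FSC ratios).
#' @param n_bins equal-width bins spanning the pooled range (default 256).
#' @param spline_df optional fixed equivalent degrees of freedom.
#' @param grid_points grid resolution for crossing detection; each sign
#'   change is refined by bisection.
#' @param positive_part see Description.
#' @return An object of class `distribution_comparison`: `f`, `bin_edges`,
#'   `treated_counts`, `control_counts` (scaled), `difference_curve`,
#'   `spline_fit`, `crossings` (phenotype values), `crossing_percentiles`
#'   (control percentiles), `degenerate`.
#' @export
tail_excess_frequency <- function(treated, control, n_bins = 256L,
                                  spline_df = NULL, grid_points = 1000L,
                                  positive_part = FALSE) {
  if (length(treated) == 0 || length(control) == 0) {
    cond_error("both samples must be non-empty", "mutscreen_empty_input")
  }
  rng <- range(c(treated, control))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  tc <- tabulate(bin_of(treated), nbins = n_bins)
  cc <- tabulate(bin_of(control), nbins = n_bins) *
    (length(treated) / length(control))
  d <- tc - cc
  fit <- if (is.null(spline_df)) {
    smooth.spline(centers, d)
  } else {
    smooth.spline(centers, d, df = spline_df)
  }
  grid <- seq(rng[1], rng[2], length.out = grid_points)
  sg <- predict(fit, grid)$y
  flips <- which(sg[-1] * sg[-length(sg)] < 0)
  crossings <- vapply(flips, function(i) {
    uniroot(function(z) predict(fit, z)$y, c(grid[i], grid[i + 1]))$root
  }, numeric(1))
  # cumulative integral of the spline: its maximum sits at a downward zero
  # crossing (start of the central deficit) and its minimum at an upward one
  # (end of the deficit); that pair brackets the central mass even when a
  # lightly-smoothed spline wiggles through zero elsewhere
  cum <- cumsum(sg) * (grid[2] - grid[1])
  cum_at <- approx(grid, cum, xout = crossings, rule = 2)$y
  downward <- sg[flips] > 0
  lower <- crossings[downward]
  upper <- crossings[!downward]
  if (length(lower) && length(upper)) {
    lo_cand <- lower[which.max(cum_at[downward])]
    hi_cand <- upper[which.min(cum_at[!downward])]
  }
  degenerate <- length(lower) == 0 || length(upper) == 0 || lo_cand >= hi_cand
  if (degenerate) {
    warning("degenerate screen comparison: fewer than two interior zero crossings; f set to 0",
            call. = FALSE)
    lo <- hi <- NA_real_
    f <- 0
  } else {
    lo <- lo_cand
    hi <- hi_cand
    low_bins <- edges[-1] <= lo
    high_bins <- edges[-length(edges)] >= hi
    excess <- if (positive_part) pmax(d, 0) else d
    f <- (sum(excess[low_bins]) + sum(excess[high_bins])) / length(treated)
    f <- max(f, 0)
  }
  structure(list(f = f, bin_edges = edges, treated_counts = tc,
                 control_counts = cc, difference_curve = d,
                 spline_fit = fit, crossings = c(lower = lo, upper = hi),
                 crossing_percentiles = 100 * ecdf(control)(c(lo, hi)),
                 degenerate = degenerate),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("Treated vs control distribution comparison (%d bins)\n",
              length(x$treated_counts)))
  if (x$degenerate) {
    cat("  degenerate: no bracketing zero crossings; f = 0\n")
  } else {
    cat(sprintf("  spline zero crossings at %.4g / %.4g (control percentiles %.1f / %.1f)\n",
                x$crossings[1], x$crossings[2],
                x$crossing_percentiles[1], x$crossing_percentiles[2]))
    cat(sprintf("  mutant frequency f = %.4g\n", x$f))
  }
  invisible(x)
}

#' Poisson mutation load from a mutant frequency
#'
#' Treating the per-cell number of activity-affecting mutations as
#' Poisson(lambda), the observed mutant frequency `f` identifies
#' `P0 = 1 - f` and hence `lambda = -log(P0)`, the expected single-mutant
#' fraction `P1 = lambda * exp(-lambda)` and the multi-mutant fraction
#' `P>1 = 1 - P0 - P1`.
#'
#' @param f mutant frequency in \[0, 1).
#' @return An object of class `poisson_load`: `f`, `p0`, `lam`, `p1`,
#'   `p_gt1` (and `fold`, `spontaneous_rate` slots filled by
#'   [spontaneous_rate()]).
#' @examples
#' poisson_mutation_load(0.0298)  # lambda 0.0303, P1 2.94%, P>1 0.04%
#' @export
poisson_mutation_load <- function(f) {
  if (!is.numeric(f) || f < 0 || f >= 1) {
    cond_error("f must lie in [0, 1)", "mutscreen_bad_frequency")
  }
  p0 <- 1 - f
  lam <- -log(p0)
  p1 <- lam * exp(-lam)
  structure(list(f = f, p0 = p0, lam = lam, p1 = p1, p_gt1 = 1 - p0 - p1,
                 fold = NA_real_, spontaneous_rate = NA_real_),
            class = "poisson_load")
}

#' @export
print.poisson_load <- function(x, ...) {
  cat(sprintf("Poisson mutation load: f = %.4g, lambda = %.4g\n", x$f, x$lam))
  cat(sprintf("  P0 = %.4g  P1 = %.4g (%.2f%%)  P>1 = %.4g (%.2f%%)\n",
              x$p0, x$p1, 100 * x$p1, x$p_gt1, 100 * x$p_gt1))
  if (is.finite(x$fold)) {
    cat(sprintf("  mutagen fold = %.4g -> spontaneous rate %.2g per haploid genome per generation\n",
                x$fold, x$spontaneous_rate))
  }
  invisible(x)
}

#' Mutagen calibration factor from a marker phenotype
#'
#' Ratio of the marker-mutant frequency observed in the mutagenized
#' population to the known spontaneous mutation rate of the same marker
#' (e.g. canavanine resistance): the factor by which the mutagen elevated
#' the point-mutation rate.
#'
#' @param observed_marker_frequency marker-mutant frequency in the treated
#'   population.
#' @param reported_spontaneous_marker_rate published spontaneous rate for
#'   the marker.
#' @return The fold elevation.
#' @export
calibration_fold <- function(observed_marker_frequency,
                             reported_spontaneous_marker_rate) {
  if (observed_marker_frequency <= 0 || reported_spontaneous_marker_rate <= 0) {
    cond_error("both frequencies must be > 0", "mutscreen_bad_frequency")
  }
  observed_marker_frequency / reported_spontaneous_marker_rate
}

#' Spontaneous mutation rate from a mutagen-calibrated load
#'
#' Divides the mutagen-induced load by the fold elevation of the mutagen,
#' assuming the mutagen targeted reporter-activity sites and marker sites
#' proportionally.
#'
#' @param lam mean mutations per genome in the treated population, or a
#'   [poisson_mutation_load()] object.
#' @param fold mutagen fold elevation (> 0).
#' @return The spontaneous rate (per haploid genome per generation); if
#'   `lam` is a `poisson_load`, the object with `fold` and
#'   `spontaneous_rate` filled in.
#' @examples
#' spontaneous_rate(0.0303, 5737)  # 5.3e-6
#' @export
spontaneous_rate <- function(lam, fold) {
  if (fold <= 0) cond_error("fold must be > 0", "mutscreen_bad_fold")
  if (inherits(lam, "poisson_load")) {
    lam$fold <- fold
    lam$spontaneous_rate <- lam$lam / fold
    return(lam)
  }
  lam / fold
}

#' Expected mutant purity of a sorted tail
#'
#' If sorting thresholds capture a fraction `s_c` of the control population
#' and `s_t` of the treated population, the expected fraction of sorted
#' treated cells that are mutants is `(s_t - s_c) / s_t` (the excess over
#' the control background). Negative purities (treated tail smaller than
#' control tail) are clipped to 0 with a warning.
#'
#' @param s_t treated-population tail fraction (any consistent unit, e.g.
#'   percent).
#' @param s_c control-population tail fraction, same unit.
#' @return Purity as a fraction in \[0, 1\].
#' @examples
#' 100 * sorted_tail_purity(1.21, 0.82)  # 32.2
#' 100 * sorted_tail_purity(1.04, 0.64)  # 38.5
#' @export
sorted_tail_purity <- function(s_t, s_c) {
  if (any(s_t <= 0)) cond_error("s_t must be > 0", "mutscreen_bad_fraction")
  if (any(s_c < 0)) cond_error("s_c must be >= 0", "mutscreen_bad_fraction")
  p <- (s_t - s_c) / s_t
  if (any(p < 0)) {
    warning("control tail exceeds treated tail; purity clipped to 0", call. = FALSE)
    p <- pmax(p, 0)
  }
  p
}

#' Sorting plan for one tail of the distribution
#'
#' @param tail `"low"` or `"high"`.
#' @param n_events_sorted sorted FACS events.
#' @param colony_rate fraction of sorted events forming colonies.
#' @param s_t,s_c treated/control tail fractions captured by the sorting
#'   thresholds (used for the purity), or give `purity` directly.
#' @param purity expected mutant purity of the tail; computed from
#'   `s_t`/`s_c` when omitted.
#' @return An object of class `sort_plan`.
#' @export
sort_plan <- function(tail = c("low", "high"), n_events_sorted, colony_rate,
                      s_t = NULL, s_c = NULL, purity = NULL) {
  tail <- match.arg(tail)
  stopifnot(n_events_sorted >= 0, colony_rate >= 0, colony_rate <= 1)
  if (is.null(purity)) {
    if (is.null(s_t) || is.null(s_c)) {
      cond_error("supply either purity or both s_t and s_c", "mutscreen_bad_plan")
    }
    purity <- sorted_tail_purity(s_t, s_c)
  }
  structure(list(tail = tail, n_events_sorted = n_events_sorted,
                 colony_rate = colony_rate, s_t = s_t, s_c = s_c,
                 purity = purity),
            class = "sort_plan")
}

#' Expected direction composition of the recovered mutant collection
#'
#' From the two tails' sorting plans, the expected number of recovered
#' mutants per tail is `n_events_sorted * colony_rate * purity`; the
#' high-fluorescence tail's share of that total is the fraction of
#' recovered mutants expected to increase fluorescence.
#'
#' @param plan_low,plan_high [sort_plan()]s for the low- and
#'   high-fluorescence tails.
#' @return A list with `expected_low`, `expected_high`, `frac_increase`
#'   (high-tail share) and `frac_decrease`.
#' @export
expected_direction_fraction <- function(plan_low, plan_high) {
  stopifnot(inherits(plan_low, "sort_plan"), inherits(plan_high, "sort_plan"))
  e_low <- plan_low$n_events_sorted * plan_low$colony_rate * plan_low$purity
  e_high <- plan_high$n_events_sorted * plan_high$colony_rate * plan_high$purity
  if (e_low + e_high == 0) {
    cond_error("both tails expect zero mutants", "mutscreen_zero_expected")
  }
  list(expected_low = e_low, expected_high = e_high,
       frac_increase = e_high / (e_low + e_high),
       frac_decrease = e_low / (e_low + e_high))
}
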