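#' Model II regression slope
#'
#' Both variables are treated as error-prone. `"ma"` (major axis, the
#' default) takes the slope from the leading eigenvector of the 2x2
#' covariance matrix; `"sma"` (standardized major axis) uses
#' `sign(cov) * sd(y)/sd(x)`. MA is invariant to a common rescaling of both
#' axes but not to rescaling one axis; SMA is equivariant to separate axis
#' rescalings. Swapping x and y maps either slope to its reciprocal.
#'
#' @param x,y numeric vectors, `n >= 3`, each with positive variance.
#' @param method `"ma"` or `"sma"`.
#' @return An object of class `model2_fit`: `slope`, `n`, `method`.
#' @examples
#' model2_regression(1:10, 1.5 * (1:10))$slope  # 1.5
#' @export
model2_regression <- function(x, y, method = c("ma", "sma")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) cond_error("model II regression needs n >= 3", "mutscreen_too_few_points")
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxx == 0 || syy == 0) {
    cond_error("degenerate input: a variable has zero variance", "mutscreen_degenerate")
  }
  slope <- if (method == "sma") {
    sign(if (sxy == 0) 1 else sxy) * sqrt(syy / sxx)
  } else if (sxy == 0) {
    if (sxx > syy) 0 else Inf  # principal axis aligned with one axis
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  structure(list(slope = slope, n = n, method = method), class = "model2_fit")
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("Model II (%s) regression: slope b = %.4g (n = %d)\n",
              toupper(x$method), x$slope, x$n))
  invisible(x)
}

#' Recessivity call for a heterozygous diploid
#'
#' A mutant allele is called recessive when its heterozygote shows no
#' significant effect: `|z| < threshold`, strictly, so that the recessive
#' and mutant calls are complementary at the boundary.
#'
#' @param z_yfp_diploid diploid YFP Z-score(s), computed against diploid
#'   controls.
#' @param threshold critical value (default the |Z| = 2.58 rule).
#' @return Logical vector.
#' @export
recessivity_call <- function(z_yfp_diploid, threshold = z_threshold(0.01)) {
  stopifnot(all(is.finite(z_yfp_diploid)))
  abs(z_yfp_diploid) < threshold
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact by complete enumeration of group assignments (handling ties via
#' midranks) when the combined sample size is at most `exact_max`, normal
#' approximation with tie correction and continuity correction otherwise.
#' The exact two-sided p-value is the probability, over all equally likely
#' assignments of the pooled observations to the two groups, of a rank sum
#' at least as far from its null mean as the one observed.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (`"less"`: x tends smaller than y).
#' @param exact force or forbid enumeration; default decides by size.
#' @param exact_max combined-size limit for the default enumeration.
#' @return A list with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @examples
#' mww_test(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1, exact
#' @export
mww_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                     exact = NULL, exact_max = 12L) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) cond_error("both groups must be non-empty", "mutscreen_empty_group")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (is.null(exact)) exact <- n <= exact_max
  eps <- sqrt(.Machine$double.eps)
  if (exact) {
    if (choose(n, n1) > 5e5) {
      cond_error("exact enumeration too large; set exact = FALSE",
                 "mutscreen_too_large")
    }
    idx <- combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    p <- switch(alternative,
                two.sided = mean(abs(sums - mu) >= abs(w - mu) - eps),
                less      = mean(sums <= w + eps),
                greater   = mean(sums >= w - eps))
    method <- "exact MWW (enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- w - mu
      cc <- switch(alternative, two.sided = sign(dev) * 0.5, less = -0.5,
                   greater = 0.5)
      z <- (dev - cc) / sqrt(sigma2)
      p <- switch(alternative,
                  two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5),
                  less = pnorm(z),
                  greater = pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p.value = p, method = method)
}

#' Compare effect magnitudes between two mutant classes
#'
#' Rank-based comparison (MWW) of the absolute Z-scores of two mutational
#' classes; no multiple-testing correction is applied.
#'
#' @param groupA_absZ,groupB_absZ absolute Z-scores of the two classes.
#' @param sided `"two.sided"` (default) or a one-sided alternative
#'   (`"less"`: group A tends smaller).
#' @param ... passed to [mww_test()].
#' @return The MWW p-value.
#' @export
class_effect_comparison <- function(groupA_absZ, groupB_absZ,
                                    sided = c("two.sided", "less", "greater"),
                                    ...) {
  sided <- match.arg(sided)
  mww_test(groupA_absZ, groupB_absZ, alternative = sided, ...)$p.value
}

#' Compare two colony-formation rates by Fisher's exact test
#'
#' Two-sided Fisher's exact test on the 2x2 success/failure table, using
#' the point-probability rule (the p-value sums the probabilities of all
#' tables no more likely than the observed one).
#'
#' @param a_success,a_total,b_success,b_total counts for the two groups.
#' @return The two-sided p-value.
#' @examples
#' colony_rate_comparison(5, 5, 0, 5)  # 2/252
#' @export
colony_rate_comparison <- function(a_success, a_total, b_success, b_total) {
  counts <- c(a_success, a_total, b_success, b_total)
  if (any(counts < 0) || a_success > a_total || b_success > b_total ||
      a_total == 0 || b_total == 0) {
    cond_error("counts must be non-negative with success <= total and totals > 0",
               "mutscreen_bad_counts")
  }
  tab <- matrix(c(a_success, a_total - a_success,
                  b_success, b_total - b_success), nrow = 2, byrow = TRUE)
  fisher.test(tab)$p.value
}

#' Categorize a mutant's effect on the reference (CFP) allele
#'
#' @param z_cfp,z_yfp diploid Z-scores for CFP and YFP fluorescence.
#' @param threshold significance threshold on `|z_cfp|`.
#' @return `"no_cfp_effect"`, `"same_direction"` or `"opposite_direction"`
#'   (vectorised).
#' @export
cfp_cross_effect <- function(z_cfp, z_yfp, threshold = z_threshold(0.01)) {
  stopifnot(all(is.finite(z_cfp)), all(is.finite(z_yfp)),
            length(z_cfp) == length(z_yfp))
  out <- rep("no_cfp_effect", length(z_cfp))
  sig <- abs(z_cfp) > threshold
  out[sig & sign(z_cfp) == sign(z_yfp)] <- "same_direction"
  out[sig & sign(z_cfp) != sign(z_yfp)] <- "opposite_direction"
  out
}

#' Per-class summary of frequency, effects and dominance
#'
#' Builds the class-by-class summary of a screen: counts and fractions of
#' the classified mutants, median haploid |Z| and direction composition,
#' diploid medians, model II slope of diploid on haploid YFP Z, fraction
#' recessive, and the CFP (reference-allele) statistics. Genotypes lacking
#' diploid data contribute to haploid statistics only; an empty class
#' yields a zero-count row rather than an error.
#'
#' @param assignments data.frame with `genotype_id`, `class` (from
#'   [classify_mutants()]); `"ambiguous"` genotypes are excluded from the
#'   class comparisons.
#' @param haploid_z data.frame with `genotype_id`, `z_median` for haploids.
#' @param diploid_measurements optional data.frame with `genotype_id`,
#'   `z_yfp`, `z_cfp` from diploid crosses (diploid-specific controls).
#' @param threshold significance threshold used for direction, recessivity
#'   and CFP-effect calls.
#' @param regression_method model II variant, `"ma"` or `"sma"`.
#' @return data.frame of class `class_summary`, one row per class.
#' @export
build_summary_table <- function(assignments, haploid_z,
                                diploid_measurements = NULL,
                                threshold = z_threshold(0.01),
                                regression_method = c("ma", "sma")) {
  regression_method <- match.arg(regression_method)
  keep <- assignments$class %in% mutation_classes
  assignments <- assignments[keep, , drop = FALSE]
  total <- nrow(assignments)
  rows <- lapply(mutation_classes, function(cl) {
    ids <- assignments$genotype_id[assignments$class == cl]
    zh_all <- haploid_z$z_median[match(ids, haploid_z$genotype_id)]
    zh <- zh_all[is.finite(zh_all)]
    count <- length(ids)
    row <- data.frame(class = cl, count = count,
                      fraction = if (total > 0) count / total else 0,
                      median_absZ_haploid = if (count) median(abs(zh)) else NA_real_,
                      frac_increase = if (count) mean(zh > 0) else NA_real_)
    if (!is.null(diploid_measurements)) {
      di <- diploid_measurements[match(ids, diploid_measurements$genotype_id), ]
      okd <- is.finite(di$z_yfp) & is.finite(zh_all)
      zd <- di$z_yfp[okd]; zc <- di$z_cfp[okd]; zh_d <- zh_all[okd]
      nd <- sum(okd)
      row$n_diploid <- nd
      row$median_absZ_diploid <- if (nd) median(abs(zd)) else NA_real_
      row$slope_hap_dip <- if (nd >= 3 && sd(zh_d) > 0 && sd(zd) > 0) {
        model2_regression(zh_d, zd, regression_method)$slope
      } else NA_real_
      row$frac_recessive <- if (nd) mean(recessivity_call(zd, threshold)) else NA_real_
      row$median_absZ_cfp <- if (nd) median(abs(zc)) else NA_real_
      row$slope_yfp_cfp <- if (nd >= 3 && sd(zd) > 0 && sd(zc) > 0) {
        model2_regression(zd, zc, regression_method)$slope
      } else NA_real_
      row$frac_cfp_altered <- if (nd) mean(abs(zc) > threshold) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("class_summary", "data.frame")
  out
}
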