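# core event generator: log10 FSC ~ N(mu, sd); log10 fluorescence is linear
# in log10 FSC plus residual noise plus any genotype/culture shift
sim_events <- function(n, config, yfp_shift = 0, with_cfp = FALSE, cfp_shift = 0) {
  fsc <- rnorm(n, config$fsc_mean, config$fsc_sd)
  yfp <- config$yfp_intercept + config$yfp_slope * fsc +
    rnorm(n, 0, config$yfp_resid_sd) + yfp_shift
  out <- data.frame(fsc = fsc, yfp = yfp)
  if (with_cfp) {
    out$cfp <- config$cfp_intercept + config$yfp_slope * fsc +
      rnorm(n, 0, config$cfp_resid_sd) + cfp_shift
  }
  out
}

# a culture-to-culture shift of delta in log10 fluorescence moves the
# median-ratio phenotype by ~delta / fsc_mean, so noise specified on the
# phenotype scale is injected as noise_sd * fsc_mean in log10 units
culture_shift <- function(noise_sd, config) rnorm(1, 0, noise_sd * config$fsc_mean)

#' Simulate a control (unmutagenized) cell population
#'
#' Per-cell cytometry events for cells carrying the unmutated reporter:
#' log10 FSC is normal, log10 YFP follows the configured log-linear model.
#'
#' @param config a [sim_config()].
#' @param n number of events; defaults to `config$n_cells_control`.
#' @param seed RNG seed (defaults to `config$seed`); the caller's RNG state
#'   is left untouched.
#' @return data.frame with `genotype_id`, `fsc`, `yfp` (log10 units).
#' @export
simulate_control_population <- function(config, n = config$n_cells_control,
                                        seed = config$seed) {
  if (n < 1) cond_error("n must be >= 1", "mutscreen_bad_n")
  with_seed(seed, {
    ev <- sim_events(n, config)
    cbind(genotype_id = "control", ev)
  })
}

#' Simulate an EMS-treated cell population with a Poisson mutation load
#'
#' Each cell carries `K ~ Poisson(mean_load)` activity-affecting mutations.
#' Every mutation draws a class from `class_weights` and a multiplicative
#' effect from that class's effect distribution; effects of multiple
#' mutations in one cell combine multiplicatively (additively in log10).
#'
#' @inheritParams simulate_control_population
#' @param n number of cells; defaults to `config$n_cells_treated`.
#' @return A list with `events` (as in [simulate_control_population()]) and
#'   `truth`, a data.frame of per-cell truth records (`genotype_id`,
#'   `n_mutations`, `classes`, `effect` = total multiplicative effect) whose
#'   `"mutations"` attribute holds the per-mutation long table.
#' @export
simulate_treated_population <- function(config, n = config$n_cells_treated,
                                        seed = config$seed) {
  if (n < 1) cond_error("n must be >= 1", "mutscreen_bad_n")
  validate_sim_config(config)
  with_seed(seed, {
    k <- rpois(n, config$mean_load)
    hit <- which(k > 0)
    m <- sum(k)
    shift <- numeric(n)
    mut <- data.frame(genotype_id = integer(0), class = character(0),
                      effect = numeric(0))
    if (m > 0) {
      cell <- rep(hit, k[hit])
      cls <- sample(mutation_classes, m, replace = TRUE,
                    prob = config$class_weights[mutation_classes])
      le <- draw_log10_effects(cls, config)
      shift_by_cell <- rowsum(le, cell)
      shift[as.integer(rownames(shift_by_cell))] <- shift_by_cell[, 1]
      mut <- data.frame(genotype_id = cell, class = cls, effect = 10^le)
    }
    ev <- sim_events(n, config, yfp_shift = shift)
    truth <- data.frame(genotype_id = seq_len(n), n_mutations = k,
                        effect = 10^shift)
    truth$classes <- ""
    if (m > 0) {
      agg <- tapply(mut$class, mut$genotype_id, paste, collapse = ",")
      truth$classes[as.integer(names(agg))] <- unname(agg)
    }
    attr(truth, "mutations") <- mut
    list(events = cbind(genotype_id = seq_len(n), ev), truth = truth)
  })
}

# signed log10 effects for a vector of class labels
draw_log10_effects <- function(classes, config) {
  le <- numeric(length(classes))
  for (cl in unique(classes)) {
    i <- classes == cl
    p <- config$effect_params[[cl]]
    mag <- rlnorm(sum(i), p$meanlog, p$sdlog)
    sgn <- ifelse(runif(sum(i)) < p$p_positive, 1, -1)
    le[i] <- sgn * mag
  }
  le
}

#' Simulate one clonal haploid culture
#'
#' @param config a [sim_config()].
#' @param log10_effect genotype effect on log10 reporter activity.
#' @param n_events events recorded; defaults to `config$events_per_culture`.
#' @param seed RNG seed.
#' @return data.frame with `fsc`, `yfp`.
#' @export
simulate_haploid_culture <- function(config, log10_effect = 0,
                                     n_events = config$events_per_culture,
                                     seed = NULL) {
  with_seed(seed, {
    sim_events(n_events, config,
               yfp_shift = log10_effect + culture_shift(config$culture_noise_sd, config))
  })
}

#' Simulate a heterozygous diploid cross against the CFP reference
#'
#' The mutant haploid genotype is crossed to a reference strain whose
#' reporter drives CFP. The diploid YFP channel reads out the mutant allele
#' and the CFP channel the reference allele: coding and cis mutations shift
#' YFP only (scaled by their dominance coefficient), trans mutations shift
#' both channels by `dominance * log10(effect)`, and CNV genotypes shift YFP
#' by their planted effect while multiplying CFP by `config$cnv_cfp_effect`.
#'
#' @param truth_record one-row data.frame with `class`, `effect`,
#'   `dominance` (class `"control"` or effect 1 gives the ancestral cross).
#' @param config a [sim_config()].
#' @param n_events events recorded; defaults to
#'   `config$events_per_diploid_culture`.
#' @param seed RNG seed.
#' @return data.frame with `fsc`, `yfp`, `cfp`.
#' @export
simulate_diploid_cross <- function(truth_record, config,
                                   n_events = config$events_per_diploid_culture,
                                   seed = NULL) {
  stopifnot(is.data.frame(truth_record), nrow(truth_record) == 1)
  cls <- truth_record$class
  le <- log10(truth_record$effect)
  d <- truth_record$dominance
  if (cls == "control" || truth_record$effect == 1) {
    y <- 0; cf <- 0
  } else if (cls == "trans") {
    y <- d * le; cf <- d * le
  } else if (cls == "cnv") {
    y <- d * le; cf <- log10(config$cnv_cfp_effect)
  } else {  # coding / cis act allele-specifically on the YFP allele
    y <- d * le; cf <- 0
  }
  with_seed(seed, {
    sim_events(n_events, config, with_cfp = TRUE,
               yfp_shift = y + culture_shift(config$diploid_culture_noise_sd, config),
               cfp_shift = cf + culture_shift(config$diploid_culture_noise_sd, config))
  })
}

#' Simulate a pyrosequencing copy-number assay
#'
#' YFP-supporting reads are binomial with success probability
#' `copies_yfp / (copies_yfp + 1)` (the expected allele fraction for
#' `copies_yfp` reporter copies against one reference copy).
#'
#' @param copies_yfp reporter copies (>= 1).
#' @param config a [sim_config()] (supplies `pyro_reads`).
#' @param seed RNG seed.
#' @return Named vector `c(yfp_reads, cfp_reads)`.
#' @export
simulate_pyro_assay <- function(copies_yfp, config, seed = NULL) {
  if (copies_yfp < 1) cond_error("copies_yfp must be >= 1", "mutscreen_bad_copies")
  if (config$pyro_reads < 1) cond_error("pyro_reads must be >= 1", "mutscreen_zero_reads")
  with_seed(seed, {
    y <- rbinom(1, config$pyro_reads, expected_allele_fraction(copies_yfp))
    c(yfp_reads = y, cfp_reads = config$pyro_reads - y)
  })
}

#' Simulate an EMS-type reporter-gene mutation record for a mutation class
#'
#' EMS predominantly causes G/C to A/T transitions, so records carry G->A or
#' C->T substitutions. Coding-class mutations land in the CDS at a position
#' where the transition is nonsynonymous or nonsense (verified by
#' translation); cis-class mutations land in the promoter span. Trans-acting
#' and CNV genotypes carry no reporter-gene mutation and return `NULL`.
#'
#' @param class_label one of `"coding"`, `"cnv"`, `"cis"`, `"trans"`.
#' @param annotation a [reporter_annotation()].
#' @param seed RNG seed.
#' @return `NULL`, or a one-row data.frame with `position`, `ref`, `alt`,
#'   `region`, `coding_effect`.
#' @export
simulate_transgene_mutation <- function(class_label, annotation, seed = NULL) {
  stopifnot(class_label %in% mutation_classes)
  if (class_label %in% c("trans", "cnv")) return(NULL)
  with_seed(seed, {
    if (class_label == "coding") {
      cand <- ems_nonsilent_sites(annotation)
      if (nrow(cand) == 0) {
        cond_error("CDS has no EMS-mutable nonsilent site", "mutscreen_bad_annotation")
      }
      pick <- cand[sample.int(nrow(cand), 1), ]
      data.frame(position = pick$position, ref = pick$ref, alt = pick$alt,
                 region = "cds", coding_effect = pick$effect)
    } else {  # cis: promoter position; promoter sequence is not modelled,
              # the record asserts a G/C base consistent with EMS chemistry
      pos <- sample(seq(annotation$promoter[1], annotation$promoter[2]), 1)
      if (runif(1) < 0.5) {
        data.frame(position = pos, ref = "G", alt = "A",
                   region = "promoter", coding_effect = "n/a")
      } else {
        data.frame(position = pos, ref = "C", alt = "T",
                   region = "promoter", coding_effect = "n/a")
      }
    }
  })
}

# all CDS sites where the EMS transition (G->A / C->T) is nonsynonymous or
# nonsense, with TSS-relative positions
ems_nonsilent_sites <- function(annotation) {
  bases <- strsplit(annotation$cds_sequence, "")[[1]]
  idx <- which(bases %in% c("G", "C"))
  alt <- ifelse(bases[idx] == "G", "A", "T")
  eff <- vapply(seq_along(idx), function(i) {
    off <- idx[i]
    ci <- (off - 1L) %/% 3L
    codon <- paste(bases[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    mutated <- codon
    substr(mutated, off - ci * 3L, off - ci * 3L) <- alt[i]
    aa0 <- translate_codon(codon); aa1 <- translate_codon(mutated)
    if (aa1 == "*" && aa0 != "*") "nonsense"
    else if (aa1 == aa0) "synonymous" else "nonsynonymous"
  }, character(1))
  keep <- eff != "synonymous"
  data.frame(position = annotation$cds[1] + idx[keep] - 1L,
             ref = bases[idx][keep], alt = alt[keep], effect = eff[keep])
}

#' Simulate a complete mutant-collection screen with truth table
#'
#' Builds the full dataset the downstream analysis consumes: replicate
#' haploid and diploid control cultures, one haploid culture and one diploid
#' cross per mutant genotype, a pyrosequencing copy-number assay per
#' genotype, reporter-gene mutation records for coding and cis genotypes,
#' and the truth table recording every planted effect. Each genotype carries
#' exactly one mutation (multi-hit genotypes are ~1% of mutants under the
#' default load and are modelled only in
#' [simulate_treated_population()]).
#'
#' @param config a [sim_config()].
#' @param class_counts named integer vector over coding/cnv/cis/trans fixing
#'   the panel composition, or `NULL` to draw classes from
#'   `config$class_weights`.
#' @param n_mutant_genotypes panel size when `class_counts` is `NULL`.
#' @param annotation a [reporter_annotation()].
#' @param seed master seed; per-genotype sub-seeds are derived
#'   deterministically from it.
#' @return An object of class `screen_dataset`: a list with `haploid_events`,
#'   `diploid_events` (both with `genotype_id`, `replicate` columns),
#'   `pyro_assays`, `transgene_mutations`, `truth`, `annotation`, `config`.
#' @export
simulate_screen <- function(config = sim_config(),
                            class_counts = c(coding = 16L, cnv = 22L,
                                             cis = 4L, trans = 179L),
                            n_mutant_genotypes = NULL,
                            annotation = default_annotation(),
                            seed = config$seed) {
  validate_sim_config(config)
  classes <- if (!is.null(class_counts)) {
    stopifnot(all(names(class_counts) %in% mutation_classes))
    rep(names(class_counts), class_counts)
  } else {
    stopifnot(n_mutant_genotypes >= 0)
    with_seed(seed + 1L, sample(mutation_classes, n_mutant_genotypes,
                                replace = TRUE,
                                prob = config$class_weights[mutation_classes]))
  }
  n_mut <- length(classes)
  ids <- sprintf("M%04d", seq_len(n_mut))
  seeds <- derive_seeds(seed, 4L * n_mut + 2L * config$n_control_replicates + 2L)

  truth <- with_seed(seeds[length(seeds)], {
    le <- if (n_mut > 0) draw_log10_effects(classes, config) else numeric(0)
    data.frame(genotype_id = ids, class = classes,
               n_mutations = rep(1L, n_mut), effect = 10^le,
               dominance = unname(config$dominance[classes]),
               copies_yfp = ifelse(classes == "cnv", config$copies_cnv, 1L))
  })

  k <- 0L
  nxt <- function() { k <<- k + 1L; seeds[k] }

  hap <- vector("list", config$n_control_replicates + n_mut)
  for (i in seq_len(config$n_control_replicates)) {
    ev <- simulate_haploid_culture(config, 0, seed = nxt())
    hap[[i]] <- cbind(genotype_id = "control", replicate = i, ev)
  }
  for (j in seq_len(n_mut)) {
    ev <- simulate_haploid_culture(config, log10(truth$effect[j]), seed = nxt())
    hap[[config$n_control_replicates + j]] <-
      cbind(genotype_id = ids[j], replicate = 1L, ev)
  }

  ctrl_rec <- data.frame(class = "control", effect = 1, dominance = 0)
  dip <- vector("list", config$n_control_replicates + n_mut)
  for (i in seq_len(config$n_control_replicates)) {
    ev <- simulate_diploid_cross(ctrl_rec, config, seed = nxt())
    dip[[i]] <- cbind(genotype_id = "control", replicate = i, ev)
  }
  for (j in seq_len(n_mut)) {
    ev <- simulate_diploid_cross(truth[j, ], config, seed = nxt())
    dip[[config$n_control_replicates + j]] <-
      cbind(genotype_id = ids[j], replicate = 1L, ev)
  }

  pyro <- do.call(rbind, lapply(seq_len(n_mut), function(j) {
    r <- simulate_pyro_assay(truth$copies_yfp[j], config, seed = nxt())
    data.frame(genotype_id = ids[j], yfp_reads = r[["yfp_reads"]],
               cfp_reads = r[["cfp_reads"]])
  }))
  if (is.null(pyro)) {
    pyro <- data.frame(genotype_id = character(0), yfp_reads = integer(0),
                       cfp_reads = integer(0))
  }

  tg <- do.call(rbind, lapply(seq_len(n_mut), function(j) {
    rec <- simulate_transgene_mutation(truth$class[j], annotation, seed = nxt())
    if (is.null(rec)) return(NULL)
    cbind(genotype_id = ids[j], rec)
  }))
  if (is.null(tg)) {
    tg <- data.frame(genotype_id = character(0), position = integer(0),
                     ref = character(0), alt = character(0),
                     region = character(0), coding_effect = character(0))
  }
  truth$position <- tg$position[match(truth$genotype_id, tg$genotype_id)]
  truth$ref <- tg$ref[match(truth$genotype_id, tg$genotype_id)]
  truth$alt <- tg$alt[match(truth$genotype_id, tg$genotype_id)]

  structure(list(haploid_events = do.call(rbind, hap),
                 diploid_events = do.call(rbind, dip),
                 pyro_assays = pyro, transgene_mutations = tg,
                 truth = truth, annotation = annotation, config = config),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  n_mut <- nrow(x$truth)
  cat(sprintf("Simulated screen: %d mutant genotypes (%s), %d control replicates/ploidy\n",
              n_mut,
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            as.integer(table(x$truth$class))), collapse = " "),
              x$config$n_control_replicates))
  cat(sprintf("  haploid events: %d rows; diploid events: %d rows\n",
              nrow(x$haploid_events), nrow(x$diploid_events)))
  invisible(x)
}
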