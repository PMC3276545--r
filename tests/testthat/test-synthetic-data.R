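test_that("seeded simulations are bit-reproducible and seeds matter", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_control_population(cfg, n = 2000)
  b <- simulate_control_population(cfg, n = 2000)
  expect_identical(a, b)
  d <- simulate_control_population(cfg, n = 2000, seed = 12)
  expect_false(identical(a$yfp, d$yfp))

  ta <- simulate_treated_population(cfg, n = 2000)
  tb <- simulate_treated_population(cfg, n = 2000)
  expect_identical(ta$events, tb$events)
  expect_identical(ta$truth$effect, tb$truth$effect)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_control_population(tiny_config(), n = 100))
  expect_identical(before, .Random.seed)
})

test_that("noise-free control events fall exactly on the FSC-YFP line", {
  cfg <- tiny_config(yfp_resid_sd = 0, yfp_slope = 1, yfp_intercept = 0)
  ev <- simulate_control_population(cfg, n = 500)
  expect_equal(ev$yfp, ev$fsc)
})

test_that("log FSC and log YFP are tightly correlated under defaults", {
  # generating model: cor = slope*fsc_sd / sqrt((slope*fsc_sd)^2 + resid^2)
  # = 0.1/sqrt(0.01 + 0.012^2) = 0.993 under the default parameters
  ev <- simulate_control_population(sim_config(seed = 4), n = 50000)
  expect_gt(cor(ev$fsc, ev$yfp), 0.9)
})

test_that("treated population carries a Poisson mutation load", {
  cfg <- sim_config(seed = 8, mean_load = 0.0303)
  tp <- simulate_treated_population(cfg, n = 1e6)
  frac <- mean(tp$truth$n_mutations >= 1)
  expected <- 1 - exp(-0.0303)            # 0.029846 in closed form
  se <- sqrt(expected * (1 - expected) / 1e6)
  expect_lt(abs(frac - expected), 3 * se)
  # truth bookkeeping is self-consistent
  mut <- attr(tp$truth, "mutations")
  expect_equal(nrow(mut), sum(tp$truth$n_mutations))
  expect_true(all(tp$truth$effect > 0))
})

test_that("zero mean load reproduces the control distribution in law", {
  cfg <- tiny_config(seed = 3, mean_load = 0)
  tp <- simulate_treated_population(cfg, n = 20000)
  co <- simulate_control_population(cfg, n = 20000, seed = 31)
  expect_true(all(tp$truth$n_mutations == 0))
  expect_lt(abs(mean(tp$events$yfp) - mean(co$yfp)), 4 * 0.1 / sqrt(20000) * 2)
  expect_lt(abs(sd(tp$events$yfp) / sd(co$yfp) - 1), 0.05)
})

test_that("coding-only mutation loads only ever decrease reporter activity", {
  cfg <- tiny_config(seed = 5, mean_load = 0.5,
                     class_weights = c(coding = 1, cnv = 0, cis = 0, trans = 0))
  tp <- simulate_treated_population(cfg, n = 5000)
  mut <- attr(tp$truth, "mutations")
  expect_gt(nrow(mut), 100)
  expect_true(all(mut$class == "coding"))
  expect_true(all(mut$effect < 1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_weights = c(coding = .5, cnv = .5, cis = .1, trans = 0)),
               class = "mutscreen_bad_config")
  expect_error(sim_config(mean_load = -1), class = "mutscreen_bad_config")
  expect_error(sim_config(dominance = c(coding = 2, cnv = 1, cis = 1, trans = 0)),
               class = "mutscreen_bad_config")
  expect_error(sim_config(pyro_reads = 0), class = "mutscreen_bad_config")
  expect_error(simulate_control_population(tiny_config(), n = 0),
               class = "mutscreen_bad_n")
})

test_that("pyrosequencing assay follows the n/(n+1) allele-fraction model", {
  cfg <- tiny_config(pyro_reads = 200000L)
  r1 <- simulate_pyro_assay(1, cfg, seed = 2)
  f1 <- r1[["yfp_reads"]] / sum(r1)
  expect_lt(abs(f1 - 1 / 2), 3 * sqrt(0.25 / 200000))
  r2 <- simulate_pyro_assay(2, cfg, seed = 2)
  f2 <- r2[["yfp_reads"]] / sum(r2)
  expect_lt(abs(f2 - 2 / 3), 3 * sqrt(2 / 9 / 200000))
  expect_equal(sum(r1), 200000)
  expect_error(simulate_pyro_assay(0, cfg), class = "mutscreen_bad_copies")
})

test_that("diploid crosses respect allele specificity and dominance", {
  cfg <- tiny_config(events_per_diploid_culture = 30000L,
                     diploid_culture_noise_sd = 1e-6)
  ctrl <- simulate_diploid_cross(data.frame(class = "control", effect = 1,
                                            dominance = 0), cfg, seed = 7)
  # fully recessive trans mutation: indistinguishable from the control cross
  tr0 <- simulate_diploid_cross(data.frame(class = "trans", effect = 2,
                                           dominance = 0), cfg, seed = 8)
  tol <- 5 * cfg$yfp_resid_sd / sqrt(30000) + 5 * cfg$fsc_sd / sqrt(30000)
  expect_lt(abs(mean(tr0$yfp) - mean(ctrl$yfp)), tol)
  expect_lt(abs(mean(tr0$cfp) - mean(ctrl$cfp)), tol)
  # cis with d = 1: YFP shifted by the haploid effect, CFP untouched
  cis <- simulate_diploid_cross(data.frame(class = "cis", effect = 2,
                                           dominance = 1), cfg, seed = 9)
  expect_lt(abs(mean(cis$yfp) - mean(ctrl$yfp) - log10(2)), tol)
  expect_lt(abs(mean(cis$cfp) - mean(ctrl$cfp)), tol)
  # dominant trans hits both channels
  tr1 <- simulate_diploid_cross(data.frame(class = "trans", effect = 2,
                                           dominance = 1), cfg, seed = 10)
  expect_lt(abs(mean(tr1$cfp) - mean(ctrl$cfp) - log10(2)), tol)
  # CNV: YFP up, CFP down (reference-allele repression)
  cnv <- simulate_diploid_cross(data.frame(class = "cnv", effect = 1.5,
                                           dominance = 1), cfg, seed = 11)
  expect_gt(mean(cnv$yfp), mean(ctrl$yfp))
  expect_lt(mean(cnv$cfp), mean(ctrl$cfp))
})

test_that("reporter-gene mutation records match their class", {
  ann <- default_annotation()
  expect_null(simulate_transgene_mutation("trans", ann, seed = 1))
  expect_null(simulate_transgene_mutation("cnv", ann, seed = 1))
  for (s in 1:10) {
    rec <- simulate_transgene_mutation("coding", ann, seed = s)
    expect_equal(locate_mutation(rec$position, ann), "cds")
    expect_true(rec$coding_effect %in% c("nonsynonymous", "nonsense"))
    # the translation-based caller agrees with the record
    expect_equal(coding_effect(rec$position, rec$ref, rec$alt, ann),
                 rec$coding_effect)
    # EMS chemistry: G->A or C->T only
    expect_true(paste0(rec$ref, rec$alt) %in% c("GA", "CT"))
    cis <- simulate_transgene_mutation("cis", ann, seed = s)
    expect_equal(locate_mutation(cis$position, ann), "promoter")
    expect_lt(cis$position, 0)
  }
})

test_that("most mutants are recessive when trans mutations are fully recessive", {
  # class weights 7/10/2/81% with dominance 1/1/1/0: only the trans class
  # (99% of which stay under |Z| = 2.58 in diploids) contributes recessives,
  # so the expected overall recessive fraction is 0.81 * 0.99
  cfg <- sim_config(seed = 21, n_control_replicates = 50L,
                    events_per_culture = 50L,
                    events_per_diploid_culture = 200L)
  ds <- simulate_screen(cfg, class_counts = NULL, n_mutant_genotypes = 10000L)
  dy <- screen_zscores(culture_phenotypes(ds$diploid_events, "yfp",
                                          min_events_used = 20L),
                       min_controls = 10L)
  m <- dy[dy$genotype_id != "control", ]
  expect_gte(mean(recessivity_call(m$z_median)), 0.80)
})

test_that("screen datasets are internally consistent", {
  ds <- simulate_screen(tiny_config(seed = 2),
                        class_counts = c(coding = 3, cnv = 3, cis = 2, trans = 6))
  expect_s3_class(ds, "screen_dataset")
  expect_equal(nrow(ds$truth), 14)
  expect_setequal(unique(ds$haploid_events$genotype_id),
                  c("control", ds$truth$genotype_id))
  expect_setequal(ds$pyro_assays$genotype_id, ds$truth$genotype_id)
  # only coding and cis genotypes carry reporter-gene mutations
  expect_setequal(ds$transgene_mutations$genotype_id,
                  ds$truth$genotype_id[ds$truth$class %in% c("coding", "cis")])
  # CNV genotypes carry two reporter copies, all others one
  expect_true(all(ds$truth$copies_yfp[ds$truth$class == "cnv"] == 2))
  expect_true(all(ds$truth$copies_yfp[ds$truth$class != "cnv"] == 1))
  # event counts per culture match the configured sizes
  tab <- table(paste(ds$haploid_events$genotype_id, ds$haploid_events$replicate))
  expect_true(all(tab == ds$config$events_per_culture))
  tab2 <- table(paste(ds$diploid_events$genotype_id, ds$diploid_events$replicate))
  expect_true(all(tab2 == ds$config$events_per_diploid_culture))
})
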