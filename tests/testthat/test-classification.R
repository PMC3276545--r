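# compact annotation for codon-level tests: CDS = ATG GAA TGG CTG TAA
mini_annotation <- function() {
  reporter_annotation(promoter_span = c(-10L, -1L), cds_span = c(1L, 15L),
                      terminator_span = c(16L, 25L),
                      cds_sequence = "ATGGAATGGCTGTAA")
}

test_that("mutation positions map onto the annotation spans", {
  ann <- default_annotation()
  expect_equal(locate_mutation(-140, ann), "promoter")
  expect_equal(locate_mutation(c(-255, -240), ann), c("promoter", "promoter"))
  expect_equal(locate_mutation(348, ann), "cds")
  expect_equal(locate_mutation(800, ann), "terminator")
  expect_equal(locate_mutation(5000, ann), "none")
  expect_equal(locate_mutation(5, ann), "none")      # 5' leader
  expect_error(locate_mutation(0, ann), class = "mutscreen_bad_position")
})

test_that("annotation validation rejects malformed reporters", {
  expect_error(reporter_annotation(c(-10, -1), c(1, 14), c(16, 25), "ATGGAATGGCTGTA"),
               class = "mutscreen_bad_annotation")  # length not divisible by 3
  expect_error(reporter_annotation(c(-10, 2), c(1, 15), c(16, 25),
                                   "ATGGAATGGCTGTAA"),
               class = "mutscreen_bad_annotation")  # overlapping spans
  expect_error(reporter_annotation(c(-10, -1), c(1, 15), c(16, 25), "ATGGAANGGCTGTAA"),
               class = "mutscreen_bad_annotation")  # ambiguous base
})

test_that("coding effects are called by codon translation", {
  ann <- mini_annotation()
  expect_equal(coding_effect(4, "G", "A", ann), "nonsynonymous")  # GAA->AAA, E->K
  expect_equal(coding_effect(9, "G", "A", ann), "nonsense")       # TGG->TGA, W->*
  expect_equal(coding_effect(12, "G", "A", ann), "synonymous")    # CTG->CTA, L->L
  expect_error(coding_effect(4, "C", "T", ann), class = "mutscreen_ref_mismatch")
  expect_error(coding_effect(-5, "G", "A", ann), class = "mutscreen_bad_mutation")
})

test_that("the bundled reporter reproduces the documented landmark calls", {
  ann <- default_annotation()
  # position +348 maps to a third codon position where G->A is silent
  expect_equal(coding_effect(348, "G", "A", ann), "synonymous")
  # GC content against a direct per-base count
  b <- strsplit(ann$cds_sequence, "")[[1]]
  expect_equal(gc_content(ann$cds_sequence), 100 * sum(b %in% c("G", "C")) / length(b))
  expect_equal(round(gc_content(ann$cds_sequence), 2), 35.56)
  expect_equal(nchar(ann$cds_sequence), 717)        # 238 aa + stop
})

test_that("gc_content counts G+C and rejects ambiguity codes", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("acgt"), 50)
  expect_error(gc_content("ACGN"), class = "mutscreen_bad_sequence")
})

test_that("copy-number calls split the 1/2 vs 2/3 allele-fraction clusters", {
  expect_equal(call_copy_number(500, 500)$copies, 1L)
  expect_equal(call_copy_number(667, 333)$copies, 2L)
  expect_error(call_copy_number(0, 0), class = "mutscreen_zero_reads")
  # observed fraction inside the guard band is indeterminate
  mid <- call_copy_number(583, 417)
  expect_true(is.na(mid$copies))
  expect_equal(mid$qc_flag, "indeterminate")
  expect_equal(call_copy_number(30, 30)$qc_flag, "low_depth")
  # calls are monotone in the YFP fraction
  y <- seq(300, 800, by = 10)
  calls <- call_copy_number(y, 1000 - y)$copies
  calls[is.na(calls)] <- 1.5
  expect_true(all(diff(calls) >= 0))
  # expected fraction n/(n+1) is strictly increasing in n
  expect_true(all(diff(expected_allele_fraction(1:6)) > 0))
})

test_that("class assignment follows the evidence lattice", {
  nonsyn <- data.frame(position = 100, ref = "G", alt = "A", region = "cds",
                       coding_effect = "nonsynonymous")
  silent <- data.frame(position = 348, ref = "G", alt = "A", region = "cds",
                       coding_effect = "synonymous")
  promo <- data.frame(position = -140, ref = "G", alt = "A",
                      region = "promoter", coding_effect = "n/a")
  one_copy <- call_copy_number(500, 500)
  two_copy <- call_copy_number(667, 333)
  indet <- call_copy_number(583, 417)

  expect_equal(assign_class(nonsyn, one_copy)$class, "coding")
  expect_equal(assign_class(nonsyn, NULL)$class, "coding")
  expect_equal(assign_class(promo, one_copy)$class, "cis")
  expect_equal(assign_class(NULL, two_copy)$class, "cnv")
  expect_equal(assign_class(NULL, one_copy)$class, "trans")
  # the synonymous change is uninformative: copy number decides
  expect_equal(assign_class(silent, one_copy)$class, "trans")
  expect_equal(assign_class(silent, two_copy)$class, "cnv")
  # no informative evidence at all -> ambiguous
  expect_equal(assign_class(NULL, NULL)$class, "ambiguous")
  expect_equal(assign_class(silent, NULL)$class, "ambiguous")
  expect_equal(assign_class(NULL, indet)$class, "ambiguous")
  # coding evidence outranks a CNV call
  expect_equal(assign_class(nonsyn, two_copy)$class, "coding")
  conflicted <- data.frame(position = -140, ref = "G", alt = "A",
                           region = "promoter", coding_effect = "nonsynonymous")
  expect_error(assign_class(conflicted, NULL), class = "mutscreen_evidence_conflict")
})

test_that("classification recovers the planted truth on a clean screen", {
  cfg <- tiny_config(seed = 27, pyro_reads = 20000L)
  ds <- simulate_screen(cfg, class_counts = c(coding = 5, cnv = 5, cis = 3, trans = 12))
  cn <- call_copy_number(ds$pyro_assays$yfp_reads, ds$pyro_assays$cfp_reads)
  cn <- cbind(genotype_id = ds$pyro_assays$genotype_id, cn)
  asg <- classify_mutants(ds$truth$genotype_id, ds$transgene_mutations, cn)
  expect_equal(asg$class, ds$truth$class)
  # every genotype gets exactly one class (total function)
  expect_equal(nrow(asg), nrow(ds$truth))
  expect_true(all(asg$class %in% c("coding", "cnv", "cis", "trans", "ambiguous")))
  # withholding the assay makes CNV/trans genotypes ambiguous, not misassigned
  asg2 <- classify_mutants(ds$truth$genotype_id, ds$transgene_mutations, cn[0, ])
  expect_true(all(asg2$class[ds$truth$class %in% c("cnv", "trans")] == "ambiguous"))
  expect_equal(asg2$class[ds$truth$class == "coding"],
               rep("coding", 5))
})

test_that("simulated mutation classes follow the configured weights", {
  cfg <- tiny_config(seed = 28, mean_load = 0.1)
  tp <- simulate_treated_population(cfg, n = 2e5)
  mut <- attr(tp$truth, "mutations")
  n <- nrow(mut)
  expect_gt(n, 15000)
  freq <- prop.table(table(factor(mut$class, c("coding", "cnv", "cis", "trans"))))
  for (cl in names(freq)) {
    p <- cfg$class_weights[[cl]]
    expect_lt(abs(freq[[cl]] - p), 4 * sqrt(p * (1 - p) / n))
  }
})
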