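#' Locate a mutation within the reporter annotation
#'
#' @param position TSS-relative coordinate (no position 0).
#' @param annotation a [reporter_annotation()].
#' @return `"promoter"`, `"cds"`, `"terminator"`, or `"none"` (vectorised).
#' @examples
#' ann <- default_annotation()
#' locate_mutation(-140, ann)  # promoter
#' locate_mutation(348, ann)   # cds
#' @export
locate_mutation <- function(position, annotation) {
  stopifnot(inherits(annotation, "reporter_annotation"))
  if (any(position == 0)) {
    cond_error("position 0 is undefined in TSS-relative coordinates",
               "mutscreen_bad_position")
  }
  inside <- function(s) position >= s[1] & position <= s[2]
  out <- rep("none", length(position))
  out[inside(annotation$terminator)] <- "terminator"
  out[inside(annotation$cds)] <- "cds"
  out[inside(annotation$promoter)] <- "promoter"
  out
}

#' Predicted coding consequence of a CDS substitution
#'
#' Maps a TSS-relative position into the CDS, checks the reference base
#' against the annotated sequence, and translates the affected codon before
#' and after the substitution with the standard nuclear genetic code.
#'
#' @param position TSS-relative coordinate inside the CDS span.
#' @param ref,alt single reference/alternate nucleotides.
#' @param annotation a [reporter_annotation()].
#' @return `"synonymous"`, `"nonsynonymous"`, or `"nonsense"` (stop gain).
#' @export
coding_effect <- function(position, ref, alt, annotation) {
  stopifnot(length(position) == 1, nchar(ref) == 1, nchar(alt) == 1)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) cond_error("ref and alt must differ", "mutscreen_bad_mutation")
  if (locate_mutation(position, annotation) != "cds") {
    cond_error("position is not inside the CDS span", "mutscreen_bad_mutation")
  }
  off <- cds_offset(position, annotation)
  if (substr(annotation$cds_sequence, off, off) != ref) {
    cond_error(sprintf("reference base mismatch at CDS offset %d: annotation has %s, record says %s",
                       off, substr(annotation$cds_sequence, off, off), ref),
               "mutscreen_ref_mismatch")
  }
  codon_idx <- (off - 1L) %/% 3L
  codon <- substr(annotation$cds_sequence, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  pos_in_codon <- off - codon_idx * 3L
  mutated <- codon
  substr(mutated, pos_in_codon, pos_in_codon) <- alt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(mutated)
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  if (aa_alt == aa_ref) return("synonymous")
  "nonsynonymous"
}

#' Call reporter copy number from pyrosequencing read counts
#'
#' With `n` reporter (YFP) copies against one reference (CFP) copy the
#' expected YFP allele fraction is `n / (n + 1)`: 1/2 for a single copy,
#' 2/3 for a duplication. The caller splits at the midpoint 7/12 with an
#' indeterminate buffer of `guard_se` binomial standard errors (computed at
#' the threshold fraction and the observed read depth) on either side.
#'
#' @param yfp_reads,cfp_reads read counts (vectorised).
#' @param threshold decision point on the YFP fraction (default 7/12).
#' @param guard_se half-width of the indeterminate zone, in binomial SEs.
#' @param min_reads depths below this are flagged and called indeterminate.
#' @return A data.frame with `yfp_reads`, `cfp_reads`, `yfp_fraction`,
#'   `copies` (`1`, `2`, or `NA` for indeterminate) and `qc_flag`.
#' @examples
#' call_copy_number(500, 500)$copies  # 1
#' call_copy_number(667, 333)$copies  # 2
#' @export
call_copy_number <- function(yfp_reads, cfp_reads, threshold = 7 / 12,
                             guard_se = 2, min_reads = 100L) {
  stopifnot(length(yfp_reads) == length(cfp_reads),
            all(yfp_reads >= 0), all(cfp_reads >= 0))
  n <- yfp_reads + cfp_reads
  if (any(n == 0)) {
    cond_error("copy-number assay with zero total reads", "mutscreen_zero_reads")
  }
  frac <- yfp_reads / n
  se <- sqrt(threshold * (1 - threshold) / n)
  copies <- rep(NA_integer_, length(n))
  copies[frac < threshold - guard_se * se] <- 1L
  copies[frac > threshold + guard_se * se] <- 2L
  low_depth <- n < min_reads
  copies[low_depth] <- NA_integer_
  data.frame(yfp_reads = yfp_reads, cfp_reads = cfp_reads,
             yfp_fraction = frac, copies = copies,
             qc_flag = ifelse(low_depth, "low_depth",
                              ifelse(is.na(copies), "indeterminate", "ok")))
}

#' Expected pyrosequencing allele fraction for a given copy number
#'
#' @param copies_yfp reporter copies against a single reference copy.
#' @return `copies_yfp / (copies_yfp + 1)`.
#' @export
expected_allele_fraction <- function(copies_yfp) {
  stopifnot(all(copies_yfp >= 1))
  copies_yfp / (copies_yfp + 1)
}

#' Assign a mutant genotype to a functional class
#'
#' Evidence combines an optional reporter-gene mutation record and an
#' optional copy-number call. A nonsynonymous or nonsense CDS change gives
#' `"coding"`; a promoter change gives `"cis"`; otherwise a two-copy call
#' gives `"cnv"` and a one-copy call `"trans"`. Synonymous (and terminator)
#' changes are class-uninformative and fall through to the copy-number
#' evidence. With no informative mutation and no usable copy-number call the
#' genotype is `"ambiguous"` (it could be a CNV or trans-acting).
#' Precedence coding > cis > CNV > trans resolves the (never observed in
#' practice) case of multiple evidence lines.
#'
#' @param mutation one-row data.frame with `position`, `ref`, `alt`,
#'   `region`, `coding_effect` (see [simulate_transgene_mutation()]), or
#'   `NULL`.
#' @param cnv one-row result of [call_copy_number()], or `NULL` if the assay
#'   failed/was not run.
#' @return A list with `class` and `evidence`.
#' @export
assign_class <- function(mutation = NULL, cnv = NULL) {
  if (!is.null(mutation) && nrow(mutation) > 0) {
    if (mutation$region == "promoter" &&
        !is.na(mutation$coding_effect) && mutation$coding_effect != "n/a") {
      cond_error("conflicting evidence: promoter mutation with a coding_effect",
                 "mutscreen_evidence_conflict")
    }
    if (mutation$region == "cds" &&
        mutation$coding_effect %in% c("nonsynonymous", "nonsense")) {
      return(list(class = "coding", evidence = "nonsynonymous/nonsense CDS change"))
    }
    if (mutation$region == "promoter") {
      return(list(class = "cis", evidence = "promoter change"))
    }
    # synonymous / terminator / outside changes are uninformative
  }
  if (!is.null(cnv) && nrow(cnv) > 0 && !is.na(cnv$copies)) {
    if (cnv$copies >= 2) {
      return(list(class = "cnv", evidence = sprintf("copy-number call %d", cnv$copies)))
    }
    return(list(class = "trans",
                evidence = "single copy, no informative reporter-gene change"))
  }
  list(class = "ambiguous", evidence = "no informative reporter-gene change and no usable copy-number assay")
}

#' Classify every genotype of a screen
#'
#' Table-level wrapper around [assign_class()]: joins reporter-gene mutation
#' records and pyrosequencing copy-number calls by `genotype_id`.
#'
#' @param genotype_ids character vector of genotypes to classify.
#' @param transgene_mutations data.frame with `genotype_id`, `position`,
#'   `ref`, `alt`, `region`, `coding_effect` (zero rows allowed).
#' @param copy_calls data.frame with `genotype_id` plus the columns of
#'   [call_copy_number()]; genotypes absent from it are treated as untested.
#' @return data.frame with `genotype_id`, `class`, `evidence`.
#' @export
classify_mutants <- function(genotype_ids, transgene_mutations, copy_calls) {
  if (length(genotype_ids) == 0) {
    return(data.frame(genotype_id = character(0), class = character(0),
                      evidence = character(0)))
  }
  rows <- lapply(genotype_ids, function(g) {
    mut <- transgene_mutations[transgene_mutations$genotype_id == g, , drop = FALSE]
    cnv <- copy_calls[copy_calls$genotype_id == g, , drop = FALSE]
    a <- assign_class(if (nrow(mut)) mut[1, , drop = FALSE] else NULL,
                      if (nrow(cnv)) cnv[1, , drop = FALSE] else NULL)
    data.frame(genotype_id = g, class = a$class, evidence = a$evidence)
  })
  do.call(rbind, rows)
}

#' GC content of a nucleotide sequence
#'
#' @param sequence non-empty A/C/G/T string (case-insensitive).
#' @return Percentage of G+C bases.
#' @examples
#' gc_content("GGCC")  # 100
#' @export
gc_content <- function(sequence) {
  stopifnot(length(sequence) == 1, nchar(sequence) > 0)
  b <- strsplit(toupper(sequence), "")[[1]]
  if (any(!b %in% c("A", "C", "G", "T"))) {
    cond_error("sequence contains ambiguous bases", "mutscreen_bad_sequence")
  }
  100 * sum(b %in% c("G", "C")) / length(b)
}
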