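#' Reporter-gene annotation in TSS-relative coordinates
#'
#' Describes the promoter--CDS--terminator structure of the reporter
#' transgene. Coordinates are relative to the transcription start site (+1),
#' negative upstream, with no position 0 (the coordinate jumps from -1 to
#' +1). Spans are inclusive intervals, ordered promoter < CDS <= terminator,
#' and the CDS length must be a multiple of 3 and match `cds_sequence`.
#'
#' @param promoter_span,cds_span,terminator_span length-2 integer vectors
#'   `c(start, end)` of inclusive TSS-relative coordinates.
#' @param cds_sequence coding sequence (A/C/G/T string), first base at
#'   `cds_span[1]`.
#' @param tss_offset_to_atg number of transcribed bases before the ATG
#'   (`cds_span[1] - 1` for a CDS downstream of the TSS); kept explicit
#'   because it is an annotation fact, not a constant.
#' @return An object of class `reporter_annotation`.
#' @seealso [default_annotation()] for the bundled synthetic reporter.
#' @export
reporter_annotation <- function(promoter_span, cds_span, terminator_span,
                                cds_sequence, tss_offset_to_atg = cds_span[1] - 1L) {
  spans <- list(promoter = as.integer(promoter_span),
                cds = as.integer(cds_span),
                terminator = as.integer(terminator_span))
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2 || s[1] > s[2] || any(s == 0L)) {
      cond_error(sprintf("%s span must be c(start, end), start <= end, no position 0", nm),
                 "mutscreen_bad_annotation")
    }
  }
  if (!(spans$promoter[2] < spans$cds[1] && spans$cds[2] < spans$terminator[1])) {
    cond_error("spans must be ordered promoter < cds < terminator and non-overlapping",
               "mutscreen_bad_annotation")
  }
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) == 0) {
    cond_error("annotation requires a non-empty CDS", "mutscreen_bad_annotation")
  }
  if (grepl("[^ACGT]", cds_sequence)) {
    cond_error("cds_sequence may contain only A/C/G/T", "mutscreen_bad_annotation")
  }
  len <- span_length(spans$cds)
  if (nchar(cds_sequence) != len) {
    cond_error("cds_sequence length must match the cds span", "mutscreen_bad_annotation")
  }
  if (len %% 3L != 0L) {
    cond_error("CDS length must be divisible by 3", "mutscreen_bad_annotation")
  }
  structure(c(spans, list(cds_sequence = cds_sequence,
                          tss_offset_to_atg = as.integer(tss_offset_to_atg))),
            class = "reporter_annotation")
}

# inclusive span length under the no-zero coordinate convention
span_length <- function(s) {
  (s[2] - s[1] + 1L) - (s[1] < 0L && s[2] > 0L)
}

#' Bundled synthetic reporter annotation
#'
#' Loads the synthetic stand-in YFP coding sequence shipped with the package
#' (717 nt, GC content 35.56%) and wraps it in the default annotation:
#' promoter -680..-1, CDS +25..+741, terminator +742..+990. The sequence is a
#' generated stand-in with the documented length and base composition of the
#' Venus YFP reporter, not the real Venus sequence.
#'
#' @return A [reporter_annotation()].
#' @export
default_annotation <- function() {
  fa <- system.file("extdata", "yfp_cds_synthetic.fa", package = "mutscreen",
                    mustWork = TRUE)
  seqs <- Biostrings::readDNAStringSet(fa)
  reporter_annotation(promoter_span = c(-680L, -1L),
                      cds_span = c(25L, 741L),
                      terminator_span = c(742L, 990L),
                      cds_sequence = as.character(seqs[[1]]))
}

#' @export
print.reporter_annotation <- function(x, ...) {
  cat(sprintf("Reporter annotation: promoter %d..%d | CDS %d..%d (%d nt) | terminator %d..%d\n",
              x$promoter[1], x$promoter[2], x$cds[1], x$cds[2],
              nchar(x$cds_sequence), x$terminator[1], x$terminator[2]))
  invisible(x)
}

# map a TSS-relative position to a 1-based CDS offset (NA outside the CDS)
cds_offset <- function(position, annotation) {
  ifelse(position >= annotation$cds[1] & position <= annotation$cds[2],
         position - annotation$cds[1] + 1L, NA_integer_)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}
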