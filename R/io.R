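#' Read and write screen tables as TSV
#'
#' Event tables carry `genotype_id`, optional `replicate`, and the log10
#' channel columns (`fsc`, `yfp`, optionally `cfp`, `cy5`); truth and
#' classification tables are plain rectangular TSVs. All writers emit
#' tab-separated files without quoting or row names so that every stage of
#' the pipeline can be re-run from its intermediate files.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_screen_tsv` returns a data.frame; writers return `path`
#'   invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read and write a reporter annotation as JSON (plus its CDS)
#'
#' @param annotation a [reporter_annotation()].
#' @param path JSON file path.
#' @return `read_annotation` returns a [reporter_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "reporter_annotation"))
  write_json(list(promoter_span = annotation$promoter,
                  cds_span = annotation$cds,
                  terminator_span = annotation$terminator,
                  cds_sequence = annotation$cds_sequence,
                  tss_offset_to_atg = annotation$tss_offset_to_atg),
             path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  j <- read_json(path, simplifyVector = TRUE)
  reporter_annotation(j$promoter_span, j$cds_span, j$terminator_span,
                      j$cds_sequence, j$tss_offset_to_atg)
}
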