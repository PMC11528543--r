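#' Relative enrichment of regions in genome elements
#'
#' For each named element set (exon, intron, promoter, enhancer, CGI, ...)
#' the enrichment is the base-pair fraction of the regions overlapping the
#' element divided by the element's base-pair fraction of the genome:
#' `(overlap_bp / region_bp) / (element_bp / genome_bp)`. Element intervals
#' are merged within a set before measuring their genomic footprint; region
#' base pairs are summed as given, so splitting a region in two leaves the
#' enrichment unchanged.
#'
#' @param regions Region `data.frame` (e.g. DMRs); must be non-empty.
#' @param elements Named list of region `data.frame`s.
#' @param genome_size Total genome length in bp.
#' @return A `data.frame` with `element`, `overlap_bp`, `region_bp`,
#'   `element_bp`, `enrichment`.
#' @export
element_enrichment <- function(regions, elements, genome_size) {
  if (nrow(regions) == 0)
    stop("empty region set; enrichment undefined", call. = FALSE)
  stopifnot(is.list(elements), length(names(elements)) == length(elements))
  rgr <- .gr(regions)
  region_bp <- sum(GenomicRanges::width(rgr))
  out <- lapply(names(elements), function(nm) {
    egr <- GenomicRanges::reduce(.gr(elements[[nm]]))
    element_bp <- sum(GenomicRanges::width(egr))
    ov <- GenomicRanges::findOverlaps(rgr, egr)
    overlap_bp <- if (length(ov) == 0) 0 else
      sum(GenomicRanges::width(GenomicRanges::pintersect(
        rgr[S4Vectors::queryHits(ov)], egr[S4Vectors::subjectHits(ov)])))
    data.frame(element = nm, overlap_bp = overlap_bp,
               region_bp = region_bp, element_bp = element_bp,
               enrichment = (overlap_bp / region_bp) /
                 (element_bp / genome_size),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble a per-run summary report
#'
#' Collects stage outputs into one deterministic report: DMR counts by
#' direction, NDR counts by class, per-sample global levels, reversal
#' percentages. Missing stages are reported as explicit gaps rather than
#' omitted.
#'
#' @param dmrs DMR table from [merge_dmrs()] (or `NULL`).
#' @param ndrs Classified NDR table from [classify_ndrs()] (or `NULL`).
#' @param global_levels Named list/vector of per-sample global levels (or
#'   `NULL`).
#' @param reversal Output of [reversal_fraction()] (or `NULL`).
#' @param path Optional path; writes the report as JSON when given.
#' @return A named list; absent stages carry `NA` with a `missing` marker.
#' @export
summarize_run <- function(dmrs = NULL, ndrs = NULL, global_levels = NULL,
                          reversal = NULL, path = NULL) {
  gap <- list(missing = TRUE)
  report <- list(
    dmrs = if (is.null(dmrs)) gap else list(
      missing = FALSE,
      n_total = nrow(dmrs),
      n_hyper = sum(dmrs$direction == "hyper"),
      n_hypo = sum(dmrs$direction == "hypo")),
    ndrs = if (is.null(ndrs)) gap else list(
      missing = FALSE,
      n_total = nrow(ndrs),
      n_proximal = sum(ndrs$klass == "proximal"),
      n_distal = sum(ndrs$klass == "distal")),
    global_levels = if (is.null(global_levels)) gap else
      c(list(missing = FALSE), as.list(global_levels)),
    reversal = if (is.null(reversal)) gap else list(
      missing = FALSE,
      pct_up = reversal$pct_up, pct_down = reversal$pct_down,
      n_up = reversal$n_up, n_down = reversal$n_down))
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}
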