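# Internal helpers shared across modules. All public tables use the 0-based
# half-open coordinate convention (BED-compatible); GRanges conversion happens
# only here.

#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce
#' @importFrom IRanges IRanges coverage slice
#' @importFrom S4Vectors queryHits subjectHits mcols runValue
NULL

# regions: data.frame with chrom/start/end (0-based half-open) -> GRanges
.gr <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

# sites: data.frame with chrom/start (width-1 intervals) -> GRanges
.gr_sites <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$start + 1L, width = 1L))
}

# GRanges -> 0-based half-open data.frame
.df_from_gr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.validate_intervals <- function(regions, what = "region") {
  if (nrow(regions) == 0) return(invisible(regions))
  if (any(regions$start < 0) || any(regions$start >= regions$end) ||
      any(!nzchar(regions$chrom)) || any(is.na(regions$chrom)))
    stop(sprintf("invalid %s coordinates: need chrom non-empty, 0 <= start < end",
                 what), call. = FALSE)
  invisible(regions)
}

.validate_sites <- function(sites) {
  need <- c("chrom", "start", "strand", "context", "meth", "total")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("site table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(sites) && (any(sites$meth < 0) || any(sites$total < 0) ||
                      any(sites$meth > sites$total)))
    stop("site counts must satisfy 0 <= meth <= total", call. = FALSE)
  invisible(sites)
}

# Round-half-up to whole numbers (74/88 -> 84, 217/275 -> 79); base round()
# rounds half to even, which is the wrong presentation for report percentages.
.round_half_up <- function(x) floor(x + 0.5)

# group-wise sums aligned to 1..n (rowsum() drops empty groups)
.grouped_sum <- function(x, group, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, group)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

.chrom_sizes_ok <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))) ||
      any(chrom_sizes <= 0))
    stop("chrom_sizes must be a named vector of positive lengths",
         call. = FALSE)
  invisible(chrom_sizes)
}
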