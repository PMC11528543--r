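#' Sliding windows along the genome
#'
#' Windows of `width` bp (default 100) at every `step` bp (default 20);
#' windows running past the chromosome end are truncated there, so near-end
#' windows may be short. These are the scoring windows for NDR detection.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param width,step Window width and step in bp.
#' @return Region `data.frame` (`chrom`, `start`, `end`).
#' @export
sliding_windows <- function(chrom_sizes, width = 100L, step = 20L) {
  .chrom_sizes_ok(chrom_sizes)
  stopifnot(width >= 1, step >= 1)
  out <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq.int(0L, size - 1L, by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width, size)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chi-squared test of pooled window counts against the genomic background
#'
#' One-degree-of-freedom goodness-of-fit of the observed (methylated,
#' unmethylated) GCH call counts in a window against the expectation under
#' the whole-genome background level: `(m - bt)^2/(bt) + (u - (1-b)t)^2 /
#' ((1-b)t)` with `t = total`, `b = background`. Callers additionally require
#' the observed level to exceed the background (direction gate), making the
#' test effectively one-sided at NDR thresholds.
#'
#' @param meth,total Pooled methylated and total call counts (vectors).
#' @param background Whole-genome background level, strictly in (0, 1).
#' @return A `data.frame` with `statistic` and `p`; untestable entries
#'   (`total == 0`) get `NA`.
#' @export
window_chi2 <- function(meth, total, background) {
  stopifnot(length(background) == 1)
  if (is.na(background) || background <= 0 || background >= 1)
    stop("background must lie strictly between 0 and 1", call. = FALSE)
  if (any(meth > total) || any(meth < 0))
    stop("need 0 <= meth <= total", call. = FALSE)
  e1 <- background * total
  e0 <- (1 - background) * total
  stat <- (meth - e1)^2 / e1 + ((total - meth) - e0)^2 / e0
  stat[total == 0] <- NA_real_
  data.frame(statistic = stat,
             p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Call nucleosome-depleted regions for one sample
#'
#' NDRs are spans of elevated GpC accessibility. The caller (a) scores 100-bp
#' windows sliding by 20 bp, pooling GCH calls per window, and keeps windows
#' whose pooled level exceeds the whole-genome background with a chi-squared
#' p-value at most `p_max` (default 1e-10); (b) merges overlapping or
#' book-ended significant windows into candidate regions; (c) keeps
#' candidates holding at least `min_sites` distinct GCH sites (default 5) and
#' spanning at least `min_len` bp (default 140). Region statistics are
#' recomputed over the merged span: `level` is the mean of per-site levels,
#' the chi-squared test is re-run on the pooled counts, and regions whose
#' site-mean level does not exceed the background are dropped.
#'
#' @param sites GCH site table for one sample (annotated contexts; filtered
#'   internally at `min_depth`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param background Whole-genome background GCH level; default the sample's
#'   [global_level()] over retained sites.
#' @param p_max,min_sites,min_len,width,step,min_depth Calling parameters.
#' @return A `data.frame` of NDRs with `n_gch_sites`, `level`, `background`,
#'   `chi2_p`.
#' @export
call_sample_ndrs <- function(sites, chrom_sizes, background = NULL,
                             p_max = 1e-10, min_sites = 5L, min_len = 140L,
                             width = 100L, step = 20L, min_depth = 3L) {
  gch <- filter_sites(sites, channel = "GCH", min_depth = min_depth)
  if (nrow(gch) == 0)
    stop("no GCH sites at >= ", min_depth, "x; cannot call NDRs",
         call. = FALSE)
  if (is.null(background)) background <- global_level(gch)
  if (background <= 0 || background >= 1)
    stop("degenerate background level ", background, call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_gch_sites = integer(), level = numeric(),
                      background = numeric(), chi2_p = numeric(),
                      stringsAsFactors = FALSE)
  windows <- sliding_windows(chrom_sizes, width = width, step = step)
  hits <- GenomicRanges::findOverlaps(.gr(windows), .gr_sites(gch))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  nw <- nrow(windows)
  meth <- .grouped_sum(gch$meth[sh], qh, nw)
  total <- .grouped_sum(gch$total[sh], qh, nw)
  chi <- window_chi2(meth, total, background)
  keep <- !is.na(chi$p) & chi$p <= p_max & total > 0 &
    meth / total > background
  if (!any(keep)) return(empty)
  cand <- GenomicRanges::reduce(.gr(windows[keep, , drop = FALSE]))
  regions <- .df_from_gr(cand)
  regions <- region_level(gch, regions, min_sites = 1L)
  # pooled counts for the region-wide chi-squared test
  rh <- GenomicRanges::findOverlaps(.gr(regions), .gr_sites(gch))
  rq <- S4Vectors::queryHits(rh)
  rs <- S4Vectors::subjectHits(rh)
  rmeth <- .grouped_sum(gch$meth[rs], rq, nrow(regions))
  rtotal <- .grouped_sum(gch$total[rs], rq, nrow(regions))
  rchi <- window_chi2(rmeth, rtotal, background)
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, n_gch_sites = regions$n_sites,
                    level = regions$level, background = background,
                    chi2_p = rchi$p, stringsAsFactors = FALSE)
  out <- out[out$n_gch_sites >= min_sites &
             (out$end - out$start) >= min_len &
             !is.na(out$level) & out$level > background, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge NDR sets across samples or groups
#'
#' Computes the interval partition of the union of all samples' NDRs
#' (multi-intersection semantics), keeps segments covered by at least
#' `min_samples` of the input sets (default 1 = union), and connects
#' retained segments separated by at most `connect_gap` bp (default 10).
#'
#' @param ndr_sets List of NDR `data.frame`s (one per sample), each with
#'   `chrom`, `start`, `end`.
#' @param min_samples Minimum supporting sample count per segment.
#' @param connect_gap Maximum gap bridged when connecting segments.
#' @return Region `data.frame` of merged NDR intervals.
#' @export
merge_group_ndrs <- function(ndr_sets, min_samples = 1L, connect_gap = 10L) {
  stopifnot(is.list(ndr_sets), length(ndr_sets) >= 1)
  grl <- lapply(ndr_sets, function(d) {
    # within one sample overlapping NDRs count once
    GenomicRanges::reduce(.gr(d))
  })
  all_gr <- do.call(c, grl)
  if (length(all_gr) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  cov <- GenomicRanges::coverage(all_gr)
  seg <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(rep(names(seg), lengths(seg)),
                               unlist(seg, use.names = FALSE))
  gr <- GenomicRanges::reduce(gr, min.gapwidth = connect_gap + 1L)
  out <- .df_from_gr(gr)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify NDRs as promoter-proximal or distal
#'
#' An NDR overlapping any promoter (1 kb upstream to 0.5 kb downstream of a
#' TSS, strand-aware) by at least 1 bp is proximal; all others are distal.
#'
#' @param ndrs NDR `data.frame`.
#' @param promoters Promoter regions (see [promoter_regions()]).
#' @return `ndrs` with a `klass` column (`"proximal"`/`"distal"`).
#' @export
classify_ndrs <- function(ndrs, promoters) {
  ndrs$klass <- character(nrow(ndrs))
  if (nrow(ndrs) == 0) return(ndrs)
  n <- GenomicRanges::countOverlaps(.gr(ndrs), .gr(promoters))
  ndrs$klass <- ifelse(n > 0, "proximal", "distal")
  ndrs
}
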