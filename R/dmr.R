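#' 300-bp genome tiles for differential methylation testing
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Region `data.frame` of non-overlapping 300 bp windows (last window
#'   of a chromosome may be short).
#' @export
tile_300bp <- function(chrom_sizes) genome_bins(chrom_sizes, width = 300L)

#' Per-sample window methylation levels
#'
#' Computes each sample's mean WCG level per window (mean of per-site levels,
#' [region_level()]); a sample's value is missing when the window holds fewer
#' than `min_sites` covered WCG sites in that sample.
#'
#' @param sample_sites List of filtered WCG site tables, one per sample.
#' @param windows Window `data.frame` (e.g. from [tile_300bp()]).
#' @param min_sites Minimum WCG sites per window per sample (default 3).
#' @return Numeric matrix, windows x samples, `NA` for missing values.
#' @export
window_values <- function(sample_sites, windows, min_sites = 3L) {
  stopifnot(is.list(sample_sites), length(sample_sites) >= 1)
  vals <- vapply(sample_sites, function(s)
    region_level(s, windows, min_sites = min_sites)$level,
    numeric(nrow(windows)))
  vals <- matrix(vals, nrow = nrow(windows))
  colnames(vals) <- names(sample_sites)
  vals
}

#' Row-wise two-sample t-tests on a window-by-sample matrix
#'
#' Vectorized two-tailed Student's t-test (equal-variance by default; Welch
#' behind `var_equal = FALSE`) of group 1 against group 2 for every row.
#' Missing values are dropped per row; rows with fewer than 2 non-missing
#' values in either group are skipped (`NA` statistics). Degenerate rows with
#' zero pooled variance give p = 1 when the group means agree (no evidence)
#' and p = 0 when they differ (the limit of the t statistic).
#'
#' @param values Numeric matrix (windows x samples).
#' @param group1,group2 Column indices (or names) of the two groups.
#' @param var_equal Use pooled-variance Student form (default `TRUE`).
#' @return A `data.frame` with `mean_g1`, `mean_g2`, `delta`
#'   (`mean_g1 - mean_g2`), `n1`, `n2`, `p`.
#' @export
test_windows <- function(values, group1, group2, var_equal = TRUE) {
  x1 <- values[, group1, drop = FALSE]
  x2 <- values[, group2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- pmax(0, rowSums(x1 * x1, na.rm = TRUE) - n1 * m1^2) / (n1 - 1)
  v2 <- pmax(0, rowSums(x2 * x2, na.rm = TRUE) - n2 * m2^2) / (n2 - 1)
  ok <- n1 >= 2 & n2 >= 2
  delta <- m1 - m2
  p <- rep(NA_real_, nrow(values))
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  pos <- ok & se > 0
  p[pos] <- 2 * stats::pt(-abs(delta[pos] / se[pos]), df[pos])
  zero <- ok & se == 0
  p[zero] <- ifelse(delta[zero] == 0, 1, 0)
  data.frame(mean_g1 = ifelse(is.nan(m1), NA_real_, m1),
             mean_g2 = ifelse(is.nan(m2), NA_real_, m2),
             delta = ifelse(ok, delta, NA_real_),
             n1 = n1, n2 = n2, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment over the non-missing p-values; `NA` entries
#' (untested windows) are preserved and do not enter the FDR universe.
#'
#' @param p Numeric vector of p-values (may contain `NA`).
#' @return Vector of adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) && (any(p < 0, na.rm = TRUE) || any(p > 1, na.rm = TRUE)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Call differentially methylated windows
#'
#' A tested window is differentially methylated when the absolute group
#' difference exceeds `delta_min` (strict, default 0.20), the two-tailed
#' t-test p-value is at most `p_max` and the BH FDR at most `fdr_max`
#' (defaults 0.05). Direction is `hyper` (group 1 above group 2) or `hypo`.
#'
#' @param windows Window `data.frame`.
#' @param tests Output of [test_windows()] for the same windows.
#' @param delta_min,p_max,fdr_max Calling thresholds.
#' @return The significant windows with `mean_g1`, `mean_g2`, `delta`, `p`,
#'   `q` and `direction` columns.
#' @export
call_dmws <- function(windows, tests, delta_min = 0.20, p_max = 0.05,
                      fdr_max = 0.05) {
  stopifnot(nrow(windows) == nrow(tests))
  q <- bh_fdr(tests$p)
  keep <- !is.na(tests$p) & abs(tests$delta) > delta_min &
    tests$p <= p_max & !is.na(q) & q <= fdr_max
  out <- cbind(windows[keep, c("chrom", "start", "end"), drop = FALSE],
               tests[keep, c("mean_g1", "mean_g2", "delta", "p"),
                     drop = FALSE])
  out$q <- q[keep]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Merge differentially methylated windows into regions
#'
#' Same-direction windows on one chromosome separated by at most `max_gap`
#' bp (default 300) are merged into a single region spanning from the first
#' to the last constituent; hyper- and hypomethylated windows never merge.
#'
#' @param dmws Output of [call_dmws()].
#' @param max_gap Maximum inter-window gap in bp (default 300).
#' @return A `data.frame` of DMRs with `n_windows`, `delta` (mean of
#'   constituent deltas) and `direction`.
#' @export
merge_dmrs <- function(dmws, max_gap = 300L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      delta = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(dmws) == 0) return(empty)
  out <- lapply(c("hyper", "hypo"), function(dir) {
    d <- dmws[dmws$direction == dir, , drop = FALSE]
    if (nrow(d) == 0) return(empty)
    red <- GenomicRanges::reduce(.gr(d), min.gapwidth = max_gap + 1L,
                                 with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    res <- .df_from_gr(red)
    res$n_windows <- lengths(revmap)
    res$delta <- vapply(revmap, function(i) mean(d$delta[i]), numeric(1))
    res$direction <- dir
    res
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end DMR calling between two sample groups
#'
#' Tiles the genome into 300 bp windows, computes per-sample window WCG
#' levels (3x depth, >= 3 sites per window), runs two-tailed Student's
#' t-tests with BH correction, gates windows at |delta| > 20%, p <= 0.05 and
#' FDR <= 0.05, and merges same-direction windows within 300 bp.
#'
#' @param sites_g1,sites_g2 Lists of per-sample site tables (annotated with
#'   contexts; filtering happens internally).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param min_depth,min_sites,delta_min,p_max,fdr_max,max_gap,window_size
#'   Pipeline thresholds (defaults as above).
#' @param var_equal Use the pooled-variance Student form (default `TRUE`).
#' @return A list with `windows`, `values` (windows x samples), `tests`,
#'   `dmws` and `dmrs`.
#' @export
call_dmrs <- function(sites_g1, sites_g2, chrom_sizes, min_depth = 3L,
                      min_sites = 3L, delta_min = 0.20, p_max = 0.05,
                      fdr_max = 0.05, max_gap = 300L, window_size = 300L,
                      var_equal = TRUE) {
  windows <- genome_bins(chrom_sizes, width = window_size)
  f1 <- lapply(sites_g1, filter_sites, channel = "WCG", min_depth = min_depth)
  f2 <- lapply(sites_g2, filter_sites, channel = "WCG", min_depth = min_depth)
  vals <- window_values(c(f1, f2), windows, min_sites = min_sites)
  tests <- test_windows(vals, seq_along(f1),
                        length(f1) + seq_along(f2), var_equal = var_equal)
  dmws <- call_dmws(windows, tests, delta_min = delta_min, p_max = p_max,
                    fdr_max = fdr_max)
  list(windows = windows, values = vals, tests = tests, dmws = dmws,
       dmrs = merge_dmrs(dmws, max_gap = max_gap))
}
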