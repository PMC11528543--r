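#' Filter cytosine sites by channel and coverage
#'
#' Keeps sites whose context matches the requested channel (`WCG` for
#' endogenous methylation, `GCH` for accessibility) and whose read depth is
#' at least `min_depth` (default 3x, the depth cutoff used throughout the
#' pipeline). Ambiguous `GCG` and off-target-prone `CCG` sites, and `OTHER`
#' contexts, are always dropped.
#'
#' @param sites Site table with a `context` column (see
#'   [annotate_contexts()]).
#' @param channel `"WCG"` or `"GCH"`.
#' @param min_depth Minimum `total` count (default 3).
#' @return The filtered site table.
#' @export
filter_sites <- function(sites, channel = c("WCG", "GCH"), min_depth = 3L) {
  channel <- match.arg(channel)
  .validate_sites(sites)
  out <- sites[!is.na(sites$context) & sites$context == channel &
               sites$total >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site methylation level
#'
#' The level of a covered cytosine is the ratio of methylated calls to all
#' calls at the site.
#'
#' @param meth,total Vectors of methylated and total call counts.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
site_level <- function(meth, total) {
  if (any(total == 0))
    stop("site level undefined at zero coverage", call. = FALSE)
  if (any(meth > total) || any(meth < 0))
    stop("need 0 <= meth <= total", call. = FALSE)
  meth / total
}

#' Mean methylation/accessibility level of genomic regions
#'
#' The level of a region is the unweighted mean of per-site levels over the
#' sites falling inside it; regions with fewer than `min_sites` qualifying
#' sites (default 3) get `NA`. A pooled-count mode (`sum(meth)/sum(total)`)
#' is available for sensitivity analysis.
#'
#' @param sites Filtered site table (see [filter_sites()]).
#' @param regions Region `data.frame` (`chrom`, `start`, `end`).
#' @param min_sites Minimum site count for a defined level (default 3).
#' @param mode `"site_mean"` (default) or `"pooled"`.
#' @return `regions` with columns `n_sites` and `level` appended.
#' @export
region_level <- function(sites, regions, min_sites = 3L,
                         mode = c("site_mean", "pooled")) {
  mode <- match.arg(mode)
  .validate_sites(sites)
  .validate_intervals(regions)
  nr <- nrow(regions)
  regions$n_sites <- integer(nr)
  regions$level <- rep(NA_real_, nr)
  if (nr == 0) return(regions)
  if (nrow(sites)) {
    hits <- GenomicRanges::findOverlaps(.gr(regions), .gr_sites(sites))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    n <- tabulate(qh, nbins = nr)
    if (mode == "site_mean") {
      lv <- sites$meth[sh] / sites$total[sh]
      level <- .grouped_sum(lv, qh, nr) / ifelse(n > 0, n, NA)
    } else {
      level <- .grouped_sum(sites$meth[sh], qh, nr) /
        .grouped_sum(sites$total[sh], qh, nr)
    }
    regions$n_sites <- n
    regions$level <- ifelse(n >= min_sites, level, NA_real_)
  }
  regions
}

#' Non-overlapping genome tiles
#'
#' Tiles each chromosome with fixed-width bins (default 1 kb, the bin size
#' used for genome-wide level summaries); the last tile of a chromosome may
#' be shorter.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param width Tile width in bp.
#' @return Region `data.frame` (`chrom`, `start`, `end`).
#' @export
genome_bins <- function(chrom_sizes, width = 1000L) {
  .chrom_sizes_ok(chrom_sizes)
  stopifnot(width >= 1)
  out <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq.int(0L, size - 1L, by = width)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width, size)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome-wide mean level
#'
#' Unweighted mean of per-site levels over all retained sites of one channel;
#' this is also the whole-genome background used by the NDR caller.
#'
#' @param sites Filtered site table.
#' @return Fraction in `[0, 1]`.
#' @export
global_level <- function(sites) {
  .validate_sites(sites)
  if (nrow(sites) == 0)
    stop("no sites; global level undefined", call. = FALSE)
  mean(sites$meth / sites$total)
}

#' Metagene profile over gene bodies
#'
#' Each gene body (TSS to TES) is divided into 100 equal-fraction bins, and
#' each 2 kb flank into 100 bins of 20 bp, giving a 300-bin profile with bin
#' 0 always 5'-most (minus-strand genes are reversed). A gene's bin level is
#' the mean of per-site levels in that bin; the profile is the across-gene
#' mean of bin levels, skipping gene-bins without sites.
#'
#' @param sites Filtered site table.
#' @param genes Gene table from [read_genes()]; genes shorter than 100 bp are
#'   skipped with a warning.
#' @param flank Flank size in bp (default 2000; bin width `flank/100`).
#' @return A `data.frame` with `bin` (0-299), `region` (upstream/body/
#'   downstream), `level` and `n_genes` (genes contributing to the bin).
#' @export
genebody_profile <- function(sites, genes, flank = 2000L) {
  if (nrow(genes) == 0) stop("empty gene list", call. = FALSE)
  short <- genes$end - genes$start < 100L
  if (any(short)) {
    warning("skipping ", sum(short), " gene(s) shorter than 100 bp")
    genes <- genes[!short, , drop = FALSE]
    if (nrow(genes) == 0) stop("no genes left to profile", call. = FALSE)
  }
  fw <- flank / 100
  span <- data.frame(chrom = genes$chrom,
                     start = pmax(0L, genes$start - as.integer(flank)),
                     end = genes$end + as.integer(flank))
  labels <- rep(c("upstream", "body", "downstream"), each = 100L)
  asn <- .sites_in_spans(sites, span)
  if (nrow(asn) == 0) return(.empty_profile(300L, labels))
  g <- asn$region_idx
  pos <- asn$pos
  gs <- genes$start[g]; ge <- genes$end[g]; len <- ge - gs
  plus <- genes$strand[g] == "+"
  bin <- integer(nrow(asn))
  up <- ifelse(plus, pos < gs, pos >= ge)
  dn <- ifelse(plus, pos >= ge, pos < gs)
  body <- !up & !dn
  bin[up & plus] <- floor((pos - (gs - flank))[up & plus] / fw)
  bin[up & !plus] <- floor(((ge + flank - 1) - pos)[up & !plus] / fw)
  bin[body & plus] <- 100L + floor(100 * (pos - gs)[body & plus] /
                                     len[body & plus])
  bin[body & !plus] <- 100L + floor(100 * ((ge - 1) - pos)[body & !plus] /
                                      len[body & !plus])
  bin[dn & plus] <- 200L + floor((pos - ge)[dn & plus] / fw)
  bin[dn & !plus] <- 200L + floor(((gs - 1) - pos)[dn & !plus] / fw)
  .profile_from_assignments(g, bin, asn$level, 300L, labels)
}

#' Metagene profile around transcription start sites
#'
#' 200 bins of 20 bp covering TSS +/- 2 kb, strand-oriented so bin 0 is the
#' 5'-most (upstream) edge. Bin levels are computed as in
#' [genebody_profile()].
#'
#' @param sites Filtered site table.
#' @param genes Gene table from [read_genes()].
#' @param flank Half-window around the TSS in bp (default 2000; 20 bp bins).
#' @return A `data.frame` with `bin` (0-199), `region`, `level`, `n_genes`.
#' @export
tss_profile <- function(sites, genes, flank = 2000L) {
  if (nrow(genes) == 0) stop("empty gene list", call. = FALSE)
  nbins <- as.integer(2 * flank / 20)
  span <- data.frame(chrom = genes$chrom,
                     start = pmax(0L, as.integer(genes$tss - flank)),
                     end = as.integer(genes$tss + flank))
  asn <- .sites_in_spans(sites, span)
  if (nrow(asn) == 0)
    return(.empty_profile(nbins, rep("tss_flank", nbins)))
  g <- asn$region_idx
  pos <- asn$pos
  tss <- genes$tss[g]
  plus <- genes$strand[g] == "+"
  bin <- ifelse(plus, floor((pos - (tss - flank)) / 20),
                floor(((tss + flank - 1) - pos) / 20))
  keep <- bin >= 0 & bin < nbins
  .profile_from_assignments(g[keep], as.integer(bin[keep]), asn$level[keep],
                            nbins, rep("tss_flank", nbins))
}

# overlap sites with per-gene spans; returns one row per (site, span) pair
.sites_in_spans <- function(sites, spans) {
  .validate_sites(sites)
  if (nrow(sites) == 0)
    return(data.frame(region_idx = integer(), pos = integer(),
                      level = numeric()))
  hits <- GenomicRanges::findOverlaps(.gr(spans), .gr_sites(sites))
  sh <- S4Vectors::subjectHits(hits)
  data.frame(region_idx = S4Vectors::queryHits(hits),
             pos = sites$start[sh],
             level = sites$meth[sh] / sites$total[sh])
}

.profile_from_assignments <- function(gene_idx, bin, level, nbins, region) {
  out <- .empty_profile(nbins, region)
  if (!length(bin)) return(out)
  key <- (gene_idx - 1) * nbins + bin + 1
  per <- rowsum(cbind(level, 1), key)
  bin_of <- (as.numeric(rownames(per)) - 1) %% nbins
  gene_bin_mean <- per[, 1] / per[, 2]
  agg <- rowsum(cbind(gene_bin_mean, 1), bin_of)
  idx <- as.integer(rownames(agg)) + 1L
  out$level[idx] <- agg[, 1] / agg[, 2]
  out$n_genes[idx] <- as.integer(agg[, 2])
  out
}

.empty_profile <- function(nbins, region = NA_character_) {
  data.frame(bin = seq_len(nbins) - 1L, region = region,
             level = NA_real_, n_genes = 0L, stringsAsFactors = FALSE)
}
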