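# Shared fixture builders and the reciprocal-overlap matcher used by the
# recovery tests. All fixtures are built in code; coordinates follow the
# package-wide 0-based half-open convention.

make_sites <- function(start, meth, total, chrom = "chr1", strand = "+",
                       context = "WCG") {
  data.frame(chrom = chrom, start = as.integer(start), strand = strand,
             context = context, meth = as.integer(meth),
             total = as.integer(total), stringsAsFactors = FALSE)
}

# sites at fixed per-site level `level` and depth `total`, one per position
uniform_sites <- function(start, level, total = 10L, chrom = "chr1",
                          context = "WCG") {
  make_sites(start, meth = round(level * total), total = total,
             chrom = chrom, context = context)
}

# hits between region sets a and b with >= 50% reciprocal overlap
recip_hits <- function(a, b) {
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  h <- GenomicRanges::findOverlaps(ga, gb)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    ga[S4Vectors::queryHits(h)], gb[S4Vectors::subjectHits(h)]))
  ok <- ov >= 0.5 * GenomicRanges::width(ga[S4Vectors::queryHits(h)]) &
    ov >= 0.5 * GenomicRanges::width(gb[S4Vectors::subjectHits(h)])
  h[ok]
}

recovery_rates <- function(called, truth) {
  h <- recip_hits(called, truth)
  list(sensitivity = length(unique(S4Vectors::subjectHits(h))) / nrow(truth),
       precision = length(unique(S4Vectors::queryHits(h))) / nrow(called))
}

# independent step-up BH oracle: q_(i) = min_{j >= i} m * p_(j) / j
bh_by_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    q[ord[i]] <- min(1, running)
  }
  q
}
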