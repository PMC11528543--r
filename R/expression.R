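#' Reads per kilobase per million mapped reads
#'
#' `RPKM = counts / (length_bp / 1000) / (library_size / 1e6)`.
#'
#' @param counts Matrix of raw counts (genes x samples) or a vector.
#' @param gene_length_bp Per-gene lengths in bp.
#' @param library_size Per-sample totals; defaults to column sums.
#' @return Matrix (or vector) of RPKM values.
#' @export
rpkm <- function(counts, gene_length_bp, library_size = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive",
                                     call. = FALSE)
  if (any(library_size <= 0)) stop("library size must be positive",
                                   call. = FALSE)
  sweep(counts / (gene_length_bp / 1000), 2, library_size / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio of
#' a sample's count to the gene's geometric mean, computed over genes with
#' all-positive counts.
#'
#' @param counts Matrix of raw counts (genes x samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has all-positive counts; size factors undefined",
         call. = FALSE)
  apply(counts[use, , drop = FALSE], 2, function(k)
    exp(stats::median(log(k) - log_gm[use])))
}

#' Two-group negative-binomial Wald test per gene
#'
#' A documented stand-in providing the per-gene (log2 fold change, p-value)
#' contract of count-based differential expression tools, so that externally
#' computed statistics can be swapped in downstream. Counts are normalized by
#' median-of-ratios size factors; the fold change is
#' `log2((mu1 + 1)/(mu2 + 1))` of normalized group means (pseudocount 1); the
#' gene-wise NB dispersion is a method-of-moments estimate pooled across the
#' two groups and floored at `disp_floor` (default 0.01); the Wald statistic
#' for the log fold change (delta method) is referred to a t distribution
#' with `n1 + n2 - 2` degrees of freedom, which keeps the null p-values
#' approximately uniform at small sample sizes. Genes with all-zero counts
#' get `log2fc = 0, p = 1`.
#'
#' @param counts_g1,counts_g2 Count matrices (genes x samples), same genes.
#' @param sf Optional size factors for `cbind(counts_g1, counts_g2)`;
#'   computed internally when `NULL`.
#' @param disp_floor Minimum dispersion (default 0.01).
#' @return A `data.frame` with `gene_id` (rownames when present), `base_mean`,
#'   `log2fc`, `p`.
#' @export
diff_test <- function(counts_g1, counts_g2, sf = NULL, disp_floor = 0.01) {
  counts_g1 <- as.matrix(counts_g1)
  counts_g2 <- as.matrix(counts_g2)
  stopifnot(nrow(counts_g1) == nrow(counts_g2))
  n1 <- ncol(counts_g1)
  n2 <- ncol(counts_g2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(cbind(counts_g1, counts_g2))
  s1 <- sf[seq_len(n1)]
  s2 <- sf[n1 + seq_len(n2)]
  q1 <- sweep(counts_g1, 2, s1, "/")
  q2 <- sweep(counts_g2, 2, s2, "/")
  mu1 <- rowMeans(q1)
  mu2 <- rowMeans(q2)
  v1 <- apply(q1, 1, stats::var)
  v2 <- apply(q2, 1, stats::var)
  c1 <- mean(1 / s1)
  c2 <- mean(1 / s2)
  # MoM: Var(q_ij) = mu / s_j + alpha * mu^2, pooled over both groups
  num <- (n1 - 1) * (v1 - mu1 * c1) + (n2 - 1) * (v2 - mu2 * c2)
  den <- (n1 - 1) * mu1^2 + (n2 - 1) * mu2^2
  alpha <- ifelse(den > 0, pmax(disp_floor, num / den), disp_floor)
  log2fc <- log2((mu1 + 1) / (mu2 + 1))
  var_mu1 <- (mu1 * c1 + alpha * mu1^2) / n1
  var_mu2 <- (mu2 * c2 + alpha * mu2^2) / n2
  se <- sqrt(var_mu1 / (mu1 + 1)^2 + var_mu2 / (mu2 + 1)^2) / log(2)
  w <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(w), df = n1 + n2 - 2)
  zero <- mu1 == 0 & mu2 == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  gene_id <- rownames(counts_g1)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(counts_g1)))
  data.frame(gene_id = gene_id, base_mean = (mu1 + mu2) / 2,
             log2fc = log2fc, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gate differential-expression statistics into DEG calls
#'
#' A gene is differentially expressed when `|log2fc| > 0.5` (strict), BH
#' FDR `<= 0.05`, and its mean RPKM over the compared samples exceeds the
#' biotype-specific floor: 1 for protein-coding genes, 0.1 for lncRNAs.
#' FDR is computed over all tested genes supplied here.
#'
#' @param stats A `data.frame` with `gene_id`, `log2fc`, `p` (e.g. from
#'   [diff_test()] or an external tool).
#' @param mean_rpkm Per-gene mean RPKM across the compared samples.
#' @param biotype Per-gene biotype (`"coding"`/`"lncRNA"`; other values use
#'   the coding floor).
#' @param lfc_min,fdr_max Effect-size and FDR gates (defaults 0.5, 0.05).
#' @param rpkm_min_coding,rpkm_min_lnc Expression floors (defaults 1, 0.1).
#' @return `stats` with `q`, `mean_rpkm`, `biotype` and `status`
#'   (`"up"`/`"down"`/`"ns"`) columns.
#' @export
call_degs <- function(stats, mean_rpkm, biotype, lfc_min = 0.5,
                      fdr_max = 0.05, rpkm_min_coding = 1,
                      rpkm_min_lnc = 0.1) {
  stopifnot(nrow(stats) == length(mean_rpkm),
            nrow(stats) == length(biotype))
  stats$q <- bh_fdr(stats$p)
  stats$mean_rpkm <- mean_rpkm
  stats$biotype <- biotype
  floor_rpkm <- ifelse(biotype == "lncRNA", rpkm_min_lnc, rpkm_min_coding)
  sig <- !is.na(stats$q) & abs(stats$log2fc) > lfc_min &
    stats$q <= fdr_max & mean_rpkm > floor_rpkm
  stats$status <- ifelse(sig & stats$log2fc > 0, "up",
                         ifelse(sig, "down", "ns"))
  stats
}

#' Annotate cis-regulatory lncRNA / protein-coding gene pairs
#'
#' For every same-direction pair of a differentially expressed lncRNA and a
#' differentially expressed protein-coding gene lying within `max_dist` bp
#' (default 100 kb) on the same chromosome, the Pearson correlation of their
#' expression across samples is tested; pairs with `r >= r_min` (default
#' 0.6) and correlation-test `p <= p_max` (default 0.05) are kept. Distance
#' is 0 when the gene spans overlap, otherwise the nearest-end gap. Pairs
#' with a constant expression vector are skipped.
#'
#' @param degs DEG table from [call_degs()] covering both biotypes.
#' @param expr Expression matrix (RPKM, genes x samples) with rownames;
#'   correlations use all supplied samples.
#' @param genes Gene table from [read_genes()].
#' @param max_dist,r_min,p_max Pairing thresholds.
#' @return A `data.frame` with `lnc_id`, `coding_id`, `distance_bp`, `r`,
#'   `p`, `direction`.
#' @export
cis_pairs <- function(degs, expr, genes, max_dist = 100000L, r_min = 0.6,
                      p_max = 0.05) {
  empty <- data.frame(lnc_id = character(), coding_id = character(),
                      distance_bp = integer(), r = numeric(), p = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  out <- list(empty)
  for (dir in c("up", "down")) {
    lnc <- degs$gene_id[degs$status == dir & degs$biotype == "lncRNA"]
    cod <- degs$gene_id[degs$status == dir & degs$biotype == "coding"]
    if (!length(lnc) || !length(cod)) next
    gl <- genes[match(lnc, genes$gene_id), ]
    gc <- genes[match(cod, genes$gene_id), ]
    for (i in seq_along(lnc)) {
      same <- which(gc$chrom == gl$chrom[i])
      if (!length(same)) next
      gap <- pmax(0L, pmax(gc$start[same] - gl$end[i],
                           gl$start[i] - gc$end[same]))
      near <- same[gap <= max_dist]
      gap <- gap[gap <= max_dist]
      for (j in seq_along(near)) {
        x <- expr[lnc[i], ]
        y <- expr[cod[near[j]], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        ct <- stats::cor.test(x, y, method = "pearson")
        if (!is.na(ct$estimate) && ct$estimate >= r_min &&
            ct$p.value <= p_max)
          out[[length(out) + 1L]] <- data.frame(
            lnc_id = lnc[i], coding_id = cod[near[j]],
            distance_bp = as.integer(gap[j]),
            r = unname(ct$estimate), p = ct$p.value, direction = dir,
            stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample expression ratio of two isoforms
#'
#' E.g. the MYH7/MYH6 ratio used as a readout of the myosin heavy chain
#' isoform switch: the fetal and hypertrophic myocardium shift from MYH6
#' (alpha-MHC) toward MYH7 (beta-MHC), raising the ratio even while both
#' genes' absolute expression falls.
#'
#' @param rpkm_a,rpkm_b Per-sample RPKM vectors of the two genes.
#' @return Per-sample ratios; samples with a zero denominator get `NA` with
#'   a warning.
#' @export
isoform_ratio <- function(rpkm_a, rpkm_b) {
  stopifnot(length(rpkm_a) == length(rpkm_b))
  out <- ifelse(rpkm_b > 0, rpkm_a / rpkm_b, NA_real_)
  if (any(rpkm_b == 0))
    warning(sum(rpkm_b == 0), " sample(s) with zero denominator flagged NA")
  out
}

#' Construct the fetal gene program
#'
#' Genes shifted in the same direction in the diseased and the fetal
#' myocardium relative to the same control group: `co_up` is the
#' intersection of up-regulated DEGs of the two contrasts, `co_down` of the
#' down-regulated ones.
#'
#' @param deg_disease,deg_fetal DEG tables from [call_degs()], both computed
#'   against the same control group.
#' @return A list with character vectors `co_up` and `co_down`.
#' @export
fetal_program <- function(deg_disease, deg_fetal) {
  list(co_up = intersect(deg_disease$gene_id[deg_disease$status == "up"],
                         deg_fetal$gene_id[deg_fetal$status == "up"]),
       co_down = intersect(deg_disease$gene_id[deg_disease$status == "down"],
                           deg_fetal$gene_id[deg_fetal$status == "down"]))
}

#' Quantify reversal of the fetal program under treatment
#'
#' A program gene counts as reversed when both treated-vs-disease contrasts
#' shift it back toward the control state: co-upregulated genes must be
#' down-regulated in both treated groups, co-downregulated genes
#' up-regulated in both. Fractions are reported per side as percentages
#' rounded half-up.
#'
#' @param program Output of [fetal_program()].
#' @param deg_treated_a,deg_treated_b DEG tables of the two treated groups,
#'   each contrasted against the untreated disease group.
#' @return A list with `reversed_up`, `reversed_down` (gene vectors),
#'   `n_up`, `n_down`, `pct_up`, `pct_down` (percentages; `NA` for an empty
#'   program side, with a warning).
#' @export
reversal_fraction <- function(program, deg_treated_a, deg_treated_b) {
  down_a <- deg_treated_a$gene_id[deg_treated_a$status == "down"]
  down_b <- deg_treated_b$gene_id[deg_treated_b$status == "down"]
  up_a <- deg_treated_a$gene_id[deg_treated_a$status == "up"]
  up_b <- deg_treated_b$gene_id[deg_treated_b$status == "up"]
  rev_up <- intersect(program$co_up, intersect(down_a, down_b))
  rev_down <- intersect(program$co_down, intersect(up_a, up_b))
  pct <- function(k, n, side) {
    if (n == 0) {
      warning("empty ", side, " program side; fraction undefined")
      return(NA_real_)
    }
    .round_half_up(100 * k / n)
  }
  list(reversed_up = rev_up, reversed_down = rev_down,
       n_up = length(program$co_up), n_down = length(program$co_down),
       pct_up = pct(length(rev_up), length(program$co_up), "co-up"),
       pct_down = pct(length(rev_down), length(program$co_down), "co-down"))
}
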