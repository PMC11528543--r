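#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator with defaults on
#' the scale of adult human myocardium NOMe-seq: global WCG methylation
#' around 0.72, open-chromatin GCH footprint level 0.45 over a 0.15
#' background, 10x mean coverage, 6 samples per methylation group. Planted
#' feature geometry (150 accessible regions of 200-500 bp, 100 methylation
#' shifts of 900 bp at delta 0.30) matches the recovery conditions exercised
#' by the test suite. Expression defaults mirror the fetal-program analysis:
#' five groups (control, disease, fetal, two treated), program sides of 88
#' and 275 genes with reversal fractions 0.84 and 0.79.
#'
#' @param seed Integer seed; one seed determines every draw.
#' @param genome_length,gc_fraction Synthetic genome size and GC content.
#' @param n_per_group,depth Methylation samples per group and mean coverage
#'   (Poisson).
#' @param wcg_background,gch_background,ndr_gch_level Channel levels.
#' @param n_ndr,ndr_length Planted accessible regions: count and length
#'   range.
#' @param n_dmr,dmr_length,dmr_delta Planted methylation shifts: count,
#'   length, group-1 level offset (direction drawn per plant; levels are
#'   clamped to `[0.01, 0.99]`).
#' @param bb_theta Optional beta-binomial overdispersion (`NULL` = pure
#'   binomial calls).
#' @param n_genes,nb_dispersion,fold_change Expression genes, NB dispersion
#'   and planted fold change.
#' @param lnc_fraction Fraction of genes annotated as lncRNA.
#' @param program_up,program_down,reversal_up,reversal_down Fetal-program
#'   sides and reversed fractions.
#' @param n_de_extra Additional disease-only DE genes per direction.
#' @param n_cis_pairs Planted correlated lncRNA/coding pairs within 100 kb.
#' @param n_expr_per_group Expression samples per group.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 2e6, gc_fraction = 0.40,
                       n_per_group = 6L, depth = 10,
                       wcg_background = 0.72, gch_background = 0.15,
                       ndr_gch_level = 0.45, n_ndr = 150L,
                       ndr_length = c(200L, 500L), n_dmr = 100L,
                       dmr_length = 900L, dmr_delta = 0.30, bb_theta = NULL,
                       n_genes = 2000L, nb_dispersion = 0.05,
                       fold_change = 3, lnc_fraction = 0.15,
                       program_up = 88L, program_down = 275L,
                       reversal_up = 0.84, reversal_down = 0.79,
                       n_de_extra = 100L, n_cis_pairs = 10L,
                       n_expr_per_group = 4L) {
  cfg <- as.list(environment())
  stopifnot(cfg$genome_length >= 1e4,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$ndr_gch_level > cfg$gch_background,
            cfg$wcg_background > 0, cfg$wcg_background < 1,
            cfg$reversal_up >= 0, cfg$reversal_up <= 1,
            cfg$reversal_down >= 0, cfg$reversal_down <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference genome with known cytosine contexts
#'
#' Draws a random A/C/G/T sequence at the configured GC fraction and emits
#' its own trinucleotide context classification, derived by exact pattern
#' matching of the eight class-defining trinucleotides (and their reverse
#' complements for the minus strand) — an independent route from
#' [classify_contexts()], usable as a cross-check.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; writes `genome.fa` and
#'   `contexts.tsv` when given.
#' @return A list with `genome` (a [Biostrings::DNAStringSet] with one
#'   sequence `chrS`) and `contexts` (a `data.frame` of WCG/GCH/GCG/CCG
#'   sites with `chrom`, `start`, `strand`, `context`).
#' @export
simulate_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_fraction
  bases <- sample(c("A", "C", "G", "T"), config$genome_length,
                  replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq <- paste(bases, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chrS"))
  contexts <- .contexts_by_pattern(seq, "chrS")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    utils::write.table(contexts, file.path(dir, "contexts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genome = genome, contexts = contexts)
}

# context classification by literal trinucleotide matching; the match centre
# (offset + 1) is the cytosine position of the class on that strand
.contexts_by_pattern <- function(seq, chrom) {
  subj <- Biostrings::DNAString(seq)
  fwd <- list(WCG = c("ACG", "TCG"), GCH = c("GCA", "GCT", "GCC"),
              GCG = "GCG", CCG = "CCG")
  one <- function(pats, strand) {
    starts <- unlist(lapply(pats, function(p) {
      if (strand == "-")
        p <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
      IRanges::start(Biostrings::matchPattern(p, subj))
    }))
    # 1-based start of the trinucleotide == 0-based position of its centre
    sort(starts)
  }
  out <- lapply(names(fwd), function(cls) {
    rbind(
      data.frame(chrom = chrom, start = one(fwd[[cls]], "+"),
                 strand = "+", context = cls, stringsAsFactors = FALSE),
      data.frame(chrom = chrom, start = one(fwd[[cls]], "-"),
                 strand = "-", context = cls, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# place n non-overlapping intervals, one per equal slot, with a margin
.place_intervals <- function(n, lengths, genome_length, margin = 500) {
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  slot <- floor(genome_length / n)
  if (slot < max(lengths) + 2 * margin)
    stop("genome too short to place ", n, " separated intervals",
         call. = FALSE)
  offs <- floor(stats::runif(n, margin, slot - margin - lengths))
  start <- (seq_len(n) - 1L) * slot + as.integer(offs)
  data.frame(chrom = "chrS", start = start,
             end = start + as.integer(lengths), stringsAsFactors = FALSE)
}

#' Simulate per-sample cytosine call tables with planted features
#'
#' For every classified cytosine, per sample: depth is Poisson with the
#' configured mean and methylated calls are binomial at the site's true
#' level. GCH sites sit at the accessibility background except inside
#' planted nucleosome-depleted regions (all samples, level
#' `ndr_gch_level`). WCG sites sit at the methylation background except
#' inside planted differential regions, where group 1 is shifted by
#' `dmr_delta` (direction drawn per plant, levels clamped to
#' `[0.01, 0.99]`). GCG and CCG sites are simulated at the methylation
#' background so downstream exclusion is exercised. With `bb_theta` set,
#' per-site success probabilities are beta-distributed around the true
#' level (beta-binomial stress mode).
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [simulate_genome()] (or a list with a
#'   `contexts` data.frame).
#' @param dir Optional output directory; writes one cytosine-report TSV per
#'   sample plus `truth_ndrs.bed` and `truth_dmrs.bed`.
#' @return A list with `samples` (list `group1`/`group2` of site tables),
#'   `truth` (`ndrs`, `dmrs` with direction) and `config`.
#' @export
simulate_calls <- function(config, sim_genome, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ctx <- sim_genome$contexts
  set.seed(config$seed + 1L)
  ndr_len <- if (config$n_ndr > 0)
    sample(seq(config$ndr_length[1], config$ndr_length[2]),
           config$n_ndr, replace = TRUE) else integer()
  ndrs <- .place_intervals(config$n_ndr, ndr_len, config$genome_length)
  dmrs <- .place_intervals(config$n_dmr,
                           rep(config$dmr_length, config$n_dmr),
                           config$genome_length,
                           margin = 700)
  dmrs$direction <- if (config$n_dmr > 0)
    sample(c("hyper", "hypo"), config$n_dmr, replace = TRUE) else character()

  in_plant <- function(plants) {
    hit <- rep(FALSE, nrow(ctx))
    if (nrow(plants))
      hit[S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(.gr(plants), .gr_sites(ctx)))] <- TRUE
    hit
  }
  in_ndr <- in_plant(ndrs)
  in_dmr <- in_plant(dmrs)
  dmr_dir <- rep(NA_character_, nrow(ctx))
  if (nrow(dmrs)) {
    h <- GenomicRanges::findOverlaps(.gr(dmrs), .gr_sites(ctx))
    dmr_dir[S4Vectors::subjectHits(h)] <- dmrs$direction[S4Vectors::queryHits(h)]
  }
  clamp <- function(x) pmin(0.99, pmax(0.01, x))
  base_level <- ifelse(ctx$context == "GCH",
                       ifelse(in_ndr, config$ndr_gch_level,
                              config$gch_background),
                       config$wcg_background)
  g1_level <- base_level
  shift <- ctx$context == "WCG" & in_dmr
  g1_level[shift] <- clamp(config$wcg_background +
                             ifelse(dmr_dir[shift] == "hyper", 1, -1) *
                             config$dmr_delta)
  draw_sample <- function(level) {
    n <- length(level)
    total <- stats::rpois(n, config$depth)
    p <- if (is.null(config$bb_theta)) level
         else stats::rbeta(n, level * config$bb_theta,
                           (1 - level) * config$bb_theta)
    meth <- stats::rbinom(n, total, p)
    data.frame(chrom = ctx$chrom, start = ctx$start, strand = ctx$strand,
               context = ctx$context, meth = meth, total = total,
               stringsAsFactors = FALSE)
  }
  g1 <- lapply(seq_len(config$n_per_group), function(i) draw_sample(g1_level))
  g2 <- lapply(seq_len(config$n_per_group), function(i) draw_sample(base_level))
  names(g1) <- paste0("g1_s", seq_along(g1))
  names(g2) <- paste0("g2_s", seq_along(g2))
  out <- list(samples = list(group1 = g1, group2 = g2),
              truth = list(ndrs = ndrs, dmrs = dmrs), config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (grp in names(out$samples))
      for (nm in names(out$samples[[grp]])) {
        s <- out$samples[[grp]][[nm]]
        rep <- data.frame(s$chrom, s$start + 1L, s$strand, s$meth,
                          s$total - s$meth, s$context)
        utils::write.table(rep, file.path(dir, paste0(nm, ".cytosine_report.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    write_regions(ndrs, file.path(dir, "truth_ndrs.bed"))
    write_regions(dmrs, file.path(dir, "truth_dmrs.bed"))
  }
  out
}

#' Simulate expression counts with a planted fetal program
#'
#' Negative-binomial counts for five groups (control, disease, fetal,
#' treated_a, treated_b). Program genes are shifted by the configured fold
#' change in the same direction in disease and fetal; a fraction of each
#' program side (`reversal_up`/`reversal_down`, rounded to whole genes)
#' returns to the control level in both treated groups, the remainder stays
#' at the disease level. Additional disease-only DE genes are planted per
#' direction. Planted cis-pairs (a lncRNA and a coding gene placed within
#' 100 kb on the synthetic annotation) share a per-sample latent factor so
#' their expression is strongly correlated, and both members carry the
#' disease fold change of their pair's direction.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; writes `counts.tsv`, `genes.bed`
#'   and `truth.json`.
#' @return A list with `counts` (genes x samples), `groups` (per-sample
#'   labels), `genes` (annotation as from [read_genes()]), `truth` (program
#'   sides, reversed sets, DE sets, cis pairs) and `config`.
#' @export
simulate_expression <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ng <- config$n_genes
  gene_id <- sprintf("G%04d", seq_len(ng))
  biotype <- ifelse(stats::runif(ng) < config$lnc_fraction, "lncRNA",
                    "coding")
  len <- sample(500:5000, ng, replace = TRUE)
  gap <- sample(5000:30000, ng, replace = TRUE)
  start <- cumsum(gap) + cumsum(c(0, len[-ng]))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  genes <- data.frame(gene_id = gene_id, chrom = "chrE",
                      start = as.integer(start),
                      end = as.integer(start + len), strand = strand,
                      biotype = biotype,
                      tss = ifelse(strand == "+", start, start + len),
                      tes = ifelse(strand == "+", start + len, start),
                      length_bp = as.integer(len), stringsAsFactors = FALSE)

  coding_idx <- which(biotype == "coding")
  lnc_idx <- which(biotype == "lncRNA")
  need <- config$program_up + config$program_down + 2 * config$n_de_extra +
    config$n_cis_pairs
  if (length(coding_idx) < need || length(lnc_idx) < config$n_cis_pairs)
    stop("n_genes too small for the configured plants", call. = FALSE)
  pool <- sample(coding_idx)
  prog_up <- pool[seq_len(config$program_up)]
  pool <- pool[-seq_len(config$program_up)]
  prog_down <- pool[seq_len(config$program_down)]
  pool <- pool[-seq_len(config$program_down)]
  de_up <- pool[seq_len(config$n_de_extra)]
  pool <- pool[-seq_len(config$n_de_extra)]
  de_down <- pool[seq_len(config$n_de_extra)]
  pool <- pool[-seq_len(config$n_de_extra)]
  cis_lnc <- sample(lnc_idx, config$n_cis_pairs)
  cis_cod <- pool[seq_len(config$n_cis_pairs)]
  cis_dir <- sample(c("up", "down"), config$n_cis_pairs, replace = TRUE)
  # co-locate each pair: coding gene restarts just after its lncRNA
  genes$start[cis_cod] <- genes$end[cis_lnc] + 10000L
  genes$end[cis_cod] <- genes$start[cis_cod] + genes$length_bp[cis_cod]
  genes$tss[cis_cod] <- ifelse(genes$strand[cis_cod] == "+",
                               genes$start[cis_cod], genes$end[cis_cod])
  genes$tes[cis_cod] <- ifelse(genes$strand[cis_cod] == "+",
                               genes$end[cis_cod], genes$start[cis_cod])

  n_rev_up <- .round_half_up(config$reversal_up * config$program_up)
  n_rev_down <- .round_half_up(config$reversal_down * config$program_down)
  rev_up <- prog_up[seq_len(n_rev_up)]
  rev_down <- prog_down[seq_len(n_rev_down)]

  base <- exp(stats::rnorm(ng, log(80), 1))
  planted <- c(prog_up, prog_down, de_up, de_down, cis_lnc, cis_cod)
  base[planted] <- pmax(base[planted], 50)

  groups <- rep(c("control", "disease", "fetal", "treated_a", "treated_b"),
                each = config$n_expr_per_group)
  sample_id <- paste0(groups, "_", seq_len(config$n_expr_per_group))
  fc <- config$fold_change
  mu <- matrix(base, nrow = ng, ncol = length(groups))
  up_in <- function(idx, cols) mu[idx, cols] <<- mu[idx, cols] * fc
  down_in <- function(idx, cols) mu[idx, cols] <<- mu[idx, cols] / fc
  cols <- function(g) which(groups == g)
  dis_like <- c(cols("disease"), cols("fetal"))
  up_in(prog_up, dis_like); down_in(prog_down, dis_like)
  # non-reversed program genes keep the disease shift under treatment
  keep_up <- setdiff(prog_up, rev_up)
  keep_down <- setdiff(prog_down, rev_down)
  treat <- c(cols("treated_a"), cols("treated_b"))
  up_in(keep_up, treat); down_in(keep_down, treat)
  up_in(de_up, cols("disease")); down_in(de_down, cols("disease"))
  for (k in seq_len(config$n_cis_pairs)) {
    pair <- c(cis_lnc[k], cis_cod[k])
    if (cis_dir[k] == "up") up_in(pair, cols("disease"))
    else down_in(pair, cols("disease"))
    mu[pair, ] <- mu[pair, , drop = FALSE] *
      rep(exp(stats::rnorm(length(groups), 0, 0.4)), each = 2)
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = ng, dimnames = list(gene_id, sample_id))
  truth <- list(program = list(co_up = gene_id[prog_up],
                               co_down = gene_id[prog_down]),
                reversed_up = gene_id[rev_up],
                reversed_down = gene_id[rev_down],
                de_up_disease = gene_id[sort(c(prog_up, de_up,
                                               c(cis_lnc, cis_cod)[rep(cis_dir == "up", 2)]))],
                de_down_disease = gene_id[sort(c(prog_down, de_down,
                                                 c(cis_lnc, cis_cod)[rep(cis_dir == "down", 2)]))],
                cis_pairs = data.frame(lnc_id = gene_id[cis_lnc],
                                       coding_id = gene_id[cis_cod],
                                       direction = cis_dir,
                                       stringsAsFactors = FALSE))
  out <- list(counts = counts, groups = stats::setNames(groups, sample_id),
              genes = genes, truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene_id = gene_id, counts,
                                  check.names = FALSE),
                       file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(genes[, c("chrom", "start", "end", "gene_id",
                                 "biotype", "strand", "length_bp")],
                       file.path(dir, "genes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
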