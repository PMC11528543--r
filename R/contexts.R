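#' Classify every cytosine in a reference into NOMe-seq trinucleotide contexts
#'
#' NOMe-seq reads two signals from one molecule: endogenous CpG methylation
#' and exogenous GpC methyltransferase (M.CviPI) footprints. The trinucleotide
#' around each cytosine decides which channel it reports:
#'
#' * `WCG` (prev in A/T, next G): endogenous DNA methylation.
#' * `GCH` (prev G, next in A/T/C): chromatin accessibility.
#' * `GCG`: ambiguous between the two signals; classified here, excluded by
#'   downstream filters.
#' * `CCG`: prone to M.CviPI off-target activity at CC sites; likewise
#'   excluded downstream.
#' * `OTHER`: everything else, including cytosines adjacent to `N` or to a
#'   contig end.
#'
#' Both strands are classified: a reference guanine is a reverse-strand
#' cytosine and is classified from the reverse-complement trinucleotide by
#' the same rule. Classification depends only on the reference sequence.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#'   Sequences must use the A/C/G/T/N alphabet.
#' @return A `data.frame` with columns `chrom`, `start` (0-based position of
#'   the cytosine on its strand), `strand` (`+`/`-`) and `context`
#'   (`WCG`/`GCH`/`GCG`/`CCG`/`OTHER`), sorted by chromosome and position.
#' @examples
#' ctx <- classify_contexts(Biostrings::DNAStringSet(c(chrT = "ACGT")))
#' subset(ctx, strand == "+")  # the C at position 1 sits in A-C-G: WCG
#' @export
classify_contexts <- function(genome) {
  if (is.character(genome)) {
    if (length(genome) != 1 || !file.exists(genome))
      stop("genome must be a DNAStringSet or a path to a FASTA file",
           call. = FALSE)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or a path to a FASTA file",
         call. = FALSE)
  chroms <- sub("\\s.*$", "", names(genome))
  out <- lapply(seq_along(genome), function(i) {
    b <- strsplit(toupper(as.character(genome[[i]])), "", fixed = TRUE)[[1]]
    if (any(!b %in% c("A", "C", "G", "T", "N")))
      stop("sequence ", chroms[i], " contains characters outside A/C/G/T/N",
           call. = FALSE)
    n <- length(b)
    prv <- c(NA_character_, b[-n])
    nxt <- c(b[-1], NA_character_)
    fwd <- which(b == "C")
    rev <- which(b == "G")
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    data.frame(chrom = chroms[i],
               start = c(fwd, rev) - 1L,
               strand = rep(c("+", "-"), c(length(fwd), length(rev))),
               context = c(.classify_tri(prv[fwd], nxt[fwd]),
                           .classify_tri(unname(comp[nxt[rev]]),
                                         unname(comp[prv[rev]]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# prev/next are the 5'/3' neighbours of the cytosine on its own strand
.classify_tri <- function(prv, nxt) {
  ctx <- rep("OTHER", length(prv))
  ok <- !is.na(prv) & !is.na(nxt) & prv != "N" & nxt != "N"
  ctx[ok & prv %in% c("A", "T") & nxt == "G"] <- "WCG"
  ctx[ok & prv == "G" & nxt %in% c("A", "T", "C")] <- "GCH"
  ctx[ok & prv == "G" & nxt == "G"] <- "GCG"
  ctx[ok & prv == "C" & nxt == "G"] <- "CCG"
  ctx
}

#' Attach reference context classes to a site table
#'
#' Joins the `context` column of [classify_contexts()] output onto a site
#' table by chromosome, position and strand. Sites at positions absent from
#' the context map (e.g. not cytosines on that strand in the reference) get
#' context `OTHER`.
#'
#' @param sites Site table (see [read_cytosine_report()]).
#' @param context_map Output of [classify_contexts()].
#' @return `sites` with its `context` column replaced.
#' @export
annotate_contexts <- function(sites, context_map) {
  .validate_sites(sites)
  key <- function(d) paste(d$chrom, d$start, d$strand, sep = "\r")
  idx <- match(key(sites), key(context_map))
  sites$context <- ifelse(is.na(idx), "OTHER", context_map$context[idx])
  sites
}

#' Bisulfite conversion efficiency from an unmethylated spike-in
#'
#' Unmodified lambda DNA added before bisulfite conversion carries no true
#' methylation, so every methylated call on the spike-in contig is a
#' conversion failure. The conversion rate is estimated as
#' `1 - sum(meth) / sum(total)` over spike-in cytosines.
#'
#' @param spikein_sites Site table restricted to the spike-in contig.
#' @return Fraction in `[0, 1]`.
#' @examples
#' conversion_rate(data.frame(chrom = "lambda", start = 0:1, strand = "+",
#'                            context = NA, meth = c(1, 1), total = c(50, 50)))
#' @export
conversion_rate <- function(spikein_sites) {
  .validate_sites(spikein_sites)
  total <- sum(spikein_sites$total)
  if (total == 0)
    stop("spike-in has zero total coverage; conversion rate undefined",
         call. = FALSE)
  1 - sum(spikein_sites$meth) / total
}
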