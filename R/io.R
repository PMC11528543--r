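#' Read a per-cytosine methylation call table
#'
#' Parses Bismark-style per-cytosine call tables into the site table used by
#' every downstream module. Two dialects are supported:
#'
#' * `"cytosine_report"`: `chrom, position (1-based), strand, meth_count,
#'   unmeth_count[, context]` — the coverage2cytosine/CX report layout.
#' * `"bismark_cov"`: `chrom, start (1-based), end, methylation_percentage,
#'   meth_count, unmeth_count` — the `.bismark.cov` layout. Strand is not
#'   recorded in this dialect and is returned as `"*"`.
#'
#' Positions are normalized to the package-wide 0-based half-open convention;
#' no other module performs coordinate arithmetic on raw file values. The
#' optional context column is kept verbatim when present (use
#' [annotate_contexts()] to assign WCG/GCH classes from a reference).
#'
#' @param path Path to a tab-separated file (optionally with `#` comments).
#' @param dialect One of `"cytosine_report"` or `"bismark_cov"`.
#' @return A `data.frame` with columns `chrom`, `start` (0-based), `strand`,
#'   `context` (`NA` when absent from the file), `meth`, `total`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t101\t+\t3\t1", f)
#' read_cytosine_report(f, "cytosine_report")
#' @export
read_cytosine_report <- function(path,
                                 dialect = c("cytosine_report", "bismark_cov")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  keep <- nzchar(trimws(lines))
  empty <- data.frame(chrom = character(), start = integer(),
                      strand = character(), context = character(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no records in ", path)
    return(empty)
  }
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (dialect == "cytosine_report") 5L else 6L
  bad <- which(nf < min_cols)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: expected >= %d tab-separated fields",
                 line_no[bad[1]], path, min_cols), call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  as_count <- function(x, col) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("malformed row at line %d of %s: non-numeric or negative %s",
                   line_no[bad[1]], path, col), call. = FALSE)
    v
  }
  if (dialect == "cytosine_report") {
    pos <- as_count(get(2), "position")
    meth <- as_count(get(4), "methylated count")
    unmeth <- as_count(get(5), "unmethylated count")
    strand <- get(3)
    if (!all(strand %in% c("+", "-")))
      stop(sprintf("malformed row at line %d of %s: strand must be + or -",
                   line_no[which(!strand %in% c("+", "-"))[1]], path),
           call. = FALSE)
    context <- if (all(nf >= 6)) get(6) else NA_character_
    out <- data.frame(chrom = get(1), start = pos - 1L, strand = strand,
                      context = context, meth = meth, total = meth + unmeth,
                      stringsAsFactors = FALSE)
  } else {
    pos <- as_count(get(2), "start")
    meth <- as_count(get(5), "methylated count")
    unmeth <- as_count(get(6), "unmethylated count")
    out <- data.frame(chrom = get(1), start = pos - 1L, strand = "*",
                      context = NA_character_, meth = meth,
                      total = meth + unmeth, stringsAsFactors = FALSE)
  }
  .validate_sites(out)
  out
}

#' Read a gene annotation (BED-like TSV or GTF)
#'
#' Accepts either a 7-column BED-like table (`chrom, start, end, gene_id,
#' biotype, strand[, length_bp]`, 0-based half-open) or a GTF whose `gene`
#' lines carry `gene_id` and `gene_biotype`/`gene_type` attributes (parsed via
#' rtracklayer). TSS is the strand-aware 5' end and TES the 3' end: for a
#' minus-strand gene spanning `[start, end)` the TSS coordinate is `end`.
#' Biotypes `protein_coding` map to `"coding"`, `lncRNA`/`lincRNA` to
#' `"lncRNA"`, anything else to `"other"`. The `length_bp` column (exonic
#' length used for RPKM) defaults to the TSS-TES span when absent.
#'
#' @param path Path to the annotation file. Files ending in `.gtf`/`.gff` are
#'   parsed as GTF.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `tss`, `tes`, `length_bp`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    md <- S4Vectors::mcols(gr)
    bio <- if ("gene_biotype" %in% names(md)) md$gene_biotype
           else if ("gene_type" %in% names(md)) md$gene_type
           else NA_character_
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        gene_id = md$gene_id,
                        biotype = bio,
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.table(path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(genes) < 6)
      stop("BED-like gene table needs >= 6 columns: chrom, start, end, ",
           "gene_id, biotype, strand", call. = FALSE)
    names(genes)[1:6] <- c("chrom", "start", "end", "gene_id", "biotype",
                           "strand")
    if (ncol(genes) >= 7) names(genes)[7] <- "length_bp"
  }
  zero <- genes$gene_id[genes$end <= genes$start]
  if (length(zero))
    stop("gene(s) with zero or negative length: ",
         paste(zero, collapse = ", "), call. = FALSE)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be + or -", call. = FALSE)
  biotype <- ifelse(genes$biotype %in% c("protein_coding", "coding"), "coding",
             ifelse(genes$biotype %in% c("lncRNA", "lincRNA"), "lncRNA",
                    "other"))
  plus <- genes$strand == "+"
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(genes$start),
                    end = as.integer(genes$end),
                    strand = genes$strand, biotype = biotype,
                    tss = ifelse(plus, genes$start, genes$end),
                    tes = ifelse(plus, genes$end, genes$start),
                    stringsAsFactors = FALSE)
  out$length_bp <- if ("length_bp" %in% names(genes))
    as.integer(genes$length_bp) else out$end - out$start
  if (any(out$length_bp <= 0))
    stop("length_bp must be positive", call. = FALSE)
  .validate_intervals(out, "gene")
  out
}

#' Write genomic regions as BED with attribute columns
#'
#' Writes a standard BED file (0-based half-open) with any attribute columns
#' after the first three, preceded by a single `#`-prefixed header naming all
#' columns so that [read_regions()] restores the table losslessly.
#'
#' @param regions A `data.frame` with `chrom`, `start`, `end` plus optional
#'   attribute columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  .validate_intervals(regions)
  front <- c("chrom", "start", "end")
  regions <- regions[, c(front, setdiff(names(regions), front)), drop = FALSE]
  if (nrow(regions))
    regions <- regions[order(regions$chrom, regions$start, regions$end), ,
                       drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(regions), collapse = "\t")), con)
  if (nrow(regions))
    utils::write.table(regions, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_regions()]
#'
#' @param path Path to a BED file; a leading `#`-prefixed header (as written
#'   by [write_regions()]) names the columns, otherwise the first three
#'   columns are taken as `chrom`, `start`, `end`.
#' @return A `data.frame` of regions (0-based half-open) with attributes.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    cols <- if (is.null(header)) c("chrom", "start", "end") else header
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         cols), stringsAsFactors = FALSE)
    out$start <- integer(); out$end <- integer()
    return(out)
  }
  out <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(header)) {
    if (length(header) != ncol(out))
      stop("header/column mismatch in ", path, call. = FALSE)
    names(out) <- header
  } else {
    names(out)[1:3] <- c("chrom", "start", "end")
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  .validate_intervals(out)
  out
}

#' Strand-aware promoter regions
#'
#' Promoters span 1 kb upstream to 0.5 kb downstream of the TSS. For
#' minus-strand genes the upstream kilobase extends in increasing
#' coordinates. Regions are clipped at zero.
#'
#' @param genes Gene table from [read_genes()].
#' @param upstream,downstream Extents in bp (defaults 1000 and 500).
#' @return A `data.frame` with `chrom`, `start`, `end`, `gene_id`, `strand`.
#' @export
promoter_regions <- function(genes, upstream = 1000L, downstream = 500L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  out <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, as.integer(start)),
                    end = as.integer(end),
                    gene_id = genes$gene_id, strand = genes$strand,
                    stringsAsFactors = FALSE)
  .validate_intervals(out, "promoter")
  out
}
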