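# Alignment filtering and strand-specific quantification: gene counts by the
# fragment-midpoint rule, RPKM, fixed-width genome-wide bins, and per-base
# coverage profiles.

#' Filter fragment alignments
#'
#' Retains a fragment iff its mapping quality is at least `mapq_min`, it is
#' properly paired, it is not QC(chastity)-failed, and it is the first
#' occurrence of its `(chrom, start, end, strand)` coordinate tuple --
#' coordinate duplicates beyond the first are collapsed to a single copy.
#' The output preserves input order, and the operation is idempotent.
#'
#' @param records Fragment alignment data frame (columns `chrom`, `start`,
#'   `end`, `strand`, `mapq`, `properly_paired`, `qc_failed`; a `duplicate`
#'   column, if present, is informational -- deduplication is by coordinate).
#' @param mapq_min Minimum mapping quality kept (default 5, i.e. MAPQ >= 5).
#' @return The retained subset, same columns, original order.
#' @export
filter_alignments <- function(records, mapq_min = 5L) {
  keep <- records$mapq >= mapq_min &
    records$properly_paired &
    !records$qc_failed
  out <- records[keep, , drop = FALSE]
  key <- paste(out$chrom, out$start, out$end, out$strand, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

genes_df <- function(genes) {
  if (inherits(genes, "toy_genome")) genes <- genes$genes
  need <- c("gene", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop_ps("gene annotation must have columns: ", paste(need, collapse = ", "))
  }
  genes
}

check_same_strand_overlap <- function(genes) {
  for (key in unique(paste(genes$chrom, genes$strand))) {
    g <- genes[paste(genes$chrom, genes$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    if (length(ir) > 1L &&
        any(S4Vectors::queryHits(IRanges::findOverlaps(ir, ir)) !=
            S4Vectors::subjectHits(IRanges::findOverlaps(ir, ir)))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Count fragments per gene by the midpoint rule, strand-specifically
#'
#' A fragment increments a gene's count iff the fragment midpoint,
#' `floor((start + end) / 2)`, lies inside the gene interval and the strands
#' match ("only reads aligned to the proper strand"); each fragment is
#' thereby assigned to at most one gene per strand, so totals are conserved.
#'
#' @param fragments Filtered fragment alignments.
#' @param genes Gene annotation data frame (or a `toy_genome`), 0-based
#'   half-open coordinates.
#' @param overlap_resolve How to handle same-strand overlapping genes:
#'   `"error"` (default; such annotations are rejected) or `"first"`
#'   (assign the midpoint to the overlapping gene with the smaller start).
#' @return Named integer vector of counts over all annotated genes.
#' @export
count_gene_reads <- function(fragments, genes,
                             overlap_resolve = c("error", "first")) {
  overlap_resolve <- match.arg(overlap_resolve)
  genes <- genes_df(genes)
  if (overlap_resolve == "error" && check_same_strand_overlap(genes)) {
    stop_ps("annotation has overlapping same-strand genes; ",
            "use overlap_resolve = \"first\" to keep the earlier gene")
  }
  counts <- stats::setNames(integer(nrow(genes)), genes$gene)
  mid <- (fragments$start + fragments$end) %/% 2L
  for (key in unique(paste(genes$chrom, genes$strand))) {
    gsel <- paste(genes$chrom, genes$strand) == key
    g <- genes[gsel, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    fsel <- paste(fragments$chrom, fragments$strand) == key
    if (!any(fsel)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = mid[fsel] + 1L, width = 1L),
      IRanges::IRanges(start = g$start + 1L, end = g$end),
      select = "first")  # earlier-start gene wins on (resolved) overlap
    tab <- table(hits[!is.na(hits)])
    counts[g$gene[as.integer(names(tab))]] <-
      counts[g$gene[as.integer(names(tab))]] + as.integer(tab)
  }
  counts
}

#' Reads per kilobase per million (RPKM)
#'
#' `RPKM = count * 1e9 / (gene_length * library_size)`.
#'
#' @param count Fragment count(s).
#' @param gene_length Gene length(s) in bp (> 0).
#' @param library_size Total assigned fragments in the library (> 0).
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
#' @export
compute_rpkm <- function(count, gene_length, library_size) {
  if (any(library_size <= 0)) stop_ps("`library_size` must be > 0")
  if (any(gene_length <= 0)) stop_ps("`gene_length` must be > 0")
  count * 1e9 / (gene_length * library_size)
}

#' Count fragments in fixed-width genome-wide bins, per strand
#'
#' Tiles every chromosome with non-overlapping bins of `bin_width` bp (bin
#' `i` covering `[i*w, (i+1)*w)`) and assigns each fragment to the bin
#' containing its midpoint, on the fragment's own strand. Per-strand totals
#' equal the number of assigned fragments.
#'
#' @param fragments Filtered fragment alignments.
#' @param chrom_lengths Named vector of chromosome lengths (or a
#'   `toy_genome`).
#' @param bin_width Bin width in bp (default 175).
#' @return Object of class `bin_grid`: list with `bin_width`,
#'   `chrom_lengths`, and `counts` -- a dense data frame over every
#'   (chromosome, strand, bin) with `start`, `end`, `count`.
#' @export
count_bins <- function(fragments, chrom_lengths, bin_width = 175L) {
  if (inherits(chrom_lengths, "toy_genome")) {
    chrom_lengths <- stats::setNames(chrom_lengths$chromosomes$length,
                                     chrom_lengths$chromosomes$chrom)
  }
  bin_width <- as.integer(bin_width)
  grids <- list()
  for (chrom in names(chrom_lengths)) {
    n_bins <- as.integer(ceiling(chrom_lengths[[chrom]] / bin_width))
    for (strand in c("+", "-")) {
      bin <- seq_len(n_bins) - 1L
      grids[[paste(chrom, strand)]] <- data.frame(
        chrom = chrom, strand = strand, bin = bin,
        start = bin * bin_width,
        end = pmin((bin + 1L) * bin_width,
                   as.integer(chrom_lengths[[chrom]])),
        count = 0L, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, grids)
  rownames(counts) <- NULL
  if (nrow(fragments)) {
    mid <- (fragments$start + fragments$end) %/% 2L
    key <- paste(fragments$chrom, fragments$strand, mid %/% bin_width)
    tab <- table(key)
    gkey <- paste(counts$chrom, counts$strand, counts$bin)
    hit <- match(names(tab), gkey)
    if (anyNA(hit)) stop_ps("fragment midpoint outside chromosome bounds")
    counts$count[hit] <- as.integer(tab)
  }
  structure(list(bin_width = bin_width,
                 chrom_lengths = chrom_lengths,
                 counts = counts), class = "bin_grid")
}

#' Per-base fragment coverage over an interval, strand-specifically
#'
#' Coverage at position `p` is the number of same-strand fragments with
#' `start <= p < end`.
#'
#' @param fragments Filtered fragment alignments.
#' @param chrom,start,end Interval (0-based half-open). Alternatively pass a
#'   one-row gene annotation as `interval`.
#' @param strand Strand to profile.
#' @param interval Optional list/one-row data frame with `chrom`, `start`,
#'   `end` (and optionally `strand`), overriding the scalar arguments.
#' @return Object of class `coverage_profile`: list with `chrom`, `start`,
#'   `end`, `strand`, and `coverage` -- an integer vector of length
#'   `end - start`.
#' @export
coverage_profile <- function(fragments, chrom = NULL, start = NULL, end = NULL,
                             strand = "+", interval = NULL) {
  if (!is.null(interval)) {
    chrom <- interval$chrom; start <- interval$start; end <- interval$end
    if (!is.null(interval$strand)) strand <- interval$strand
  }
  stopifnot(!is.null(chrom), start < end)
  width <- end - start
  delta <- integer(width + 1L)
  sel <- fragments$chrom == chrom & fragments$strand == strand &
    fragments$end > start & fragments$start < end
  f <- fragments[sel, , drop = FALSE]
  if (nrow(f)) {
    s <- pmax(f$start, start) - start
    e <- pmin(f$end, end) - start
    delta <- tabulate(s + 1L, nbins = width + 1L) -
      tabulate(e + 1L, nbins = width + 1L)
  }
  structure(list(chrom = chrom, start = start, end = end, strand = strand,
                 coverage = cumsum(delta[seq_len(width)])),
            class = "coverage_profile")
}
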