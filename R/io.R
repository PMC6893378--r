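# File formats: the colony-table and fragment TSV dialects, minimal SAM
# emission and reading, GFF3/BED annotation round-trips, bedGraph coverage,
# and machine-readable truth tables.
#
# All internal coordinates are 0-based half-open. GFF3 is converted on
# read/write (1-based inclusive); BED and the TSV dialects match the
# internal convention.

#' Write / read a colony table
#'
#' Tab-separated with header columns `plate`, `row`, `col`, `gene`,
#' `replicate`, `screen`, `size`.
#'
#' @param colonies Colony data frame.
#' @param path File path.
#' @return `read_colony_tsv` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_colony_tsv <- function(colonies, path) {
  utils::write.table(colonies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_colony_tsv
#' @export
read_colony_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read fragment alignments as the 8-column TSV dialect
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `strand`, `mapq`,
#' `dup`, `qcfail`, `proper` (0/1 flags). Files written by older 7-column
#' emitters that lack `proper` are read with `proper = 1`.
#'
#' @param fragments Fragment alignment data frame.
#' @param path File path.
#' @return `read_fragments_tsv` returns the fragment data frame in the
#'   internal column layout; the writer returns `path` invisibly.
#' @export
write_fragments_tsv <- function(fragments, path) {
  out <- data.frame(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end, strand = fragments$strand,
                    mapq = fragments$mapq,
                    dup = as.integer(fragments$duplicate),
                    qcfail = as.integer(fragments$qc_failed),
                    proper = as.integer(fragments$properly_paired))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(d$proper)) d$proper <- 1L
  data.frame(chrom = as.character(d$chrom), start = as.integer(d$start),
             end = as.integer(d$end), strand = as.character(d$strand),
             mapq = as.integer(d$mapq),
             properly_paired = d$proper == 1L,
             duplicate = d$dup == 1L,
             qc_failed = d$qcfail == 1L,
             stringsAsFactors = FALSE)
}

#' Write / read fragment alignments as SAM
#'
#' Each fragment is emitted as a properly oriented FR read pair (two lines
#' sharing a QNAME): for a plus-strand fragment, read 1 is forward at the
#' fragment start; for a minus-strand fragment, read 1 is the reverse read
#' at the fragment's 3' (genomic right) end. FLAG bits follow the SAM
#' specification: 0x1 paired, 0x2 proper pair (cleared for improper
#' decoys), 0x10/0x20 strand, 0x40/0x80 first/last, 0x200 QC fail, 0x400
#' duplicate. Sequences are written as N runs (this emitter carries no base
#' calls). Reading goes through Rsamtools (SAM -> BAM -> records) and
#' reconstructs each fragment from its pair; fragment strand is the strand
#' of read 1.
#'
#' @param fragments Fragment alignment data frame.
#' @param path SAM file path.
#' @param chrom_lengths Named chromosome lengths for the header (or a
#'   `toy_genome`).
#' @param read_length Read length of each mate (default `min(100,`
#'   fragment length`)`).
#' @return `read_fragments_sam` returns a fragment data frame; the writer
#'   returns `path` invisibly.
#' @export
write_fragments_sam <- function(fragments, path, chrom_lengths,
                                read_length = 100L) {
  if (inherits(chrom_lengths, "toy_genome")) {
    chrom_lengths <- stats::setNames(chrom_lengths$chromosomes$length,
                                     chrom_lengths$chromosomes$chrom)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths))), con)
  n <- nrow(fragments)
  if (n == 0L) return(invisible(path))
  flen <- fragments$end - fragments$start
  rlen <- pmin(as.integer(read_length), flen)
  qname <- sprintf("frag%07d", seq_len(n))
  base <- 0x1 + ifelse(fragments$properly_paired, 0x2, 0) +
    ifelse(fragments$duplicate, 0x400, 0) +
    ifelse(fragments$qc_failed, 0x200, 0)
  minus <- fragments$strand == "-"
  # read 1 carries the fragment strand; read 2 is its mate on the opposite
  flag1 <- base + 0x40 + ifelse(minus, 0x10, 0x20)
  flag2 <- base + 0x80 + ifelse(minus, 0x20, 0x10)
  pos_left <- fragments$start + 1L                 # 1-based leftmost
  pos_right <- fragments$end - rlen + 1L
  pos1 <- ifelse(minus, pos_right, pos_left)
  pos2 <- ifelse(minus, pos_left, pos_right)
  cigar <- sprintf("%dM", rlen)
  seqs <- vapply(rlen, function(k) strrep("N", k), character(1))
  line <- function(q, f, p, mp, tl) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t*",
            q, f, fragments$chrom, p, fragments$mapq, cigar, mp, tl, seqs)
  }
  tlen <- ifelse(minus, -flen, flen)
  writeLines(c(line(qname, flag1, pos1, pos2, tlen),
               line(qname, flag2, pos2, pos1, -tlen)), con)
  invisible(path)
}

#' @rdname write_fragments_sam
#' @export
read_fragments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))))
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "mapq"),
      flag = Rsamtools::scanBamFlag()))[[1]]
  d <- data.frame(qname = res$qname, flag = res$flag,
                  chrom = as.character(res$rname), pos = res$pos,
                  qwidth = res$qwidth, mapq = res$mapq,
                  stringsAsFactors = FALSE)
  first <- bitwAnd(d$flag, 0x40) > 0
  agg_start <- tapply(d$pos, d$qname, min)
  agg_end <- tapply(d$pos + d$qwidth - 1L, d$qname, max)
  d1 <- d[first, , drop = FALSE]
  i <- match(d1$qname, names(agg_start))
  out <- data.frame(
    chrom = d1$chrom,
    start = as.integer(agg_start[i] - 1L),
    end = as.integer(agg_end[i]),
    strand = ifelse(bitwAnd(d1$flag, 0x10) > 0, "-", "+"),
    mapq = as.integer(d1$mapq),
    properly_paired = bitwAnd(d1$flag, 0x2) > 0,
    duplicate = bitwAnd(d1$flag, 0x400) > 0,
    qc_failed = bitwAnd(d1$flag, 0x200) > 0,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

genes_to_granges <- function(genome) {
  genes <- genes_df(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$ID <- genes$gene
  gr$Name <- genes$gene
  gr$type <- "gene"
  if (inherits(genome, "toy_genome")) {
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(
      genome$chromosomes$length, genome$chromosomes$chrom)
  }
  gr
}

#' Write / read a gene annotation as GFF3 or BED
#'
#' GFF3 is written 1-based inclusive and converted back to the internal
#' 0-based half-open convention on read; BED is 0-based half-open
#' natively. Both go through rtracklayer.
#'
#' @param genome A `toy_genome` or gene annotation data frame.
#' @param path File path.
#' @return Readers return a gene data frame (`gene`, `chrom`, `start`,
#'   `end`, `strand`, `length`); writers return `path` invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  rtracklayer::export(genes_to_granges(genome), path, format = "gff3")
  invisible(path)
}

#' @rdname write_genome_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  granges_to_genes(gr, ids)
}

#' @rdname write_genome_gff3
#' @export
write_genome_bed <- function(genome, path) {
  gr <- genes_to_granges(genome)
  names(gr) <- gr$ID
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_genome_gff3
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  granges_to_genes(gr, gr$name)
}

granges_to_genes <- function(gr, ids) {
  data.frame(
    gene = as.character(ids),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE)
}

#' Write a coverage profile as bedGraph
#'
#' Adjacent equal-coverage positions are collapsed into intervals; zero
#' runs are omitted. One file per strand is conventional.
#'
#' @param profile A `coverage_profile`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  x <- profile$coverage
  r <- rle(x)
  end <- profile$start + cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values > 0
  df <- data.frame(chrom = profile$chrom, start = start[keep],
                   end = end[keep], value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read planted truth as JSON
#'
#' Serializes `sga_truth` and `transcriptome_truth` objects (including
#' attributes) so planted truths round-trip losslessly alongside the data.
#'
#' @param truth An `sga_truth` or `transcriptome_truth`.
#' @param path File path.
#' @return Readers return the reconstructed truth object; the writer
#'   returns `path` invisibly.
#' @export
write_truth_json <- function(truth, path) {
  if (inherits(truth, "sga_truth")) {
    obj <- list(kind = "sga_truth",
                table = as.data.frame(truth),
                masked = attr(truth, "masked"),
                screens = attr(truth, "screens"))
  } else if (inherits(truth, "transcriptome_truth")) {
    obj <- list(kind = "transcriptome_truth", genes = truth$genes,
                conditions = truth$conditions, nts = truth$nts)
  } else stop_ps("unsupported truth object")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$kind, "sga_truth")) {
    structure(as.data.frame(obj$table, stringsAsFactors = FALSE),
              masked = as.character(obj$masked),
              screens = as.character(obj$screens),
              class = c("sga_truth", "data.frame"))
  } else if (identical(obj$kind, "transcriptome_truth")) {
    genes <- as.data.frame(obj$genes, stringsAsFactors = FALSE)
    if (is.null(genes$direction)) genes$direction <- NA_character_
    genes$direction <- as.character(genes$direction)
    # rows without a planted direction omit the key in JSON; restore the
    # canonical column order
    genes <- genes[, c("gene", "abundance", "fold_change", "direction",
                       "bias")]
    structure(list(genes = genes,
                   conditions = as.character(obj$conditions),
                   nts = as.data.frame(obj$nts, stringsAsFactors = FALSE)),
              class = "transcriptome_truth")
  } else stop_ps("unrecognized truth file")
}
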