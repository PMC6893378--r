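# Two-library differential expression: per-feature chi-squared test on
# count proportions, a Benjamini-Hochberg P-value threshold, fold-change and
# minimum-read filters, bin-level calls, merged region calls with
# genic/intergenic classification, and direction-aware three-set overlaps.

#' Differential-expression parameter set
#'
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.05).
#' @param fc_min RPKM fold-change filter, exclusive (default 1.5; use 1.3
#'   for the lenient survey mode).
#' @param min_reads Minimum aligned reads per feature, exclusive -- a
#'   feature must have `max(cA, cB) > min_reads` (default 5).
#' @param bin_width Bin width in bp for bin-level analysis (default 175).
#' @return A validated list of class `de_params`.
#' @export
de_params <- function(fdr = 0.05, fc_min = 1.5, min_reads = 5L,
                      bin_width = 175L) {
  check_scalar_num(fdr, "fdr", 1e-12, 1 - 1e-12)
  if (fc_min <= 1) stop_ps("`fc_min` must be > 1")
  if (min_reads < 0) stop_ps("`min_reads` must be >= 0")
  structure(list(fdr = fdr, fc_min = fc_min, min_reads = as.integer(min_reads),
                 bin_width = as.integer(bin_width)), class = "de_params")
}

#' Chi-squared P-value for a feature between two libraries
#'
#' Tests the null hypothesis that a feature is not differentially expressed
#' between two libraries by a Pearson chi-squared test (1 df, no continuity
#' correction) on the 2x2 table `[[cA, NA-cA], [cB, NB-cB]]` -- the feature's
#' counts against the rest of each library. Vectorized over features.
#' Features with `cA = cB = 0` are not testable and get P = 1 (flagged in
#' the `testable` attribute).
#'
#' @param cA,cB Feature counts in libraries A and B.
#' @param NA_,NB Library sizes (total assigned fragments).
#' @return Numeric vector of upper-tail P-values, with attributes
#'   `statistic` and `testable`.
#' @examples
#' chisq_de_pvalue(50, 10, 1e6, 1e6)
#' @export
chisq_de_pvalue <- function(cA, cB, NA_, NB) {
  if (any(NA_ <= 0) || any(NB <= 0)) stop_ps("library sizes must be > 0")
  if (any(cA < 0) || any(cB < 0) || any(cA > NA_) || any(cB > NB)) {
    stop_ps("counts must satisfy 0 <= count <= library size")
  }
  a <- as.numeric(cA); b <- as.numeric(NA_) - a
  c <- as.numeric(cB); d <- as.numeric(NB) - c
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den > 0, num / den, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  testable <- (cA + cB) > 0
  p[!testable] <- 1
  stat[!testable] <- 0
  attr(p, "statistic") <- stat
  attr(p, "testable") <- testable
  p
}

#' Benjamini-Hochberg P-value threshold
#'
#' Step-up rule: sort the m P-values ascending and return the largest
#' `p(k)` with `p(k) <= k * fdr / m`, or 0 (select nothing) if no k
#' qualifies or the list is empty. Every P-value at or below the returned
#' threshold is selected at the stated false discovery rate.
#'
#' @param pvalues P-values in `[0, 1]`.
#' @param fdr Target false discovery rate.
#' @return The P-value threshold (a single number, possibly 0).
#' @examples
#' bh_pvalue_threshold(c(0.001, 0.01, 0.02, 0.5), 0.05)  # 0.02
#' @export
bh_pvalue_threshold <- function(pvalues, fdr) {
  if (!length(pvalues)) return(0)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_ps("P-values must lie in [0, 1]")
  }
  p <- sort(pvalues)
  m <- length(p)
  ok <- which(p <= seq_len(m) * fdr / m)
  if (!length(ok)) 0 else p[max(ok)]
}

# Shared caller for gene- and bin-level features.
de_call_table <- function(feature, cA, cB, rA, rB, params,
                          apply_min_reads = TRUE) {
  p <- chisq_de_pvalue(cA, cB, sum(cA), sum(cB))
  testable <- attr(p, "testable")
  p <- as.numeric(p)
  thr <- bh_pvalue_threshold(p[testable], params$fdr)
  fc <- pmax(rA, rB) / pmin(rA, rB)
  direction <- ifelse(rB >= rA, "up_in_B", "down_in_B")
  pass <- testable & p <= thr & fc > params$fc_min
  if (apply_min_reads) pass <- pass & pmax(cA, cB) > params$min_reads
  data.frame(feature = feature, cA = cA, cB = cB, rpkmA = rA, rpkmB = rB,
             fc = fc, direction = direction, p = p, testable = testable,
             pass = pass, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes between two libraries
#'
#' Per gene: chi-squared P-value against the two library totals; a
#' Benjamini-Hochberg threshold computed over the testable genes
#' (`cA + cB > 0`); a gene passes iff its P-value is at or below that
#' threshold, its RPKM fold change `max(rA, rB) / min(rA, rB)` exceeds
#' `fc_min`, and `max(cA, cB) > min_reads`. Zero RPKMs are floored at the
#' RPKM of a single fragment in that library before the fold change, so
#' on/off genes get a finite, conservative fold change.
#'
#' @param countsA,countsB Named count vectors over the same gene universe.
#' @param gene_lengths Named gene lengths in bp (for RPKM); required unless
#'   both `rpkmA` and `rpkmB` are given.
#' @param rpkmA,rpkmB Optional precomputed RPKM vectors.
#' @param params A [de_params()] list.
#' @return Data frame of class `de_result` with one row per gene: `feature`,
#'   `cA`, `cB`, `rpkmA`, `rpkmB`, `fc`, `direction`
#'   (`up_in_B`/`down_in_B`), `p`, `testable`, `pass`.
#' @export
call_de_genes <- function(countsA, countsB, gene_lengths = NULL,
                          rpkmA = NULL, rpkmB = NULL, params = de_params()) {
  if (!setequal(names(countsA), names(countsB)) ||
      is.null(names(countsA))) {
    stop_ps("countsA and countsB must be named over the same gene universe")
  }
  genes <- names(countsA)
  countsB <- countsB[genes]
  NA_ <- sum(countsA); NB <- sum(countsB)
  if (is.null(rpkmA) || is.null(rpkmB)) {
    if (is.null(gene_lengths)) {
      stop_ps("supply `gene_lengths` or precomputed RPKM vectors")
    }
    len <- gene_lengths[genes]
    rpkmA <- compute_rpkm(countsA, len, NA_)
    rpkmB <- compute_rpkm(countsB, len, NB)
    floorA <- compute_rpkm(1, len, NA_)
    floorB <- compute_rpkm(1, len, NB)
  } else {
    rpkmA <- rpkmA[genes]; rpkmB <- rpkmB[genes]
    if (!is.null(gene_lengths)) {
      len <- gene_lengths[genes]
      floorA <- compute_rpkm(1, len, NA_)
      floorB <- compute_rpkm(1, len, NB)
    } else {
      # no lengths available: floor zeros at the smallest positive RPKM seen
      floorA <- min(rpkmA[rpkmA > 0], 1)
      floorB <- min(rpkmB[rpkmB > 0], 1)
    }
  }
  rA <- pmax(rpkmA, floorA)
  rB <- pmax(rpkmB, floorB)
  res <- de_call_table(genes, as.numeric(countsA), as.numeric(countsB),
                       as.numeric(rA), as.numeric(rB), params)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Call differentially expressed bins between two libraries
#'
#' Applies the gene-level statistic and filters to every genome-wide bin on
#' each strand independently (antisense signal never leaks across strands).
#' Because all bins share one width, the RPKM fold change reduces to a
#' counts-per-million fold change; zero-count bins are floored at one
#' fragment's CPM.
#'
#' @param binsA,binsB `bin_grid` objects on identical grids.
#' @param params A [de_params()] list.
#' @param apply_min_reads Apply the `min_reads` filter per bin
#'   (default TRUE).
#' @return Data frame of class `de_result` with bin features
#'   (`chrom:strand:bin`) plus `chrom`, `strand`, `bin`, `start`, `end`
#'   columns.
#' @export
call_de_bins <- function(binsA, binsB, params = de_params(),
                         apply_min_reads = TRUE) {
  stopifnot(inherits(binsA, "bin_grid"), inherits(binsB, "bin_grid"))
  same <- binsA$bin_width == binsB$bin_width &&
    identical(binsA$counts[c("chrom", "strand", "bin")],
              binsB$counts[c("chrom", "strand", "bin")])
  if (!same) stop_ps("bin grids do not match")
  ca <- binsA$counts$count
  cb <- binsB$counts$count
  if (!length(ca)) {
    return(structure(data.frame(
      feature = character(), cA = numeric(), cB = numeric(),
      rpkmA = numeric(), rpkmB = numeric(), fc = numeric(),
      direction = character(), p = numeric(), testable = logical(),
      pass = logical(), chrom = character(), strand = character(),
      bin = integer(), start = integer(), end = integer(),
      stringsAsFactors = FALSE), class = c("de_result", "data.frame")))
  }
  NA_ <- sum(ca); NB <- sum(cb)
  if (NA_ == 0 || NB == 0) stop_ps("a library has zero assigned fragments")
  cpmA <- pmax(ca, 1) * 1e6 / NA_
  cpmB <- pmax(cb, 1) * 1e6 / NB
  cpmA[ca > 0] <- ca[ca > 0] * 1e6 / NA_
  cpmB[cb > 0] <- cb[cb > 0] * 1e6 / NB
  feat <- paste(binsA$counts$chrom, binsA$counts$strand, binsA$counts$bin,
                sep = ":")
  res <- de_call_table(feat, ca, cb, cpmA, cpmB, params, apply_min_reads)
  res <- cbind(res,
               binsA$counts[c("chrom", "strand", "bin", "start", "end")])
  class(res) <- c("de_result", "data.frame")
  res
}

#' Merge differential bins into regions and classify them
#'
#' Merges runs of adjacent passing bins with the same chromosome, strand,
#' and direction into regions, then classifies each region as genic if it
#' overlaps at least 1 bp of a same-strand gene (attaching those gene ids)
#' and as intergenic otherwise -- the route by which pervasive spacer
#' (NTS-like) transcription is detected.
#'
#' @param de_bins A bin-level `de_result` (only rows with `pass = TRUE` are
#'   used).
#' @param genes Gene annotation data frame or `toy_genome`.
#' @return Data frame of regions: `chrom`, `strand`, `start`, `end`,
#'   `direction`, `n_bins`, `classification` (`genic`/`intergenic`),
#'   `genes` (comma-separated ids, empty for intergenic).
#' @export
map_bins_to_regions <- function(de_bins, genes) {
  genes <- genes_df(genes)
  d <- de_bins[de_bins$pass, , drop = FALSE]
  if (!nrow(d)) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      direction = character(), n_bins = integer(),
                      classification = character(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  d <- d[order(d$chrom, d$strand, d$direction, d$bin), , drop = FALSE]
  grp_key <- paste(d$chrom, d$strand, d$direction)
  new_run <- c(TRUE, grp_key[-1] != grp_key[-nrow(d)] |
                 diff(d$bin) != 1L)
  run_id <- cumsum(new_run)
  regions <- do.call(rbind, lapply(split(d, run_id), function(r) {
    data.frame(chrom = r$chrom[1], strand = r$strand[1],
               start = min(r$start), end = max(r$end),
               direction = r$direction[1], n_bins = nrow(r),
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  regions$classification <- "intergenic"
  regions$genes <- ""
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i] &
                 genes$strand == regions$strand[i] &
                 genes$end > regions$start[i] &
                 genes$start < regions$end[i], , drop = FALSE]
    if (nrow(g)) {
      regions$classification[i] <- "genic"
      regions$genes[i] <- paste(g$gene, collapse = ",")
    }
  }
  regions
}

#' Direction-aware overlap of three differential gene lists
#'
#' Computes, separately for up- and downregulated genes, all Venn sectors of
#' three differential-expression gene lists. A gene enters the triple
#' intersection only if it is called in all three lists with the same
#' direction. A gene listed twice with conflicting directions within one
#' list is an error.
#'
#' @param lists A list of three data frames with columns `gene` and
#'   `direction` (values `"up"`/`"down"`, or the `up_in_B`/`down_in_B`
#'   labels of a `de_result`, which are normalized).
#' @return List with per-direction sector sets (`up`, `down`; each holding
#'   `only1`, `only2`, `only3`, `only12`, `only13`, `only23`, `all3`),
#'   `triple` -- a data frame of genes in the triple intersection with their
#'   shared direction -- and `counts`, a summary of sector sizes.
#' @export
overlap_de_sets <- function(lists) {
  stopifnot(length(lists) == 3L)
  norm <- lapply(seq_along(lists), function(i) {
    d <- lists[[i]]
    if (!all(c("gene", "direction") %in% names(d))) {
      stop_ps("each list needs columns `gene` and `direction`")
    }
    dir <- sub("_in_B$", "", d$direction)
    if (!all(dir %in% c("up", "down"))) stop_ps("unknown direction labels")
    d <- data.frame(gene = as.character(d$gene), direction = dir,
                    stringsAsFactors = FALSE)
    d <- unique(d)
    if (anyDuplicated(d$gene)) {
      stop_ps("list ", i, " carries a gene with conflicting directions")
    }
    d
  })
  sector <- function(s1, s2, s3) {
    list(only1 = setdiff(s1, union(s2, s3)),
         only2 = setdiff(s2, union(s1, s3)),
         only3 = setdiff(s3, union(s1, s2)),
         only12 = setdiff(intersect(s1, s2), s3),
         only13 = setdiff(intersect(s1, s3), s2),
         only23 = setdiff(intersect(s2, s3), s1),
         all3 = intersect(intersect(s1, s2), s3))
  }
  out <- list()
  triple <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(norm, function(d) d$gene[d$direction == dir])
    out[[dir]] <- sector(sets[[1]], sets[[2]], sets[[3]])
    if (length(out[[dir]]$all3)) {
      triple[[dir]] <- data.frame(gene = out[[dir]]$all3, direction = dir,
                                  stringsAsFactors = FALSE)
    }
  }
  triple <- if (length(triple)) do.call(rbind, triple) else
    data.frame(gene = character(), direction = character())
  rownames(triple) <- NULL
  counts <- data.frame(
    direction = rep(c("up", "down"), each = 7L),
    sector = rep(names(out$up), 2L),
    n = c(lengths(out$up), lengths(out$down)))
  list(up = out$up, down = out$down, triple = triple, counts = counts)
}
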