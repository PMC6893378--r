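# Scaled metagene profiles: 100-unit gene-body coverage distributions,
# 5'->3' oriented, and a head/tail quartile statistic for the 5'-bias
# signature of incomplete elongation.

#' Scale a gene's coverage to a 100-unit profile
#'
#' Partitions the gene body into 100 equal-width segments (bases straddling
#' a segment boundary contribute fractionally to both segments), takes the
#' mean per-base coverage in each segment, and normalizes the vector to sum
#' to 1. Profiles of minus-strand genes are inverted so that unit 1 is
#' always the 5' end of the transcript. A gene with zero total coverage
#' yields an empty (all-NA) profile flagged for exclusion from aggregation.
#'
#' @param coverage A [coverage_profile()] spanning the gene on the gene's
#'   strand (or any interval containing it).
#' @param gene One-row gene annotation (`gene`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @param units Number of scaled units (default 100).
#' @return Object of class `scaled_profile`: list with `gene`, `units`
#'   (numeric vector summing to 1), `total_coverage`, `empty`.
#' @export
scale_gene_profile <- function(coverage, gene, units = 100L) {
  stopifnot(inherits(coverage, "coverage_profile"))
  if (coverage$chrom != gene$chrom ||
      coverage$start > gene$start || coverage$end < gene$end) {
    stop_ps("coverage does not span the gene")
  }
  if (!is.null(gene$strand) && coverage$strand != gene$strand) {
    stop_ps("coverage strand does not match the gene strand")
  }
  x <- coverage$coverage[(gene$start - coverage$start + 1L):
                           (gene$end - coverage$start)]
  L <- length(x)
  total <- sum(x)
  if (total == 0) {
    return(structure(list(gene = gene$gene, units = rep(NA_real_, units),
                          total_coverage = 0, empty = TRUE),
                     class = "scaled_profile"))
  }
  # C(t): coverage mass over [0, t) with per-base-constant density,
  # linearly interpolated at fractional t
  cum <- c(0, cumsum(as.numeric(x)))
  Cfun <- function(t) {
    i <- floor(t)
    frac <- t - i
    cum[i + 1L] + ifelse(i < L, frac * x[pmin(i + 1L, L)], 0)
  }
  b <- seq(0, L, length.out = units + 1L)
  seg <- diff(Cfun(b))             # mass per segment
  u <- seg / (L / units)           # mean per-base coverage per segment
  u <- u / sum(u)
  if (gene$strand == "-") u <- rev(u)
  structure(list(gene = gene$gene, units = u, total_coverage = total,
                 empty = FALSE), class = "scaled_profile")
}

#' Average scaled profiles across genes
#'
#' Unweighted arithmetic mean per unit over all non-empty profiles; since
#' each input sums to 1, so does the aggregate.
#'
#' @param profiles List of `scaled_profile` objects.
#' @return Numeric vector (one value per unit) summing to 1.
#' @export
aggregate_profiles <- function(profiles) {
  keep <- profiles[!vapply(profiles, function(p) isTRUE(p$empty), TRUE)]
  if (!length(keep)) stop_ps("all profiles are empty; nothing to aggregate")
  rowMeans(vapply(keep, function(p) p$units,
                  numeric(length(keep[[1]]$units))))
}

#' 5'-bias score of a scaled profile
#'
#' Ratio of the mean profile value over the leading `head_frac` of the gene
#' body to the mean over the trailing `tail_frac`; a flat profile scores 1,
#' and a profile is classified 5'-biased when the score exceeds
#' `bias_cutoff`. A zero tail with a positive head scores `Inf` (biased).
#'
#' @param profile A `scaled_profile`, or a bare numeric profile vector.
#' @param head_frac,tail_frac Fractions of the gene body used as head and
#'   tail (defaults 0.25 each; must sum to at most 1).
#' @param bias_cutoff Score above which a gene is called biased (default 2).
#' @return Object of class `bias_score`: list with `gene`, `score`,
#'   `biased`.
#' @export
five_prime_bias_score <- function(profile, head_frac = 0.25,
                                  tail_frac = 0.25, bias_cutoff = 2) {
  if (head_frac + tail_frac > 1 + 1e-12) {
    stop_ps("head_frac + tail_frac must be <= 1")
  }
  gene <- NA_character_
  u <- profile
  if (inherits(profile, "scaled_profile")) {
    if (isTRUE(profile$empty)) stop_ps("cannot score an empty profile")
    gene <- profile$gene
    u <- profile$units
  }
  if (!length(u) || all(is.na(u))) stop_ps("cannot score an empty profile")
  n <- length(u)
  nh <- max(1L, round(n * head_frac))
  nt <- max(1L, round(n * tail_frac))
  head_mean <- mean(u[seq_len(nh)])
  tail_mean <- mean(u[(n - nt + 1L):n])
  score <- if (tail_mean == 0) {
    if (head_mean > 0) Inf else stop_ps("profile has no head or tail mass")
  } else head_mean / tail_mean
  structure(list(gene = gene, score = score, biased = score > bias_cutoff),
            class = "bias_score")
}

#' Per-gene scaled profiles and bias scores over an annotation
#'
#' Convenience wrapper: builds each gene's strand-matched coverage profile
#' from a fragment table, scales it, and scores the 5' bias.
#'
#' @param fragments Filtered fragment alignments.
#' @param genes Gene annotation data frame or `toy_genome`.
#' @param units Profile resolution.
#' @param head_frac,tail_frac,bias_cutoff Passed to
#'   [five_prime_bias_score()].
#' @return List with `profiles` (named list of `scaled_profile`) and
#'   `scores` (data frame: `gene`, `n_units`, `total_coverage`, `score`,
#'   `biased`; empty-profile genes get NA score).
#' @export
metagene_scores <- function(fragments, genes, units = 100L,
                            head_frac = 0.25, tail_frac = 0.25,
                            bias_cutoff = 2) {
  genes <- genes_df(genes)
  profiles <- vector("list", nrow(genes))
  names(profiles) <- genes$gene
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cov <- coverage_profile(fragments, chrom = g$chrom, start = g$start,
                            end = g$end, strand = g$strand)
    pr <- scale_gene_profile(cov, g, units = units)
    profiles[[i]] <- pr
    if (pr$empty) {
      rows[[i]] <- data.frame(gene = g$gene, n_units = units,
                              total_coverage = 0, score = NA_real_,
                              biased = NA, stringsAsFactors = FALSE)
    } else {
      b <- five_prime_bias_score(pr, head_frac, tail_frac, bias_cutoff)
      rows[[i]] <- data.frame(gene = g$gene, n_units = units,
                              total_coverage = pr$total_coverage,
                              score = b$score, biased = b$biased,
                              stringsAsFactors = FALSE)
    }
  }
  list(profiles = profiles, scores = do.call(rbind, rows))
}
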