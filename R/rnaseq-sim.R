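# Fragment-level RNA-seq simulator and the reporter-propagation simulator.

# Inverse CDF of the truncated exponential on [0,1] with rate r (r = 0 is
# uniform).  Used for 5'-shifted start densities: density decays from u = 0
# (the 5' end) toward u = 1.
qtexp <- function(p, rate) {
  if (rate == 0) return(p)
  -log(1 - p * (1 - exp(-rate))) / rate
}

#' Simulate strand-specific paired-end fragment alignments
#'
#' Draws `depth` sequenced-fragment alignments over a toy genome. Fragments
#' are allocated to transcribed features (genes, plus NTS-like regions active
#' in `condition`) by a multinomial whose weights are expected abundance
#' (fragments per kb, fold change applied in the alternative condition) times
#' feature length. Start positions within a gene are uniform unless the gene
#' carries a planted 5' shift, in which case the start density decays from
#' the 5' end with a truncated-exponential rate equal to the shift parameter
#' (minus-strand genes decay from their genomic right end). Active NTS-like
#' regions emit fragments on both strands. On top of the `depth` clean
#' fragments, configurable fractions of decoys are appended -- coordinate
#' duplicates, low-MAPQ, chastity(QC)-failed, and improperly paired records
#' -- so that alignment filters are exercised on realistic input.
#'
#' @param genome A `toy_genome`.
#' @param truth A `transcriptome_truth` over the same genome.
#' @param condition Which condition's abundances to simulate.
#' @param depth Number of clean fragments to draw (> 0).
#' @param fragment_length Fragment length in bp (fixed; default 200).
#' @param decoy_frac Named fractions of `depth` for each decoy class:
#'   `duplicate`, `low_mapq`, `qc_fail`, `improper`.
#' @param mapq MAPQ assigned to clean fragments.
#' @param seed Integer seed.
#'
#' @return A data frame of fragment alignments with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `mapq`, `properly_paired`,
#'   `duplicate`, `qc_failed`. Row count = `depth` + total decoys.
#' @export
simulate_fragments <- function(genome, truth, condition, depth,
                               fragment_length = 200L,
                               decoy_frac = c(duplicate = 0.05, low_mapq = 0.05,
                                              qc_fail = 0.05, improper = 0.05),
                               mapq = 60L,
                               seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"), inherits(truth, "transcriptome_truth"))
  if (depth <= 0) stop_ps("`depth` must be > 0")
  fragment_length <- as.integer(fragment_length)
  ab <- expected_abundance(truth, condition)
  genes <- genome$genes
  feat <- data.frame(
    id = genes$gene, chrom = genes$chrom, start = genes$start, end = genes$end,
    strand = genes$strand, weight = ab[genes$gene] * genes$length / 1000,
    bias = truth$genes$bias[match(genes$gene, truth$genes$gene)],
    stringsAsFactors = FALSE)
  nts_act <- truth$nts[truth$nts$condition == condition & truth$nts$active, ,
                       drop = FALSE]
  if (nrow(nts_act) > 0L) {
    reg <- genome$nts[match(nts_act$region, genome$nts$region), , drop = FALSE]
    feat <- rbind(feat, data.frame(
      id = paste0(nts_act$region, nts_act$strand),
      chrom = reg$chrom, start = reg$start, end = reg$end,
      strand = nts_act$strand,
      weight = nts_act$abundance * (reg$end - reg$start) / 1000,
      bias = 0, stringsAsFactors = FALSE))
  }
  if (sum(feat$weight) <= 0) stop_ps("total transcription weight is zero")

  with_seed(seed, {
    n_feat <- as.integer(stats::rmultinom(1L, depth, feat$weight))
    fi <- rep.int(seq_len(nrow(feat)), n_feat)
    fi <- fi[sample.int(length(fi))]  # interleave features
    L <- feat$end[fi] - feat$start[fi]
    fl <- pmin(fragment_length, L)
    span <- L - fl  # start offsets 0..span from the 5' end
    p <- stats::runif(length(fi))
    u <- p
    b <- feat$bias[fi]
    shifted <- b > 0
    if (any(shifted)) {
      # vectorised truncated-exponential inverse CDF over per-row rates
      r <- b[shifted]
      u[shifted] <- -log(1 - p[shifted] * (1 - exp(-r))) / r
    }
    off <- floor(u * (span + 1))
    off[off > span] <- span[off > span]
    start <- ifelse(feat$strand[fi] == "+",
                    feat$start[fi] + off,
                    feat$end[fi] - fl - off)
    clean <- data.frame(
      chrom = feat$chrom[fi],
      start = as.integer(start),
      end = as.integer(start + fl),
      strand = feat$strand[fi],
      mapq = as.integer(mapq),
      properly_paired = TRUE,
      duplicate = FALSE,
      qc_failed = FALSE,
      stringsAsFactors = FALSE)

    decoys <- list()
    n_of <- function(key) {
      f <- if (key %in% names(decoy_frac)) decoy_frac[[key]] else 0
      as.integer(round(depth * f))
    }
    rand_frag <- function(n) {
      ci <- sample.int(nrow(genome$chromosomes), n, replace = TRUE)
      clen <- genome$chromosomes$length[ci]
      s <- floor(stats::runif(n) * pmax(1, clen - fragment_length))
      data.frame(chrom = genome$chromosomes$chrom[ci],
                 start = as.integer(s),
                 end = as.integer(pmin(s + fragment_length, clen)),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 mapq = as.integer(mapq), properly_paired = TRUE,
                 duplicate = FALSE, qc_failed = FALSE,
                 stringsAsFactors = FALSE)
    }
    nd <- n_of("duplicate")
    if (nd > 0L) {
      d <- clean[sample.int(nrow(clean), nd, replace = TRUE), , drop = FALSE]
      d$duplicate <- TRUE
      decoys$duplicate <- d
    }
    nl <- n_of("low_mapq")
    if (nl > 0L) {
      d <- rand_frag(nl)
      d$mapq <- sample(0:4, nl, replace = TRUE)
      decoys$low_mapq <- d
    }
    nq <- n_of("qc_fail")
    if (nq > 0L) {
      d <- rand_frag(nq)
      d$qc_failed <- TRUE
      decoys$qc_fail <- d
    }
    ni <- n_of("improper")
    if (ni > 0L) {
      d <- rand_frag(ni)
      d$properly_paired <- FALSE
      decoys$improper <- d
    }
    out <- do.call(rbind, c(list(clean), unname(decoys)))
    rownames(out) <- NULL
    out
  })
}

#' Simulate reporter-propagation outcomes
#'
#' Bernoulli draws for a silencing/loss propagation assay: each picked colony
#' independently retains the reporter with probability `p_retain` (grows on
#' medium lacking uracil) or has lost it.
#'
#' @param p_retain Retention probability in `[0, 1]`.
#' @param n_colonies Number of colonies picked.
#' @param seed Integer seed.
#' @return Character vector of length `n_colonies` with values `"retained"`
#'   or `"lost"`.
#' @export
simulate_propagation <- function(p_retain, n_colonies, seed = 1L) {
  check_scalar_num(p_retain, "p_retain", 0, 1)
  if (n_colonies < 1) stop_ps("`n_colonies` must be >= 1")
  with_seed(seed, {
    ifelse(stats::rbinom(n_colonies, 1L, p_retain) == 1L, "retained", "lost")
  })
}
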