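#' Simulate a toy genome with non-overlapping genes and NTS-like spacers
#'
#' Builds a small annotated genome for end-to-end testing: genes are packed
#' left to right on each chromosome, separated by intergenic spacers, and a
#' subset of interior spacers is flagged as NTS-like regions -- intergenic
#' intervals that are transcriptionally silent at baseline, emulating the
#' nontranscribed spacers of the rDNA repeat. All coordinates are 0-based,
#' half-open.
#'
#' @param n_genes Number of genes to place (>= 2).
#' @param n_chromosomes Number of chromosomes; genes are split evenly.
#' @param gene_length_range Length range in bp, sampled uniformly.
#' @param spacer_fraction Fraction of each chromosome devoted to intergenic
#'   spacers, in `[0, 1)`.
#' @param n_nts Number of interior spacers to flag as NTS-like regions.
#' @param chromosome_length Optional fixed chromosome length in bp (recycled
#'   across chromosomes). If the packed genes plus spacers do not fit, an
#'   error is raised; if longer than needed, the surplus becomes a trailing
#'   spacer. Default `NULL` sizes each chromosome to its content.
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#'
#' @return An object of class `toy_genome`: a list with `chromosomes`
#'   (data frame: `chrom`, `length`), `genes` (data frame: `gene`, `chrom`,
#'   `start`, `end`, `strand`, `length`) and `nts` (data frame: `region`,
#'   `chrom`, `start`, `end`).
#' @examples
#' g <- simulate_toy_genome(n_genes = 10, seed = 1)
#' head(g$genes)
#' @export
simulate_toy_genome <- function(n_genes,
                                n_chromosomes = 1L,
                                gene_length_range = c(500L, 3000L),
                                spacer_fraction = 0.2,
                                n_nts = 2L,
                                chromosome_length = NULL,
                                seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 2) stop_ps("`n_genes` must be >= 2")
  if (any(gene_length_range <= 0)) stop_ps("gene lengths must be positive")
  check_scalar_num(spacer_fraction, "spacer_fraction", 0, 1 - 1e-9)
  n_genes <- as.integer(n_genes)
  n_chromosomes <- as.integer(n_chromosomes)

  with_seed(seed, {
    lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                   n_genes, replace = TRUE)
    strands <- ifelse(stats::rbinom(n_genes, 1L, 0.5) == 1L, "+", "-")
    chrom_of <- sort(rep_len(seq_len(n_chromosomes), n_genes))
    chrom_names <- sprintf("chr%d", seq_len(n_chromosomes))

    genes <- vector("list", n_chromosomes)
    nts_all <- list()
    chrom_len <- integer(n_chromosomes)
    gi <- 0L
    for (ci in seq_len(n_chromosomes)) {
      idx <- which(chrom_of == ci)
      glen <- lens[idx]
      n_on <- length(idx)
      # spacer budget so spacers take spacer_fraction of the chromosome
      total_spacer <- round(sum(glen) * spacer_fraction / (1 - spacer_fraction))
      gap <- max(10L, as.integer(floor(total_spacer / (n_on + 1L))))
      starts <- cumsum(c(gap, glen[-n_on] + gap))
      ends <- starts + glen
      need <- ends[n_on] + gap
      if (!is.null(chromosome_length)) {
        want <- rep_len(as.integer(chromosome_length), n_chromosomes)[ci]
        if (need > want) {
          stop_ps(sprintf(
            "infeasible packing on %s: need %d bp but chromosome_length is %d",
            chrom_names[ci], need, want))
        }
        chrom_len[ci] <- want
      } else {
        chrom_len[ci] <- need
      }
      genes[[ci]] <- data.frame(
        gene = sprintf("g%04d", gi + seq_len(n_on)),
        chrom = chrom_names[ci],
        start = as.integer(starts),
        end = as.integer(ends),
        strand = strands[idx],
        length = as.integer(glen),
        stringsAsFactors = FALSE)
      gi <- gi + n_on
      # interior spacers: between gene i and i+1, trimmed by 1 bp margins
      if (n_on >= 2L) {
        sp <- data.frame(chrom = chrom_names[ci],
                         start = as.integer(ends[-n_on] + 1L),
                         end = as.integer(starts[-1L] - 1L))
        nts_all[[length(nts_all) + 1L]] <- sp[sp$end - sp$start >= 8L, , drop = FALSE]
      }
    }
    genes <- do.call(rbind, genes)
    spacers <- if (length(nts_all)) do.call(rbind, nts_all) else
      data.frame(chrom = character(), start = integer(), end = integer())
    n_nts <- min(as.integer(n_nts), nrow(spacers))
    nts <- if (n_nts > 0L) {
      pick <- sort(sample.int(nrow(spacers), n_nts))
      out <- spacers[pick, , drop = FALSE]
      out$region <- sprintf("NTS%d", seq_len(n_nts))
      rownames(out) <- NULL
      out[, c("region", "chrom", "start", "end")]
    } else {
      data.frame(region = character(), chrom = character(),
                 start = integer(), end = integer())
    }
    structure(list(
      chromosomes = data.frame(chrom = chrom_names, length = chrom_len,
                               stringsAsFactors = FALSE),
      genes = genes,
      nts = nts), class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosome(s), %d genes, %d NTS-like region(s)\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$nts)))
  invisible(x)
}

#' Construct SGA planted truth for a set of array genes
#'
#' Assigns each gene an interaction class (none, negative, suppressor) and a
#' fitness effect multiplier per screen. Interactions planted in a
#' single-query screen are inherited by the double-deletion screen (a gene
#' that is sick with one paralog deletion stays sick when both are gone);
#' `n_common` genes interact with both single queries. On top of these, a
#' set of masked interactors is planted: genes whose deletion affects
#' fitness only in the double-deletion screen, never in either single-query
#' screen. Effect multipliers below 1 model synthetic sickness, above 1
#' suppression; genes of class none carry multiplier 1 everywhere.
#'
#' @param genes Character vector of array gene ids.
#' @param screens Labels for the two single-query screens and the double
#'   screen, in that order.
#' @param n_negative,n_suppressor Number of negative/suppressor interactors
#'   planted per single-query screen (each unique to its screen).
#' @param n_common Number of negative interactors shared by both
#'   single-query screens.
#' @param n_masked Number of masked interactors (negative in the double
#'   screen only).
#' @param negative_effect,suppressor_effect Ranges the effect multipliers are
#'   drawn from (uniform, independently per gene and screen).
#' @param seed Integer seed.
#'
#' @return Object of class `sga_truth`: data frame with columns `gene`,
#'   `screen`, `class`, `multiplier` (one row per gene x screen), with the
#'   masked gene ids in `attr(, "masked")`.
#' @export
simulate_sga_truth <- function(genes,
                               screens = c("dA", "dB", "dAB"),
                               n_negative = 20L,
                               n_suppressor = 10L,
                               n_common = 0L,
                               n_masked = 10L,
                               negative_effect = c(0.2, 0.5),
                               suppressor_effect = c(1.8, 2.5),
                               seed = 1L) {
  stopifnot(length(screens) == 3L)
  genes <- as.character(genes)
  n_hit <- 2L * (n_negative + n_suppressor) + n_common + n_masked
  if (n_hit > length(genes)) {
    stop_ps("not enough genes for the requested planted interactions")
  }
  with_seed(seed, {
    pool <- sample(genes, n_hit)
    take <- function(n) {
      if (n == 0L) return(character(0))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    truth <- expand.grid(gene = genes, screen = screens,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$class <- "none"
    truth$multiplier <- 1
    plant <- function(truth, g, scrs, cls, rng) {
      i <- truth$gene %in% g & truth$screen %in% scrs
      truth$class[i] <- cls
      truth$multiplier[i] <- stats::runif(sum(i), rng[1], rng[2])
      truth
    }
    dbl <- screens[3]
    for (k in 1:2) {  # single-screen hits carry into the double screen
      truth <- plant(truth, take(n_negative), c(screens[k], dbl),
                     "negative", negative_effect)
      truth <- plant(truth, take(n_suppressor), c(screens[k], dbl),
                     "suppressor", suppressor_effect)
    }
    truth <- plant(truth, take(n_common), screens, "negative",
                   negative_effect)
    masked <- take(n_masked)
    truth <- plant(truth, masked, dbl, "negative", negative_effect)
    structure(truth, masked = masked, screens = screens, class =
                c("sga_truth", "data.frame"))
  })
}

#' Construct transcriptome planted truth over a toy genome
#'
#' Assigns every gene a baseline abundance (expected fragments per kb), plants
#' a differential-expression set with a fold change and direction that applies
#' in the second (alternative) condition, plants a 5'-bias set whose fragment
#' start density decays from the 5' end, and activates NTS-like regions (both
#' strands) in chosen conditions to emulate pervasive bidirectional spacer
#' transcription.
#'
#' @param genome A `toy_genome`.
#' @param conditions Two condition labels, reference first.
#' @param abundance_range Baseline abundance range (fragments per kb),
#'   sampled log-uniformly.
#' @param n_de Number of planted differentially expressed genes.
#' @param de_fold Fold change (> 1) applied in the alternative condition.
#' @param n_bias Number of genes given a 5'-shifted start density.
#' @param bias_shift Truncated-exponential rate of the shift (0 = uniform).
#' @param nts_conditions Conditions in which NTS-like regions transcribe
#'   (both strands); default: active only in the alternative condition.
#' @param nts_abundance Abundance of active NTS regions (fragments per kb);
#'   default: the median gene abundance.
#' @param seed Integer seed.
#'
#' @return Object of class `transcriptome_truth`: list with `genes` (data
#'   frame: `gene`, `abundance`, `fold_change`, `direction`, `bias`),
#'   `conditions`, and `nts` (data frame: `region`, `condition`, `strand`,
#'   `active`, `abundance`).
#' @export
simulate_transcriptome_truth <- function(genome,
                                         conditions = c("wt", "mut"),
                                         abundance_range = c(5, 100),
                                         n_de = 20L,
                                         de_fold = 4,
                                         n_bias = 0L,
                                         bias_shift = 3,
                                         nts_conditions = conditions[2],
                                         nts_abundance = NULL,
                                         seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"), length(conditions) == 2L)
  if (de_fold <= 1) stop_ps("`de_fold` must be > 1")
  g <- genome$genes$gene
  if (n_de + n_bias > length(g)) stop_ps("too many planted genes requested")
  with_seed(seed, {
    ab <- exp(stats::runif(length(g), log(abundance_range[1]),
                           log(abundance_range[2])))
    pick <- sample(g, n_de + n_bias)
    de <- utils::head(pick, n_de)
    bias <- utils::tail(pick, n_bias)
    genes <- data.frame(
      gene = g, abundance = ab, fold_change = 1,
      direction = NA_character_, bias = 0, stringsAsFactors = FALSE)
    genes$fold_change[genes$gene %in% de] <- de_fold
    genes$direction[genes$gene %in% de] <-
      sample(c("up", "down"), n_de, replace = TRUE)
    genes$bias[genes$gene %in% bias] <- bias_shift
    if (is.null(nts_abundance)) nts_abundance <- stats::median(ab)
    nts <- expand.grid(region = genome$nts$region, condition = conditions,
                       strand = c("+", "-"), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    nts$active <- nts$condition %in% nts_conditions
    nts$abundance <- ifelse(nts$active, nts_abundance, 0)
    structure(list(genes = genes, conditions = conditions, nts = nts),
              class = "transcriptome_truth")
  })
}

#' Expected per-gene abundance in one condition
#'
#' Applies each gene's planted fold change (in its planted direction) to the
#' baseline abundance when `condition` is the alternative condition.
#'
#' @param truth A `transcriptome_truth`.
#' @param condition One of `truth$conditions`.
#' @return Named numeric vector of expected fragments per kb.
#' @export
expected_abundance <- function(truth, condition) {
  stopifnot(inherits(truth, "transcriptome_truth"))
  if (!condition %in% truth$conditions) stop_ps("unknown condition")
  ab <- truth$genes$abundance
  if (condition == truth$conditions[2]) {
    fc <- truth$genes$fold_change
    dir <- truth$genes$direction
    ab <- ab * ifelse(is.na(dir), 1, ifelse(dir == "up", fc, 1 / fc))
  }
  stats::setNames(ab, truth$genes$gene)
}
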