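# Shared fixture builders: tiny hand-specified genomes, truths, and
# fragment tables for exact-value tests.

manual_genome <- function(genes, chrom_lengths, nts = NULL) {
  genes$length <- genes$end - genes$start
  if (is.null(nts)) {
    nts <- data.frame(region = character(), chrom = character(),
                      start = integer(), end = integer())
  }
  structure(list(
    chromosomes = data.frame(chrom = names(chrom_lengths),
                             length = as.integer(chrom_lengths),
                             stringsAsFactors = FALSE),
    genes = genes, nts = nts), class = "toy_genome")
}

manual_tx_truth <- function(genome, abundance, fold_change = NULL,
                            direction = NULL, bias = NULL,
                            conditions = c("wt", "mut"),
                            nts_active_in = character(),
                            nts_abundance = 50) {
  g <- genome$genes$gene
  n <- length(g)
  if (is.null(fold_change)) fold_change <- rep(1, n)
  if (is.null(direction)) {
    direction <- ifelse(fold_change > 1, "up", NA_character_)
  }
  if (is.null(bias)) bias <- rep(0, n)
  nts <- expand.grid(region = genome$nts$region, condition = conditions,
                     strand = c("+", "-"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  nts$active <- nts$condition %in% nts_active_in
  nts$abundance <- ifelse(nts$active, nts_abundance, 0)
  structure(list(
    genes = data.frame(gene = g, abundance = abundance,
                       fold_change = fold_change, direction = direction,
                       bias = bias, stringsAsFactors = FALSE),
    conditions = conditions, nts = nts), class = "transcriptome_truth")
}

frag_row <- function(chrom, start, end, strand = "+", mapq = 60L,
                     proper = TRUE, dup = FALSE, qcfail = FALSE) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, mapq = as.integer(mapq),
             properly_paired = proper, duplicate = dup, qc_failed = qcfail,
             stringsAsFactors = FALSE)
}

frag_table <- function(...) do.call(rbind, list(...))

# Colony table covering one screen + control, already plate-normalized
# sizes, for exact ratio checks.
manual_colonies <- function(genes, mut_sizes, ctl_sizes, screen = "dA",
                            replicates = nrow(mut_sizes)) {
  rows <- list()
  for (r in seq_len(replicates)) {
    for (i in seq_along(genes)) {
      rows[[length(rows) + 1L]] <- data.frame(
        plate = 1L, row = 1L, col = i, gene = genes[i], replicate = r,
        screen = screen, size = mut_sizes[r, i], stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        plate = 1L, row = 1L, col = i, gene = genes[i], replicate = r,
        screen = "control", size = ctl_sizes[r, i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Two-library fragment-level DE simulation over a random toy genome;
# returns gene-level calls plus the planted truth.
simulate_de_experiment <- function(n_genes, depth, n_de, de_fold, seed,
                                   params = de_params()) {
  genome <- simulate_toy_genome(n_genes = n_genes, seed = seed)
  truth <- simulate_transcriptome_truth(genome, n_de = n_de,
                                        de_fold = de_fold, seed = seed + 1L)
  fA <- filter_alignments(simulate_fragments(genome, truth, "wt", depth,
                                             seed = seed + 2L))
  fB <- filter_alignments(simulate_fragments(genome, truth, "mut", depth,
                                             seed = seed + 3L))
  cA <- count_gene_reads(fA, genome)
  cB <- count_gene_reads(fB, genome)
  de <- call_de_genes(cA, cB,
                      gene_lengths = stats::setNames(genome$genes$length,
                                                     genome$genes$gene),
                      params = params)
  list(de = de, planted = truth$genes$gene[truth$genes$fold_change > 1])
}
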