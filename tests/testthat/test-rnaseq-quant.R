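test_that("alignment filter applies MAPQ, pairing, QC, and dedup rules", {
  # MAPQ boundary: threshold of five keeps MAPQ >= 5
  f <- frag_table(frag_row("chr1", 0, 200, mapq = 4),
                  frag_row("chr1", 300, 500, mapq = 5))
  kept <- filter_alignments(f)
  expect_equal(kept$start, 300L)

  # identical coordinate tuples collapse to a single copy
  f2 <- frag_table(frag_row("chr1", 0, 200), frag_row("chr1", 0, 200),
                   frag_row("chr1", 0, 200, strand = "-"))
  expect_equal(nrow(filter_alignments(f2)), 2)

  # 100 records: 10 qc-failed, 10 improper, 10 coordinate duplicates of
  # retained records, 70 clean -> 70 retained
  clean <- do.call(rbind, lapply(seq_len(70), function(i)
    frag_row("chr1", i * 1000, i * 1000 + 200)))
  qcf <- do.call(rbind, lapply(seq_len(10), function(i)
    frag_row("chr1", 100000 + i * 1000, 100000 + i * 1000 + 200,
             qcfail = TRUE)))
  imp <- do.call(rbind, lapply(seq_len(10), function(i)
    frag_row("chr1", 200000 + i * 1000, 200000 + i * 1000 + 200,
             proper = FALSE)))
  dups <- clean[1:10, ]
  all100 <- rbind(clean, qcf, imp, dups)
  expect_equal(nrow(all100), 100)
  expect_equal(nrow(filter_alignments(all100)), 70)
})

test_that("alignment filtering is idempotent and order-stable", {
  f <- withr::with_seed(40, {
    n <- 200
    data.frame(chrom = "chr1",
               start = as.integer(sample(0:5000, n, TRUE)),
               end = 0L, strand = sample(c("+", "-"), n, TRUE),
               mapq = sample(0:60, n, TRUE),
               properly_paired = sample(c(TRUE, FALSE), n, TRUE, c(.9, .1)),
               duplicate = FALSE,
               qc_failed = sample(c(TRUE, FALSE), n, TRUE, c(.1, .9)),
               stringsAsFactors = FALSE)
  })
  f$end <- f$start + 200L
  once <- filter_alignments(f)
  expect_identical(filter_alignments(once), once)
  expect_false(is.unsorted(match(
    paste(once$chrom, once$start, once$end, once$strand),
    paste(f$chrom, f$start, f$end, f$strand))))
})

test_that("gene counting follows the strand-matched midpoint rule", {
  genes <- data.frame(gene = "g1", chrom = "chr1", start = 0L, end = 1000L,
                      strand = "+", stringsAsFactors = FALSE)
  count1 <- function(f) unname(count_gene_reads(f, manual_genome(
    genes, c(chr1 = 3000L)))["g1"])
  expect_equal(count1(frag_row("chr1", 100, 300)), 1L)           # inside
  expect_equal(count1(frag_row("chr1", 100, 300, strand = "-")), 0L) # antisense
  # fragment [990,1190): midpoint 1090 outside the gene
  expect_equal(count1(frag_row("chr1", 990, 1190)), 0L)
  # fragment [810,1010): midpoint 910 inside
  expect_equal(count1(frag_row("chr1", 810, 1010)), 1L)
  # boundary: midpoint exactly at gene start counts, at gene end does not
  expect_equal(count1(frag_row("chr1", 0, 0 + 2)), 1L)
  expect_equal(count1(frag_row("chr1", 999, 1001)), 0L)  # midpoint 1000
})

test_that("same-strand overlapping genes error unless resolved", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      start = c(0L, 500L), end = c(1000L, 1500L),
                      strand = "+", stringsAsFactors = FALSE)
  gn <- manual_genome(genes, c(chr1 = 2000L))
  f <- frag_row("chr1", 600, 800)  # midpoint 700, in both
  expect_error(count_gene_reads(f, gn), "overlapping same-strand")
  counts <- count_gene_reads(f, gn, overlap_resolve = "first")
  expect_equal(unname(counts["g1"]), 1L)  # smaller start wins
  expect_equal(unname(counts["g2"]), 0L)
  # opposite strands may overlap freely
  genes$strand <- c("+", "-")
  gn2 <- manual_genome(genes, c(chr1 = 2000L))
  expect_silent(count_gene_reads(f, gn2))
})

test_that("gene counts are conserved when genes tile all midpoints", {
  g <- simulate_toy_genome(30, seed = 50)
  tt <- simulate_transcriptome_truth(g, n_de = 0, seed = 51)
  f <- filter_alignments(simulate_fragments(g, tt, "wt", 5000, seed = 52))
  counts <- count_gene_reads(f, g)
  expect_lte(sum(counts), nrow(f))
  # all clean fragments lie within genes, so only decoy survivors differ
  clean_in_genes <- sum(counts)
  expect_gte(clean_in_genes / nrow(f), 0.8)
})

test_that("RPKM follows its defining formula and scaling law", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(7, 1500, 2e6), compute_rpkm(7, 1500, 1e6) / 2)
  expect_error(compute_rpkm(1, 1000, 0), "library_size")
  expect_error(compute_rpkm(1, 0, 10), "gene_length")
})

test_that("bin counting assigns midpoints to half-open bins and conserves totals", {
  clen <- c(chr1 = 1000L)
  # midpoint 0 -> bin 0; midpoint 175 -> bin 1
  b <- count_bins(frag_table(frag_row("chr1", 0, 2),      # midpoint 1
                             frag_row("chr1", 174, 176),  # midpoint 175
                             frag_row("chr1", 100, 200, strand = "-")),
                  clen, bin_width = 175)
  cnt <- b$counts
  expect_equal(cnt$count[cnt$strand == "+" & cnt$bin == 0], 1L)
  expect_equal(cnt$count[cnt$strand == "+" & cnt$bin == 1], 1L)
  expect_equal(cnt$count[cnt$strand == "-" & cnt$bin == 0], 1L)
  expect_equal(sum(cnt$count[cnt$strand == "+"]), 2L)
  expect_equal(sum(cnt$count[cnt$strand == "-"]), 1L)

  g <- simulate_toy_genome(20, seed = 53)
  tt <- simulate_transcriptome_truth(g, n_de = 0, seed = 54)
  f <- filter_alignments(simulate_fragments(g, tt, "wt", 4000, seed = 55))
  bg <- count_bins(f, g)
  for (s in c("+", "-")) {
    expect_equal(sum(bg$counts$count[bg$counts$strand == s]),
                 sum(f$strand == s))
  }
})

test_that("coverage profiles match a brute-force per-base oracle", {
  # one fragment: coverage 1 on [10,20), 0 elsewhere
  cp <- coverage_profile(frag_row("chr1", 10, 20), "chr1", 0, 30, "+")
  expect_equal(cp$coverage, c(rep(0L, 10), rep(1L, 10), rep(0L, 10)))
  # two overlapping fragments: 2 on the overlap
  cp2 <- coverage_profile(frag_table(frag_row("chr1", 0, 20),
                                     frag_row("chr1", 10, 30)),
                          "chr1", 0, 30, "+")
  expect_equal(max(cp2$coverage), 2L)
  expect_equal(sum(cp2$coverage), 40L)

  # randomized instance <= 10 kb against a per-base loop oracle
  f <- withr::with_seed(56, {
    s <- sample(0:9000, 300, TRUE)
    data.frame(chrom = "chr1", start = s, end = s + sample(50:400, 300, TRUE),
               strand = sample(c("+", "-"), 300, TRUE), mapq = 60L,
               properly_paired = TRUE, duplicate = FALSE, qc_failed = FALSE,
               stringsAsFactors = FALSE)
  })
  cp3 <- coverage_profile(f, "chr1", 500, 9500, "+")
  oracle <- integer(9000)
  fp <- f[f$strand == "+" & f$end > 500 & f$start < 9500, ]
  for (i in seq_len(nrow(fp))) {
    for (p in seq(max(fp$start[i], 500), min(fp$end[i], 9500) - 1)) {
      oracle[p - 500 + 1] <- oracle[p - 500 + 1] + 1L
    }
  }
  expect_equal(cp3$coverage, oracle)
  # integral identity: total mass = summed overlap lengths
  expect_equal(sum(cp3$coverage),
               sum(pmin(fp$end, 9500) - pmax(fp$start, 500)))
})

test_that("fragment tables round-trip through the TSV dialect and SAM", {
  g <- simulate_toy_genome(10, seed = 57)
  tt <- simulate_transcriptome_truth(g, n_de = 0, seed = 58)
  f <- simulate_fragments(g, tt, "wt", 500, seed = 59)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fragments_tsv(f, tsv)
  expect_equal(read_fragments_tsv(tsv), f)

  sam <- withr::local_tempfile(fileext = ".sam")
  write_fragments_sam(f, sam, g)
  back <- read_fragments_sam(sam)
  ord <- function(d) {
    d <- d[order(d$chrom, d$start, d$end, d$strand, d$mapq, d$duplicate,
                 d$qc_failed, d$properly_paired), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back), ord(f))
})

test_that("annotations round-trip through GFF3 and BED", {
  g <- simulate_toy_genome(25, n_chromosomes = 2, seed = 60)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_gff3(g, gff)
  back <- read_annotation_gff3(gff)
  ord <- function(d) d[order(d$gene), c("gene", "chrom", "start", "end",
                                        "strand", "length")]
  expect_equal(ord(back), ord(g$genes), ignore_attr = TRUE)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_genome_bed(g, bed)
  back2 <- read_annotation_bed(bed)
  expect_equal(ord(back2), ord(g$genes), ignore_attr = TRUE)
})
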