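test_that("chi-squared P-value matches the closed-form + integration oracle", {
  # equal proportions: statistic 0, P = 1
  p_eq <- chisq_de_pvalue(10, 10, 1e6, 1e6)
  expect_equal(as.numeric(p_eq), 1)
  expect_equal(attr(p_eq, "statistic"), 0)

  # oracle: Pearson statistic from the closed form; 1-df upper tail by
  # numerical integration of the chi-squared density
  pearson <- function(cA, cB, NA_, NB) {
    tab <- matrix(c(cA, NA_ - cA, cB, NB - cB), nrow = 2, byrow = TRUE)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  surv1df <- function(q) {
    stats::integrate(function(x) stats::dchisq(x, 1), q, Inf,
                     rel.tol = 1e-12)$value
  }
  cases <- list(c(50, 10, 1e6, 1e6), c(120, 80, 5e5, 7e5),
                c(3, 0, 1e4, 1e4), c(1000, 1300, 2e6, 2e6))
  for (cs in cases) {
    p <- as.numeric(chisq_de_pvalue(cs[1], cs[2], cs[3], cs[4]))
    expect_equal(p, surv1df(pearson(cs[1], cs[2], cs[3], cs[4])),
                 tolerance = 1e-9)
  }

  # symmetry: swapping the libraries leaves P unchanged
  expect_equal(as.numeric(chisq_de_pvalue(50, 10, 1e6, 2e6)),
               as.numeric(chisq_de_pvalue(10, 50, 2e6, 1e6)))

  # both zero: not testable, P = 1
  p0 <- chisq_de_pvalue(0, 0, 1e6, 1e6)
  expect_equal(as.numeric(p0), 1)
  expect_false(attr(p0, "testable"))
  expect_error(chisq_de_pvalue(5, 1, 0, 10), "library sizes")
})

test_that("BH threshold implements the step-up rule", {
  expect_equal(bh_pvalue_threshold(rep(1, 10), 0.05), 0)
  # hand-enumerated: k=3 passes (0.02 <= 3*0.05/4), k=4 fails
  expect_equal(bh_pvalue_threshold(c(0.001, 0.01, 0.02, 0.5), 0.05), 0.02)
  expect_equal(bh_pvalue_threshold(0.04, 0.05), 0.04)
  expect_equal(bh_pvalue_threshold(numeric(), 0.05), 0)
  expect_error(bh_pvalue_threshold(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  # selection at the threshold agrees with p.adjust-based BH selection
  for (s in 1:5) {
    p <- withr::with_seed(s, c(stats::runif(80), stats::rbeta(20, 0.1, 10)))
    thr <- bh_pvalue_threshold(p, 0.05)
    expect_identical(p <= thr, stats::p.adjust(p, "BH") <= 0.05)
  }
})

test_that("gene-level caller applies BH, fold-change, and min-read filters", {
  counts_A <- c(g1 = 3, g2 = 12000, g3 = 500, g4 = 100, g5 = 84385)
  counts_B <- c(g1 = 4, g2 = 10000, g3 = 100, g4 = 96, g5 = 89800)
  lens <- c(g1 = 1000, g2 = 1000, g3 = 1000, g4 = 1000, g5 = 1000)
  de <- call_de_genes(counts_A, counts_B, gene_lengths = lens)
  de <- de[match(names(counts_A), de$feature), ]
  # g1: max count 4 <= 5 -> excluded by min_reads regardless of P
  expect_false(de$pass[1])
  # g2: fold change 1.2 at libraries this size is wildly significant but
  # fails the 1.5 fold filter
  expect_lt(de$p[2], 1e-9)
  expect_false(de$pass[2])
  # g3: five-fold change, large counts -> called, down in B
  expect_true(de$pass[3])
  expect_equal(de$direction[3], "down_in_B")
  expect_error(call_de_genes(counts_A, counts_B[1:3], gene_lengths = lens),
               "universe")
})

test_that("library exchange preserves P-values and flips directions", {
  g <- simulate_toy_genome(40, seed = 70)
  tt <- simulate_transcriptome_truth(g, n_de = 8, seed = 71)
  fA <- filter_alignments(simulate_fragments(g, tt, "wt", 20000, seed = 72))
  fB <- filter_alignments(simulate_fragments(g, tt, "mut", 20000, seed = 73))
  cA <- count_gene_reads(fA, g)
  cB <- count_gene_reads(fB, g)
  lens <- stats::setNames(g$genes$length, g$genes$gene)
  d1 <- call_de_genes(cA, cB, gene_lengths = lens)
  d2 <- call_de_genes(cB, cA, gene_lengths = lens)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$fc, d2$fc)
  flip <- c(up_in_B = "down_in_B", down_in_B = "up_in_B")
  tested <- d1$fc > 1  # strict ties keep an arbitrary but harmless label
  expect_equal(unname(flip[d1$direction[tested]]), d2$direction[tested])
  expect_equal(d1$pass, d2$pass)
})

test_that("zero-RPKM genes get the one-fragment floor, not infinite fold", {
  counts_A <- c(g1 = 200, g2 = 1000)
  counts_B <- c(g1 = 0, g2 = 1200)
  lens <- c(g1 = 1000, g2 = 1000)
  de <- call_de_genes(counts_A, counts_B, gene_lengths = lens)
  g1 <- de[de$feature == "g1", ]
  expect_true(is.finite(g1$fc))
  # floored at one fragment's RPKM in library B
  expect_equal(g1$fc, (200 * 1e9 / (1000 * 1200)) /
                 (1 * 1e9 / (1000 * 1200)))
})

test_that("bin-level calls are strand-separated and match planted NTS signal", {
  # 12 expressed genes so the silent spacer is a small library fraction
  starts <- seq(0L, by = 2100L, length.out = 12L)
  genes <- data.frame(gene = sprintf("g%02d", 1:12), chrom = "chr1",
                      start = starts, end = starts + 1750L,
                      strand = rep(c("+", "-"), 6), stringsAsFactors = FALSE)
  nts <- data.frame(region = "NTS1", chrom = "chr1",
                    start = 25300L, end = 26700L)
  gn <- manual_genome(genes, c(chr1 = 28000L), nts)
  tt <- manual_tx_truth(gn, abundance = rep(40, 12), nts_active_in = "mut",
                        nts_abundance = 20)
  fA <- filter_alignments(simulate_fragments(gn, tt, "wt", 12000, seed = 74))
  fB <- filter_alignments(simulate_fragments(gn, tt, "mut", 12000, seed = 75))
  bA <- count_bins(fA, gn)
  bB <- count_bins(fB, gn)
  de <- call_de_bins(bA, bB)
  hits <- de[de$pass, ]
  # called bins sit inside the NTS interval, on both strands, up in mut
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$start >= 25300 - 175 & hits$end <= 26700 + 175))
  expect_setequal(unique(hits$strand), c("+", "-"))
  expect_true(all(hits$direction == "up_in_B"))
  regions <- map_bins_to_regions(de, gn)
  expect_true(all(regions$classification == "intergenic"))
  expect_setequal(unique(regions$strand), c("+", "-"))
  # a bin grid mismatch is rejected
  expect_error(call_de_bins(bA, count_bins(fB, gn, bin_width = 200)),
               "grids")
})

test_that("adjacent passing bins merge into regions; regions stay disjoint", {
  mk_bin <- function(bin, strand = "+", dir = "up_in_B", pass = TRUE) {
    data.frame(feature = sprintf("chr1:%s:%d", strand, bin),
               cA = 0, cB = 100, rpkmA = 1, rpkmB = 10, fc = 10,
               direction = dir, p = 1e-10, testable = TRUE, pass = pass,
               chrom = "chr1", strand = strand, bin = bin,
               start = bin * 175L, end = (bin + 1L) * 175L,
               stringsAsFactors = FALSE)
  }
  genes <- data.frame(gene = "g1", chrom = "chr1", start = 0L, end = 1000L,
                      strand = "+", stringsAsFactors = FALSE)
  gn <- manual_genome(genes, c(chr1 = 10000L))
  de <- rbind(mk_bin(10), mk_bin(11), mk_bin(12),   # one merged region
              mk_bin(14),                           # separate (gap)
              mk_bin(20, dir = "down_in_B"),        # direction break
              mk_bin(21, dir = "up_in_B"),
              mk_bin(2, strand = "-"),              # antisense over the gene
              mk_bin(3, pass = FALSE))
  regions <- map_bins_to_regions(de, gn)
  r3 <- regions[regions$start == 10 * 175 & regions$strand == "+", ]
  expect_equal(r3$n_bins, 3)
  expect_equal(r3$end - r3$start, 3 * 175)
  # a bin overlapping a gene on the same strand is genic, antisense is not
  g_bin <- map_bins_to_regions(mk_bin(1), gn)
  expect_equal(g_bin$classification, "genic")
  expect_equal(g_bin$genes, "g1")
  as_bin <- regions[regions$strand == "-", ]
  expect_equal(as_bin$classification, "intergenic")
  # disjoint per strand + direction
  for (key in unique(paste(regions$chrom, regions$strand))) {
    r <- regions[paste(regions$chrom, regions$strand) == key, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
})

test_that("three-way overlap is direction-aware", {
  l1 <- data.frame(gene = c("a", "b", "c"), direction = c("up", "up", "down"))
  l2 <- data.frame(gene = c("a", "b", "d"), direction = c("up", "down", "up"))
  l3 <- data.frame(gene = c("a", "b", "c"), direction = c("up", "up", "up"))
  ov <- overlap_de_sets(list(l1, l2, l3))
  # a: up in all three -> triple intersection
  expect_equal(ov$triple$gene, "a")
  expect_equal(ov$triple$direction, "up")
  # b: up in 1 and 3 but down in 2 -> not in the triple intersection
  expect_false("b" %in% ov$triple$gene)
  expect_true("b" %in% ov$up$only13)
  # c: down in 1 only
  expect_true("c" %in% ov$down$only1)
  # de_result-style labels are normalized
  l1b <- data.frame(gene = "a", direction = "up_in_B")
  ovb <- overlap_de_sets(list(l1b, l1b, l1b))
  expect_equal(ovb$triple$gene, "a")
  # empty lists give an empty partition
  e <- data.frame(gene = character(), direction = character())
  ov0 <- overlap_de_sets(list(e, e, e))
  expect_equal(nrow(ov0$triple), 0)
  expect_true(all(ov0$counts$n == 0))
  # conflicting directions within one list are an error
  bad <- data.frame(gene = c("a", "a"), direction = c("up", "down"))
  expect_error(overlap_de_sets(list(bad, e, e)), "conflicting")
})
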