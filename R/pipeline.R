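# Orchestration: a single seeded configuration drives simulate -> score /
# quantify -> test -> report, writing every artifact plus a run report with
# checksums and a truth-recovery summary.

#' Default pipeline configuration
#'
#' A modest, fully specified demo configuration: a one-chromosome toy
#' genome, a triplicate colony screen with planted negative, suppressor,
#' and masked interactions, and a two-condition fragment simulation with
#' planted differential expression, 5'-shifted genes, and NTS-like spacer
#' activation in the alternative condition.
#'
#' @param outdir Output directory for run artifacts.
#' @param seed Master seed; stage seeds are derived from it and logged.
#' @return A nested configuration list (class `run_config`) that
#'   round-trips through YAML unchanged via [write_run_config()].
#' @export
default_config <- function(outdir = tempfile("psrun"), seed = 1L) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    outdir = outdir,
    genome = list(n_genes = 120L, n_chromosomes = 2L,
                  gene_length_range = c(500L, 3000L),
                  spacer_fraction = 0.2, n_nts = 2L),
    sga = list(n_negative = 8L, n_suppressor = 5L, n_common = 4L,
               n_masked = 5L,
               replicates = 3L, baseline_size = 400, noise_cv = 0.05,
               alpha = 0.05, central_band = c(0.25, 0.75)),
    rnaseq = list(conditions = c("wt", "mut"), depth = 30000L,
                  n_de = 10L, de_fold = 4, n_bias = 5L, bias_shift = 3,
                  fragment_length = 200L, mapq_min = 5L),
    de = list(fdr = 0.05, fc_min = 1.5, min_reads = 5L, bin_width = 175L),
    metagene = list(head_frac = 0.25, tail_frac = 0.25, bias_cutoff = 2)),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return The reader returns the `run_config`; the writer returns `path`
#'   invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

stage_seed <- function(config, k) (config$seed * 101L + k) %% 2147483647L

#' Run the full screening-and-transcriptomics pipeline on simulated data
#'
#' Executes, in dependency order: genome simulation; SGA truth, plate
#' simulation, fitness scoring, per-screen threshold estimation,
#' interaction calling, and the unique/common/masked partition; fragment
#' simulation for both conditions, alignment filtering, gene/bin
#' quantification, gene- and bin-level differential expression, region
#' calls, and metagene bias scoring. All artifacts are written under
#' `config$outdir` and listed, with MD5 checksums, in the returned report;
#' identical configurations (including seeds) give identical checksums.
#' Because the inputs are simulated, the report also carries a
#' truth-recovery summary (confusion counts for interaction calls,
#' differential genes, and bias classification).
#'
#' @param config A `run_config` from [default_config()] /
#'   [read_run_config()], or a path to a YAML configuration.
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(!is.null(config$outdir), !is.null(config$seed))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  files <- character()

  # --- stage 1: genome -----------------------------------------------------
  g <- config$genome
  genome <- simulate_toy_genome(
    n_genes = g$n_genes, n_chromosomes = g$n_chromosomes,
    gene_length_range = g$gene_length_range,
    spacer_fraction = g$spacer_fraction, n_nts = g$n_nts,
    seed = stage_seed(config, 1L))
  files["genome_gff3"] <- write_genome_gff3(genome, out("genome.gff3"))
  files["genome_bed"] <- write_genome_bed(genome, out("genome.bed"))

  # --- stage 2: SGA screen -------------------------------------------------
  s <- config$sga
  sga_truth <- simulate_sga_truth(
    genome$genes$gene, n_negative = s$n_negative,
    n_suppressor = s$n_suppressor,
    n_common = if (is.null(s$n_common)) 0L else s$n_common,
    n_masked = s$n_masked,
    seed = stage_seed(config, 2L))
  plates <- simulate_sga_plates(
    sga_truth, replicates = s$replicates, baseline_size = s$baseline_size,
    noise_cv = s$noise_cv, seed = stage_seed(config, 3L))
  files["colonies"] <- write_colony_tsv(plates$colonies, out("colonies.tsv"))
  files["sga_truth"] <- write_truth_json(sga_truth, out("sga_truth.json"))

  ratios <- compute_fitness_ratios(plates$colonies)
  screens <- attr(sga_truth, "screens")
  thresholds <- lapply(stats::setNames(screens, screens), function(scr) {
    estimate_thresholds(
      ratios$summary$mean_ratio[ratios$summary$screen == scr],
      central_band = s$central_band)
  })
  calls <- call_interactions(ratios, thresholds, alpha = s$alpha,
                             required_reps = s$replicates)
  files["sga_ratios"] <- out("sga_ratios.tsv")
  utils::write.table(ratios$summary, files["sga_ratios"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["sga_calls"] <- out("sga_calls.tsv")
  utils::write.table(calls, files["sga_calls"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hits <- function(scr, sg) calls$gene[calls$screen == scr & calls$sign == sg]
  partition <- classify_paralog_interactors(
    hits(screens[1], "negative"), hits(screens[2], "negative"),
    hits(screens[3], "negative"))
  files["partition"] <- out("partition.json")
  jsonlite::write_json(unclass(partition), files["partition"])

  # --- stage 3: RNA-seq ----------------------------------------------------
  r <- config$rnaseq
  tx_truth <- simulate_transcriptome_truth(
    genome, conditions = r$conditions, n_de = r$n_de, de_fold = r$de_fold,
    n_bias = r$n_bias, bias_shift = r$bias_shift,
    seed = stage_seed(config, 4L))
  files["tx_truth"] <- write_truth_json(tx_truth, out("tx_truth.json"))
  params <- de_params(fdr = config$de$fdr, fc_min = config$de$fc_min,
                      min_reads = config$de$min_reads,
                      bin_width = config$de$bin_width)
  frags <- counts <- rpkm <- bins <- list()
  for (i in seq_along(r$conditions)) {
    cond <- r$conditions[i]
    f <- simulate_fragments(genome, tx_truth, cond, depth = r$depth,
                            fragment_length = r$fragment_length,
                            seed = stage_seed(config, 4L + i))
    files[paste0("fragments_", cond)] <-
      write_fragments_tsv(f, out(sprintf("fragments_%s.tsv", cond)))
    f <- filter_alignments(f, mapq_min = r$mapq_min)
    frags[[cond]] <- f
    counts[[cond]] <- count_gene_reads(f, genome)
    rpkm[[cond]] <- compute_rpkm(counts[[cond]],
                                 genome$genes$length, sum(counts[[cond]]))
    bins[[cond]] <- count_bins(f, genome, bin_width = params$bin_width)
    ct <- data.frame(gene = names(counts[[cond]]),
                     count = as.integer(counts[[cond]]),
                     rpkm = as.numeric(rpkm[[cond]]))
    files[paste0("counts_", cond)] <- out(sprintf("counts_%s.tsv", cond))
    utils::write.table(ct, files[paste0("counts_", cond)], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- stage 4: differential expression ------------------------------------
  c1 <- r$conditions[1]; c2 <- r$conditions[2]
  de_genes <- call_de_genes(counts[[c1]], counts[[c2]],
                            gene_lengths = stats::setNames(
                              genome$genes$length, genome$genes$gene),
                            params = params)
  de_bins <- call_de_bins(bins[[c1]], bins[[c2]], params = params)
  regions <- map_bins_to_regions(de_bins, genome)
  files["de_genes"] <- out("de_genes.tsv")
  utils::write.table(de_genes, files["de_genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["de_regions"] <- out("de_regions.tsv")
  utils::write.table(regions, files["de_regions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- stage 5: metagene ---------------------------------------------------
  m <- config$metagene
  mg <- metagene_scores(frags[[c2]], genome,
                        head_frac = m$head_frac, tail_frac = m$tail_frac,
                        bias_cutoff = m$bias_cutoff)
  files["bias_scores"] <- out("bias_scores.tsv")
  utils::write.table(mg$scores, files["bias_scores"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- report --------------------------------------------------------------
  report <- list(
    package = as.character(utils::packageVersion("paralogscreen")),
    config = unclass(config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    names(files))),
    recovery = list(
      sga = sga_recovery(calls, sga_truth),
      de = de_recovery(de_genes, tx_truth),
      bias = bias_recovery(mg$scores, tx_truth)))
  files["report"] <- out("report.json")
  jsonlite::write_json(report, files["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

# Confusion summary of interaction calls against planted truth.
sga_recovery <- function(calls, truth) {
  truth_hit <- truth[truth$class != "none", , drop = FALSE]
  tkey <- paste(truth_hit$gene, truth_hit$screen, truth_hit$class)
  ckey <- paste(calls$gene, calls$screen, calls$sign)
  n_truth <- length(tkey)
  tp <- sum(ckey %in% tkey)
  list(n_truth = n_truth, n_called = length(ckey), tp = tp,
       fp = length(ckey) - tp, fn = n_truth - tp,
       sensitivity = if (n_truth) tp / n_truth else NA)
}

# Confusion summary of gene-level DE calls against planted truth.
de_recovery <- function(de_genes, truth) {
  planted <- truth$genes$gene[truth$genes$fold_change > 1]
  called <- de_genes$feature[de_genes$pass]
  tp <- sum(called %in% planted)
  list(n_truth = length(planted), n_called = length(called), tp = tp,
       fp = length(called) - tp,
       sensitivity = if (length(planted)) tp / length(planted) else NA,
       fdp = if (length(called)) (length(called) - tp) / length(called)
             else 0)
}

# Confusion summary of 5'-bias classification against planted truth.
bias_recovery <- function(scores, truth) {
  planted <- truth$genes$gene[truth$genes$bias > 0]
  sc <- scores[!is.na(scores$biased), , drop = FALSE]
  called <- sc$gene[sc$biased]
  tp <- sum(called %in% planted)
  neg <- setdiff(sc$gene, planted)
  list(n_truth = length(planted), n_called = length(called), tp = tp,
       sensitivity = if (length(planted)) tp / length(planted) else NA,
       fpr = if (length(neg)) sum(!called %in% planted) / length(neg)
             else 0)
}
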