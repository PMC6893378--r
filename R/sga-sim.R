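#' Simulate triplicate colony-array screens with planted interactions
#'
#' Emulates a dual-query SGA experiment: a control screen (total haploid
#' meiotic progeny) and three selection screens (the two single paralog
#' deletions and the double deletion), each pinned in `replicates` copies.
#' Colony pixel areas are drawn with multiplicative lognormal noise of the
#' stated coefficient of variation; a mutant colony's expected size is the
#' control expectation times that gene's effect multiplier in that screen,
#' so masked interactors perturb only the double-deletion screen.
#'
#' @param truth An `sga_truth` from [simulate_sga_truth()].
#' @param genes Optional gene layout; defaults to the genes in `truth`. An
#'   error is raised if `truth` references genes absent from this layout.
#' @param plate_nrow,plate_ncol Colony grid per plate (default 16 x 24, a
#'   384-format array).
#' @param replicates Number of replicate pinnings per screen (>= 1).
#' @param baseline_size Expected control colony pixel area.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   colony noise (>= 0; 0 gives deterministic sizes).
#' @param seed Integer seed.
#'
#' @return List with `colonies` -- a data frame in the colony-table layout
#'   (`plate`, `row`, `col`, `gene`, `replicate`, `screen`, `size`) covering
#'   the control screen and all three selection screens -- and `truth`, the
#'   input truth echoed unchanged.
#' @examples
#' tr <- simulate_sga_truth(sprintf("g%03d", 1:60), n_negative = 3,
#'                          n_suppressor = 2, n_masked = 2, seed = 7)
#' sim <- simulate_sga_plates(tr, noise_cv = 0, seed = 7)
#' head(sim$colonies)
#' @export
simulate_sga_plates <- function(truth,
                                genes = NULL,
                                plate_nrow = 16L,
                                plate_ncol = 24L,
                                replicates = 3L,
                                baseline_size = 400,
                                noise_cv = 0.05,
                                seed = 1L) {
  stopifnot(inherits(truth, "sga_truth"))
  if (replicates < 1L) stop_ps("`replicates` must be >= 1")
  check_scalar_num(noise_cv, "noise_cv", 0)
  truth_genes <- unique(truth$gene)
  if (is.null(genes)) genes <- truth_genes
  if (!all(truth_genes %in% genes)) {
    stop_ps("truth references genes absent from the array layout")
  }
  screens <- attr(truth, "screens")
  n <- length(genes)
  per_plate <- plate_nrow * plate_ncol
  pos <- data.frame(
    gene = genes,
    plate = (seq_len(n) - 1L) %/% per_plate + 1L,
    row = ((seq_len(n) - 1L) %% per_plate) %/% plate_ncol + 1L,
    col = (seq_len(n) - 1L) %% plate_ncol + 1L,
    stringsAsFactors = FALSE)

  mult <- matrix(1, nrow = n, ncol = length(screens) + 1L,
                 dimnames = list(genes, c("control", screens)))
  for (scr in screens) {
    rows <- truth$screen == scr
    mult[truth$gene[rows], scr] <- truth$multiplier[rows]
  }

  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    out <- vector("list", (length(screens) + 1L) * replicates)
    k <- 0L
    for (scr in colnames(mult)) {
      for (rep_i in seq_len(replicates)) {
        expct <- baseline_size * mult[, scr]
        size <- if (noise_cv == 0) expct else
          expct * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        k <- k + 1L
        out[[k]] <- data.frame(
          plate = pos$plate, row = pos$row, col = pos$col, gene = pos$gene,
          replicate = rep_i, screen = scr, size = size,
          stringsAsFactors = FALSE)
      }
    }
    list(colonies = do.call(rbind, out), truth = truth)
  })
}
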