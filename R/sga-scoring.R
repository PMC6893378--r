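# Colony-array fitness scoring: plate normalization, mutant/control ratio
# computation, data-driven hit thresholds, interaction calls, and the
# unique/common/masked partition of paralog interactors.

#' Normalize colony sizes to the plate median
#'
#' @param sizes Pixel areas for one physical plate (one screen x replicate).
#' @return `sizes / median(sizes)`; the median of the output is 1.
#' @examples
#' normalize_plate(c(2, 4, 6, 8, 10))
#' @export
normalize_plate <- function(sizes) {
  if (!length(sizes) || !any(sizes > 0)) {
    stop_ps("cannot normalize a plate whose colony sizes are all zero")
  }
  m <- stats::median(sizes)
  if (m == 0) stop_ps("plate median colony size is zero; cannot normalize")
  sizes / m
}

#' Compute mutant/control fitness ratios per gene and screen
#'
#' Colony sizes are first normalized to the median of their own physical
#' plate (each screen x plate x replicate pinning). Each mutant colony is
#' then divided by the control-screen colony at the same array position and
#' replicate, giving one fitness ratio per replicate; the reported mean
#' ratio is the arithmetic mean over replicates. A Welch two-sample t-test
#' (two-sided) between the replicate mutant and matched control normalized
#' sizes supplies the hit P-value. Replicates whose control size is zero are
#' flagged unusable, and a gene is dropped from a screen (with a logged
#' reason) if fewer than the full replicate set remains.
#'
#' @param colonies Colony table (`plate`, `row`, `col`, `gene`, `replicate`,
#'   `screen`, `size`) containing the control screen and at least one
#'   selection screen.
#' @param control_screen Label of the control screen.
#' @param normalize Normalize to plate medians first (default TRUE; set
#'   FALSE if sizes are already normalized).
#'
#' @return Object of class `fitness_ratios`: list with
#'   `summary` (`gene`, `screen`, `n_reps`, `mean_ratio`, `pvalue`),
#'   `replicates` (per-replicate `ratio`, `mut_norm`, `ctrl_norm`), and
#'   `dropped` (`gene`, `screen`, `reason`).
#' @export
compute_fitness_ratios <- function(colonies, control_screen = "control",
                                   normalize = TRUE) {
  need <- c("plate", "row", "col", "gene", "replicate", "screen", "size")
  if (!all(need %in% names(colonies))) {
    stop_ps("colony table must have columns: ", paste(need, collapse = ", "))
  }
  if (!control_screen %in% colonies$screen) {
    stop_ps("control screen '", control_screen, "' not present")
  }
  df <- colonies
  if (normalize) {
    key <- interaction(df$screen, df$plate, df$replicate, drop = TRUE)
    df$norm <- stats::ave(df$size, key, FUN = normalize_plate)
  } else {
    df$norm <- df$size
  }
  ctl <- df[df$screen == control_screen, ]
  mut <- df[df$screen != control_screen, ]
  pos_key <- function(d) paste(d$plate, d$row, d$col, d$replicate, sep = "\r")
  ctl_norm <- stats::setNames(ctl$norm, pos_key(ctl))
  mut$ctrl_norm <- ctl_norm[pos_key(mut)]
  if (anyNA(mut$ctrl_norm)) {
    stop_ps("some mutant colonies have no matched control colony")
  }
  mut$usable <- mut$ctrl_norm > 0
  mut$ratio <- ifelse(mut$usable, mut$norm / mut$ctrl_norm, NA_real_)

  n_reps <- max(colonies$replicate)
  split_key <- paste(mut$gene, mut$screen, sep = "\r")
  pieces <- split(mut, split_key)
  summ <- vector("list", length(pieces))
  keep <- rep(TRUE, length(pieces))
  drop <- list()
  for (i in seq_along(pieces)) {
    d <- pieces[[i]]
    ok <- d[d$usable, , drop = FALSE]
    if (nrow(ok) < n_reps) {
      drop[[length(drop) + 1L]] <- data.frame(
        gene = d$gene[1], screen = d$screen[1],
        reason = "control colony size zero in >=1 replicate",
        stringsAsFactors = FALSE)
      keep[i] <- FALSE
      next
    }
    summ[[i]] <- data.frame(
      gene = d$gene[1], screen = d$screen[1], n_reps = nrow(ok),
      mean_ratio = mean(ok$ratio),
      pvalue = welch_p(ok$norm, ok$ctrl_norm),
      stringsAsFactors = FALSE)
  }
  if (any(keep)) {
    summary <- do.call(rbind, summ[keep])
    reps <- do.call(rbind, pieces[keep])
    reps <- reps[, c("gene", "screen", "replicate", "ratio", "norm",
                     "ctrl_norm")]
    names(reps)[5] <- "mut_norm"
    rownames(summary) <- rownames(reps) <- NULL
  } else {
    summary <- data.frame(gene = character(), screen = character(),
                          n_reps = integer(), mean_ratio = numeric(),
                          pvalue = numeric(), stringsAsFactors = FALSE)
    reps <- data.frame(gene = character(), screen = character(),
                       replicate = integer(), ratio = numeric(),
                       mut_norm = numeric(), ctrl_norm = numeric(),
                       stringsAsFactors = FALSE)
  }
  dropped <- if (length(drop)) do.call(rbind, drop) else
    data.frame(gene = character(), screen = character(), reason = character())
  structure(list(summary = summary, replicates = reps, dropped = dropped),
            class = "fitness_ratios")
}

#' Estimate hit thresholds from the fitness-ratio distribution
#'
#' Sorts the mean ratios, maps ranks onto `[0, 1]`, fits ordinary least
#' squares to the central linear band of the empirical distribution (ranks
#' within `central_band`), and extrapolates the fitted line to the two ends
#' of the rank axis: the intercept at rank 0 is the lower cutoff and the
#' fitted value at rank 1 the upper cutoff. Because the fit is on sorted
#' data its slope is non-negative, so lower <= upper always holds. Interactor
#' tails of up to the excluded rank mass on each side do not move the fit.
#'
#' @param mean_ratios Positive fitness ratios, at least 20 of them (below
#'   that, supply thresholds manually to [call_interactions()]).
#' @param central_band Rank interval used for the fit (default
#'   `c(0.25, 0.75)`).
#' @return Object of class `threshold_pair`: list with `lower`, `upper` and
#'   the fitted `slope`/`intercept`.
#' @examples
#' estimate_thresholds(seq(0.5, 1.5, length.out = 101))
#' @export
estimate_thresholds <- function(mean_ratios, central_band = c(0.25, 0.75)) {
  r <- mean_ratios[is.finite(mean_ratios)]
  n <- length(r)
  if (n < 20L) {
    stop_ps("need >= 20 ratios to estimate thresholds; supply them manually")
  }
  y <- sort(r)
  x <- (seq_len(n) - 1) / (n - 1)
  keep <- x >= central_band[1] & x <= central_band[2]
  if (stats::var(y[keep]) == 0) {
    # constant core: degenerate fit, both cutoffs at the common value
    lower <- upper <- y[keep][1]
    slope <- 0; intercept <- lower
  } else {
    fit <- stats::lm(y ~ x, subset = keep)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
    lower <- intercept
    upper <- intercept + slope
  }
  structure(list(lower = lower, upper = upper, slope = slope,
                 intercept = intercept), class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("threshold_pair: lower = %.4f, upper = %.4f\n", x$lower, x$upper))
  invisible(x)
}

#' Call negative and suppressor genetic interactions
#'
#' A gene is a negative interactor in a screen iff all of its replicate
#' ratios fall below the lower cutoff, and a suppressor iff all fall above
#' the upper cutoff; in both cases the Welch t-test P-value (mutant vs
#' matched control normalized sizes) must be below `alpha`. This mirrors the
#' replicate-reproducibility hit rule (all-of-R sets and P < 0.05).
#'
#' @param ratios A `fitness_ratios` object.
#' @param thresholds A `threshold_pair`, or a named list of them keyed by
#'   screen label for per-screen thresholds.
#' @param alpha Significance level (default 0.05).
#' @param required_reps Replicates that must agree (default 3); an error is
#'   raised if a gene carries fewer.
#' @return Data frame of calls: `gene`, `screen`, `sign`
#'   (`"negative"`/`"suppressor"`), `mean_ratio`, `pvalue`.
#' @export
call_interactions <- function(ratios, thresholds, alpha = 0.05,
                              required_reps = 3L) {
  stopifnot(inherits(ratios, "fitness_ratios"))
  thr_for <- function(scr) {
    t <- if (inherits(thresholds, "threshold_pair")) thresholds
         else thresholds[[scr]]
    if (is.null(t)) stop_ps("no thresholds for screen '", scr, "'")
    t
  }
  reps <- ratios$replicates
  key <- paste(reps$gene, reps$screen, sep = "\r")
  rlist <- split(reps$ratio, key)
  out <- list()
  for (i in seq_len(nrow(ratios$summary))) {
    s <- ratios$summary[i, ]
    rr <- rlist[[paste(s$gene, s$screen, sep = "\r")]]
    if (length(rr) < required_reps) {
      stop_ps("gene ", s$gene, " has fewer than required_reps replicates")
    }
    t <- thr_for(s$screen)
    sign <- if (all(rr < t$lower)) "negative"
            else if (all(rr > t$upper)) "suppressor"
            else NA_character_
    if (!is.na(sign) && !is.na(s$pvalue) && s$pvalue < alpha) {
      out[[length(out) + 1L]] <- data.frame(
        gene = s$gene, screen = s$screen, sign = sign,
        mean_ratio = s$mean_ratio, pvalue = s$pvalue,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), screen = character(),
                      sign = character(), mean_ratio = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partition paralog interactors into unique, common, and masked sets
#'
#' Deduplicates each hit list (gene identity is the systematic ORF name,
#' case-insensitive, first spelling kept), then partitions: genes hit only in
#' screen A, only in screen B, in both, and genes hit only in the double
#' deletion screen -- the masked interactors, invisible to either single
#' query. Applied identically to negative and suppressor hit lists.
#'
#' @param hits_A,hits_B Hit lists from the two single-query screens.
#' @param hits_AB Hit list from the double-deletion screen.
#' @return Object of class `paralog_partition`: list of character vectors
#'   `unique_A`, `unique_B`, `common`, `masked` (pairwise disjoint).
#' @examples
#' classify_paralog_interactors(c("g1"), character(), c("g1", "g2"))
#' @export
classify_paralog_interactors <- function(hits_A, hits_B, hits_AB) {
  dedup <- function(x) {
    x <- as.character(x)
    x[!duplicated(toupper(x))]
  }
  A <- dedup(hits_A); B <- dedup(hits_B); AB <- dedup(hits_AB)
  ua <- toupper(A); ub <- toupper(B); uab <- toupper(AB)
  structure(list(
    unique_A = A[!ua %in% ub],
    unique_B = B[!ub %in% ua],
    common = A[ua %in% ub],
    masked = AB[!uab %in% c(ua, ub)]), class = "paralog_partition")
}

#' @export
print.paralog_partition <- function(x, ...) {
  cat(sprintf(
    "paralog_partition: unique_A=%d unique_B=%d common=%d masked=%d\n",
    length(x$unique_A), length(x$unique_B), length(x$common),
    length(x$masked)))
  invisible(x)
}
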