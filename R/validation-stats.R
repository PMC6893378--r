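# Validation statistics: delta-delta-Ct qPCR fold changes, hypergeometric
# category enrichment, and reporter-propagation retention analysis.

#' Construct a qPCR Ct record
#'
#' @param sample Condition/sample label.
#' @param target Target gene name.
#' @param ct Target Ct value.
#' @param normalizers Ct values of the housekeeping normalizer genes
#'   (e.g. TCM1 and GPD1); their mean is the normalization reference.
#' @return List of class `ct_record`.
#' @export
ct_record <- function(sample, target, ct, normalizers) {
  if (!length(normalizers) || anyNA(normalizers)) {
    stop_ps("normalizer Ct values are missing")
  }
  if (!is.finite(ct)) stop_ps("target Ct must be finite")
  structure(list(sample = sample, target = target, ct = ct,
                 normalizers = as.numeric(normalizers)),
            class = "ct_record")
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' Per condition, `dCt = Ct_target - mean(normalizer Cts)`; the fold change
#' of the experimental condition relative to the reference is
#' `base^-(dCt_exp - dCt_ref)` (default base 2).
#'
#' @param target_ct `ct_record` for the experimental condition.
#' @param reference_ct `ct_record` for the reference condition (same target
#'   gene).
#' @param base Amplification base (default 2).
#' @return Fold change (positive real).
#' @examples
#' exp <- ct_record("mut", "PHO5", 20, c(22, 22))
#' ref <- ct_record("wt", "PHO5", 24, c(22, 22))
#' qpcr_fold_change(exp, ref)  # 16
#' @export
qpcr_fold_change <- function(target_ct, reference_ct, base = 2) {
  stopifnot(inherits(target_ct, "ct_record"),
            inherits(reference_ct, "ct_record"))
  if (!identical(target_ct$target, reference_ct$target)) {
    stop_ps("records must be for the same target gene")
  }
  d_exp <- target_ct$ct - mean(target_ct$normalizers)
  d_ref <- reference_ct$ct - mean(reference_ct$normalizers)
  base^-(d_exp - d_ref)
}

#' Hypergeometric category enrichment of a gene set
#'
#' For each category, the P-value is the upper-tail hypergeometric
#' probability of drawing at least the observed number of category members
#' in a query of the observed size from the universe (one-sided
#' over-representation test). A category is enriched iff P < alpha, or
#' P < alpha / m with Bonferroni correction over the m categories tested.
#'
#' @param query Query gene set (must be contained in `universe`).
#' @param categories Named list of category gene sets; genes outside the
#'   universe are ignored.
#' @param universe Universe gene set.
#' @param alpha Significance cutoff (e.g. 0.01 for interactor sets, 0.001
#'   for differential-expression sets).
#' @param bonferroni Divide alpha by the number of categories tested.
#' @return Data frame: `category`, `size`, `overlap`, `p`, `enriched`.
#' @export
hypergeometric_enrichment <- function(query, categories, universe,
                                      alpha = 0.01, bonferroni = FALSE) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    stop_ps("query contains genes outside the universe")
  }
  m <- length(categories)
  cutoff <- if (bonferroni) alpha / m else alpha
  rows <- lapply(names(categories), function(nm) {
    cat_set <- intersect(unique(as.character(categories[[nm]])), universe)
    K <- length(cat_set)
    k <- length(intersect(query, cat_set))
    p <- stats::phyper(k - 1, K, length(universe) - K, length(query),
                       lower.tail = FALSE)
    data.frame(category = nm, size = K, overlap = k, p = p,
               enriched = p < cutoff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct reporter-propagation counts
#'
#' @param strain Strain label.
#' @param n_picked Colonies picked (> 0).
#' @param n_retained Colonies that retained the reporter (grew on medium
#'   lacking uracil).
#' @return List of class `propagation_counts` with `n_lost` filled in.
#' @export
propagation_counts <- function(strain, n_picked, n_retained) {
  if (n_picked <= 0) stop_ps("`n_picked` must be > 0")
  if (n_retained < 0 || n_retained > n_picked) {
    stop_ps("`n_retained` must be between 0 and `n_picked`")
  }
  structure(list(strain = strain, n_picked = as.integer(n_picked),
                 n_retained = as.integer(n_retained),
                 n_lost = as.integer(n_picked - n_retained)),
            class = "propagation_counts")
}

#' Compare reporter retention between two strains
#'
#' Retention fraction per strain with an exact (Clopper-Pearson) binomial
#' 95\% confidence interval, and a two-sided Fisher exact test on the 2x2
#' retained/lost table comparing the strains.
#'
#' @param countsA,countsB `propagation_counts` for the two strains.
#' @param conf_level Confidence level for the binomial intervals.
#' @return List with `strains` (data frame: `strain`, `n_picked`,
#'   `n_retained`, `fraction`, `ci_lower`, `ci_upper`) and `fisher_p`.
#' @export
propagation_analysis <- function(countsA, countsB, conf_level = 0.95) {
  stopifnot(inherits(countsA, "propagation_counts"),
            inherits(countsB, "propagation_counts"))
  one <- function(x) {
    bt <- stats::binom.test(x$n_retained, x$n_picked,
                            conf.level = conf_level)
    data.frame(strain = x$strain, n_picked = x$n_picked,
               n_retained = x$n_retained,
               fraction = x$n_retained / x$n_picked,
               ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2],
               stringsAsFactors = FALSE)
  }
  tab <- matrix(c(countsA$n_retained, countsA$n_lost,
                  countsB$n_retained, countsB$n_lost), nrow = 2)
  list(strains = rbind(one(countsA), one(countsB)),
       fisher_p = stats::fisher.test(tab)$p.value)
}
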