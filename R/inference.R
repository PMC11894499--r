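#' Permutation significance for a cross-validated CPM
#'
#' Builds a null distribution of the median cross-validated Spearman rho by
#' shuffling the correspondence between the behavior vector and the
#' connectivity matrices `n_perm` times and rerunning the full CPM
#' (selection + repeated CV) for each shuffle. Covariates stay aligned with
#' the connectomes; only the behavior labels move. Because only a positive
#' association between predicted and observed scores indicates prediction
#' above chance, the p-value is one-tailed, with the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' Each shuffle uses `perm_repeats` CV repeats (default 10) rather than the
#' full observed repeat count, which keeps 1000-shuffle runs tractable; the
#' observed statistic always uses the full `repeats`.
#'
#' @inheritParams run_cv
#' @param n_perm Number of label shuffles (default 1000).
#' @param perm_repeats CV repeats per shuffle (default 10).
#' @return Object of class `cpm_permutation`: `observed` (median rho),
#'   `null_rhos`, `p_one_tailed`, `n_perm`, `seed`, and the observed
#'   [run_cv()] object as `observed_run`.
#' @export
permutation_test <- function(edges, y, X = NULL, k = 10L, repeats = 100L,
                             alpha = 0.05,
                             variant = c("combined", "positive", "negative"),
                             n_perm = 1000L, perm_repeats = 10L, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(n_perm >= 1L, perm_repeats >= 1L)
  observed_run <- run_cv(edges, y, X, k = k, repeats = repeats, alpha = alpha,
                         variant = variant, seed = seed)
  observed <- cv_score(observed_run)
  n <- length(y)
  null_rhos <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + b)
    perm <- sample.int(n)
    run_b <- run_cv(edges, y[perm], X, k = k, repeats = perm_repeats,
                    alpha = alpha, variant = variant, seed = seed + b)
    null_rhos[b] <- cv_score(run_b)
  }
  p <- (1 + sum(null_rhos >= observed)) / (n_perm + 1)
  structure(
    list(observed = observed, null_rhos = null_rhos, p_one_tailed = p,
         n_perm = as.integer(n_perm), perm_repeats = as.integer(perm_repeats),
         seed = seed, observed_run = observed_run),
    class = "cpm_permutation"
  )
}

#' @export
print.cpm_permutation <- function(x, ...) {
  cat(sprintf("<cpm_permutation> observed median rho = %.3f, %d shuffles, one-tailed p = %.4g\n",
              x$observed, x$n_perm, x$p_one_tailed))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR-adjusted p-values, capped at 1. Applied across the four
#' symptom-cluster models within a timepoint.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fit per-symptom-cluster CPM models with FDR correction
#'
#' Runs one permutation-tested CPM per symptom cluster (DSM-5 criteria B:
#' intrusion, C: avoidance, D: negative mood/cognition, E: hyperarousal)
#' against the same edge table and covariates, then adjusts the four
#' one-tailed permutation p-values by Benjamini-Hochberg FDR.
#'
#' @param edges n x E edge matrix (modeled subjects only).
#' @param cluster_scores n x 4 matrix or data.frame of cluster scores with
#'   columns named B, C, D, E (any order; matched by name).
#' @param X Optional covariate matrix.
#' @inheritParams permutation_test
#' @return data.frame with one row per cluster: `cluster`, `median_rho`,
#'   `p_raw`, `p_fdr`.
#' @export
cluster_models <- function(edges, cluster_scores, X = NULL, k = 10L,
                           repeats = 100L, alpha = 0.05, n_perm = 1000L,
                           perm_repeats = 10L, seed = 1L,
                           variant = c("combined", "positive", "negative")) {
  variant <- match.arg(variant)
  cluster_scores <- as.data.frame(cluster_scores)
  labels <- c("B", "C", "D", "E")
  if (!all(labels %in% names(cluster_scores))) {
    stop("`cluster_scores` must have columns B, C, D, E", call. = FALSE)
  }
  rows <- lapply(seq_along(labels), function(ci) {
    pt <- permutation_test(edges, cluster_scores[[labels[ci]]], X, k = k,
                           repeats = repeats, alpha = alpha, variant = variant,
                           n_perm = n_perm, perm_repeats = perm_repeats,
                           seed = seed + 10000L * ci)
    data.frame(cluster = labels[ci], median_rho = pt$observed,
               p_raw = pt$p_one_tailed)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p_raw)
  out
}
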