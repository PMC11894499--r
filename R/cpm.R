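#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive the mean of the ranks
#' they span). Used to score out-of-fold CPM predictions against observed
#' scores.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Confound-controlled partial correlation of every edge with behavior
#'
#' For each edge (column of `edges`), computes the partial Pearson
#' correlation with `y` given the covariates `X`: both edge and behavior are
#' residualized on `[1, X]` and the residuals correlated. Two-tailed
#' p-values come from the t distribution with `n - 2 - ncol(X)` degrees of
#' freedom. With no covariates this reduces to the plain Pearson
#' correlation.
#'
#' @param edges n x E numeric matrix, one row per subject, one column per
#'   edge (canonical order, see [edge_pairs()]).
#' @param y Behavior vector of length n (e.g. CAPS-5 total score).
#' @param X Optional n x c covariate matrix (age, sex, head motion,
#'   baseline severity, ...). `NULL` or zero columns means no confound
#'   control.
#' @return List with numeric vectors `r_partial` and `p` of length E.
#' @export
partial_corr_edges <- function(edges, y, X = NULL) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  if (length(y) != n) stop("`y` must have one value per row of `edges`", call. = FALSE)
  if (anyNA(y) || anyNA(edges)) stop("missing values not allowed", call. = FALSE)
  if (sd(y) == 0) stop("behavior vector is constant", call. = FALSE)
  X <- normalize_covariates(X, n)
  c_ <- ncol(X)
  if (n < c_ + 4L) {
    stop(sprintf("need at least %d subjects for %d covariate(s)", c_ + 4L, c_),
         call. = FALSE)
  }
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])
    nms <- c("(intercept)", colnames(X) %||% paste0("cov_", seq_len(c_)))
    stop(sprintf("covariate matrix is rank deficient; collinear column(s): %s",
                 paste(nms[drop_cols], collapse = ", ")), call. = FALSE)
  }
  ry <- qr.resid(qrD, y)
  re <- qr.resid(qrD, edges)
  ss_e <- colSums(re^2)
  ss_y <- sum(ry^2)
  num <- drop(crossprod(re, ry))
  r <- ifelse(ss_e > 1e-12, num / sqrt(ss_e * ss_y), 0)
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2L - c_
  p <- ifelse(abs(r) < 1, 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df), 0)
  list(r_partial = r, p = p, df = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_covariates <- function(X, n) {
  if (is.null(X)) return(matrix(numeric(0), n, 0))
  X <- as.matrix(X)
  if (length(X) == 0L) return(matrix(numeric(0), n, 0))
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("covariate matrix has wrong number of rows", call. = FALSE)
  if (anyNA(X)) stop("covariates contain missing values", call. = FALSE)
  X
}

#' Select edges associated with behavior at a p-value threshold
#'
#' Partitions edges into a positive mask (`r > 0 & p < alpha`) and a
#' negative mask (`r < 0 & p < alpha`); the two masks never intersect.
#'
#' @param r_partial,p Vectors from [partial_corr_edges()].
#' @param alpha Selection threshold (default 0.05).
#' @return Object of class `edge_selection`: `r_partial`, `p`, `pos_mask`,
#'   `neg_mask` (logical), `alpha`, and the two mask counts.
#' @export
select_edges <- function(r_partial, p, alpha = 0.05) {
  if (length(r_partial) != length(p)) {
    stop("`r_partial` and `p` must have the same length", call. = FALSE)
  }
  pos <- r_partial > 0 & p < alpha
  neg <- r_partial < 0 & p < alpha
  structure(
    list(r_partial = r_partial, p = p, pos_mask = pos, neg_mask = neg,
         alpha = alpha, n_pos = sum(pos), n_neg = sum(neg)),
    class = "edge_selection"
  )
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf("<edge_selection> %d edges, alpha = %g: %d positive, %d negative\n",
              length(x$p), x$alpha, x$n_pos, x$n_neg))
  invisible(x)
}

#' Summed selected edge strengths for one subject
#'
#' The standard CPM feature summary: the sum of Fisher-z values over the
#' positively selected edges and over the negatively selected edges. An
#' empty mask contributes 0.
#'
#' @param edge_row Numeric edge vector for one subject.
#' @param selection An [select_edges()] object.
#' @return Named numeric vector `c(pos_sum, neg_sum)`.
#' @export
summarize_features <- function(edge_row, selection) {
  if (length(edge_row) != length(selection$pos_mask)) {
    stop("edge vector length does not match selection", call. = FALSE)
  }
  c(pos_sum = sum(edge_row[selection$pos_mask]),
    neg_sum = sum(edge_row[selection$neg_mask]))
}

#' Fit a CPM model on a training set
#'
#' Runs edge selection on the training rows only, then ordinary least
#' squares of the training behavior on `[1, pos_sum, neg_sum]`. The default
#' model combines both features; when a mask is empty (or excluded by
#' `variant`) its column is dropped and the coefficient recorded as 0. With
#' no selected edges at all the model degrades to the training mean.
#'
#' @param train_edges n x E training edge matrix.
#' @param train_y Training behavior vector.
#' @param train_X Optional covariate matrix for partial-correlation
#'   selection; covariates are not used as prediction features.
#' @param alpha Edge-selection threshold.
#' @param variant `"combined"`, `"positive"`, or `"negative"`.
#' @return Object of class `cpm_fit` with `intercept`, `coef_pos`,
#'   `coef_neg`, `selection`, `variant`.
#' @export
fit_cpm <- function(train_edges, train_y, train_X = NULL, alpha = 0.05,
                    variant = c("combined", "positive", "negative")) {
  variant <- match.arg(variant)
  pc <- partial_corr_edges(train_edges, train_y, train_X)
  sel <- select_edges(pc$r_partial, pc$p, alpha)
  use_pos <- variant != "negative" && sel$n_pos > 0L
  use_neg <- variant != "positive" && sel$n_neg > 0L
  F_ <- cbind(intercept = rep(1, nrow(train_edges)))
  if (use_pos) F_ <- cbind(F_, pos_sum = drop(train_edges %*% sel$pos_mask))
  if (use_neg) F_ <- cbind(F_, neg_sum = drop(train_edges %*% sel$neg_mask))
  coefs <- qr.coef(qr(F_), train_y)
  coefs[is.na(coefs)] <- 0
  structure(
    list(intercept = unname(coefs["intercept"]),
         coef_pos = if (use_pos) unname(coefs["pos_sum"]) else 0,
         coef_neg = if (use_neg) unname(coefs["neg_sum"]) else 0,
         selection = sel, variant = variant),
    class = "cpm_fit"
  )
}

#' Predict behavior from edge data with a fitted CPM model
#'
#' @param object A [fit_cpm()] model.
#' @param newdata m x E edge matrix (or a single edge vector).
#' @param ... Unused.
#' @return Numeric vector of m predicted scores.
#' @export
predict.cpm_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  sel <- object$selection
  if (ncol(newdata) != length(sel$pos_mask)) {
    stop("edge matrix width does not match the fitted selection", call. = FALSE)
  }
  drop(object$intercept +
         object$coef_pos * (newdata %*% sel$pos_mask) +
         object$coef_neg * (newdata %*% sel$neg_mask))
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat(sprintf("<cpm_fit> variant %s: intercept %.4g, coef_pos %.4g (%d edges), coef_neg %.4g (%d edges)\n",
              x$variant, x$intercept, x$coef_pos, x$selection$n_pos,
              x$coef_neg, x$selection$n_neg))
  invisible(x)
}

#' Random fold assignments for repeated k-fold cross-validation
#'
#' Repeat `r` is seeded with `seed + r`, so any single repeat can be
#' regenerated in isolation. Fold sizes differ by at most one.
#'
#' @param n Number of subjects.
#' @param k Number of folds.
#' @param repeats Number of repeated random divisions.
#' @param seed Base integer seed.
#' @return n x repeats integer matrix of fold ids in `1..k`.
#' @export
make_folds <- function(n, k, repeats, seed) {
  folds <- matrix(0L, n, repeats)
  base_sizes <- rep(seq_len(k), length.out = n)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    folds[, r] <- sample(base_sizes)
  }
  folds
}

#' Repeated k-fold cross-validated CPM
#'
#' The full CPM loop: for each of `repeats` random divisions of the
#' subjects into `k` near-equal folds, each fold is predicted by a model
#' whose edge selection and regression coefficients are fit on the other
#' `k - 1` folds only; the Spearman correlation between out-of-fold
#' predictions and observed behavior is recorded per repeat.
#'
#' A training fold with constant behavior (or a collinear covariate design)
#' aborts that repeat with a warning; its rho is `NA`.
#'
#' @inheritParams partial_corr_edges
#' @param k Folds (default 10).
#' @param repeats Random repeated divisions (default 100).
#' @param alpha Edge-selection threshold.
#' @param variant Model form; see [fit_cpm()].
#' @param seed Integer seed; the run is reproducible from it.
#' @param folds Optional precomputed n x repeats fold matrix (used by the
#'   virtual lesion analysis to share identical divisions across runs).
#' @param backend `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation built from [fit_cpm()]); both produce the same numbers.
#' @return Object of class `cpm_cv`: `rho_per_repeat`, `predictions`
#'   (n x repeats out-of-fold), `fold_assignments`, `median_rho`,
#'   `selection_freq_pos`/`_neg` (per-edge selection counts over all
#'   `k * repeats` training fits), `k`, `repeats`, `seed`.
#' @export
run_cv <- function(edges, y, X = NULL, k = 10L, repeats = 100L, alpha = 0.05,
                   variant = c("combined", "positive", "negative"),
                   seed = 1L, folds = NULL, backend = c("cpp", "R")) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "double"
  n <- nrow(edges)
  if (length(y) != n) stop("`y` must have one value per subject", call. = FALSE)
  if (anyNA(y) || anyNA(edges)) stop("missing values not allowed; subset to modeled subjects first", call. = FALSE)
  if (n < 2L * k) {
    stop(sprintf("need at least %d subjects for %d-fold CV", 2L * k, k), call. = FALSE)
  }
  if (sd(y) == 0) stop("behavior vector is constant", call. = FALSE)
  X <- normalize_covariates(X, n)
  if (is.null(folds)) folds <- make_folds(n, k, repeats, seed)
  stopifnot(nrow(folds) == n, ncol(folds) == repeats)

  if (backend == "cpp") {
    res <- .cpm_cv_cpp(edges, as.numeric(y), X, folds, alpha,
                       match(variant, c("combined", "positive", "negative")) - 1L)
    if (res$n_degenerate > 0L) {
      warning(sprintf("%d repeat(s) aborted (constant training outcome or collinear design)",
                      res$n_degenerate), call. = FALSE)
    }
    rho <- drop(res$rho)
    preds <- res$predictions
    pos_count <- drop(res$pos_count)
    neg_count <- drop(res$neg_count)
  } else {
    preds <- matrix(NA_real_, n, repeats)
    rho <- rep(NA_real_, repeats)
    pos_count <- neg_count <- numeric(ncol(edges))
    for (r in seq_len(repeats)) {
      ok <- TRUE
      for (f in seq_len(k)) {
        tr <- folds[, r] != f
        if (sd(y[tr]) == 0) { ok <- FALSE; break }
        fit <- tryCatch(
          fit_cpm(edges[tr, , drop = FALSE], y[tr],
                  if (ncol(X)) X[tr, , drop = FALSE] else NULL,
                  alpha = alpha, variant = variant),
          error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        pos_count <- pos_count + fit$selection$pos_mask
        neg_count <- neg_count + fit$selection$neg_mask
        preds[!tr, r] <- predict(fit, edges[!tr, , drop = FALSE])
      }
      if (!ok) {
        warning(sprintf("repeat %d aborted (constant training outcome or collinear design)", r),
                call. = FALSE)
        preds[, r] <- NA_real_
        next
      }
      rho[r] <- if (sd(preds[, r]) == 0) 0 else spearman_rho(preds[, r], y)
    }
  }

  structure(
    list(k = as.integer(k), repeats = as.integer(repeats),
         fold_assignments = folds, predictions = preds,
         rho_per_repeat = rho, median_rho = median(rho, na.rm = TRUE),
         selection_freq_pos = pos_count, selection_freq_neg = neg_count,
         n_models = as.integer(k) * as.integer(repeats),
         alpha = alpha, variant = variant, seed = seed, n = n),
    class = "cpm_cv"
  )
}

#' Summary score of a cross-validation run
#'
#' The median Spearman rho across repeats (mean of the middle two for even
#' counts); aborted repeats (`NA`) are excluded.
#'
#' @param run A [run_cv()] result.
#' @return Median rho.
#' @export
cv_score <- function(run) {
  stopifnot(inherits(run, "cpm_cv"))
  if (all(is.na(run$rho_per_repeat))) stop("no completed repeats to score", call. = FALSE)
  median(run$rho_per_repeat, na.rm = TRUE)
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf("<cpm_cv> %d subjects, %d-fold x %d repeats (%s model): median rho = %.3f\n",
              x$n, x$k, x$repeats, x$variant, x$median_rho))
  invisible(x)
}

#' Edges selected in at least a given fraction of training fits
#'
#' Consensus predictive edges: an edge counts if it was selected (per sign)
#' in at least `threshold` of the `k * repeats` training models of a run.
#'
#' @param run A [run_cv()] result.
#' @param threshold Fraction in (0, 1]; 1 means selected in every fit.
#' @return List of logical vectors `pos` and `neg` and their counts.
#' @export
consensus_edges <- function(run, threshold = 1) {
  stopifnot(inherits(run, "cpm_cv"), threshold > 0, threshold <= 1)
  pos <- run$selection_freq_pos >= threshold * run$n_models
  neg <- run$selection_freq_neg >= threshold * run$n_models
  list(pos = pos, neg = neg, n_pos = sum(pos), n_neg = sum(neg),
       threshold = threshold)
}
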