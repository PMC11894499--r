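#' Construct a connectome object
#'
#' A `connectome` is a subject-level N x N matrix of Fisher-z transformed
#' pairwise correlations between node time series, with a zero diagonal by
#' convention. Off-diagonal values must be finite and the matrix symmetric.
#'
#' @param z N x N numeric matrix (symmetric, zero diagonal, finite).
#' @param subject_id Subject identifier.
#' @param node_ids Optional character vector of node identifiers (defaults
#'   to rownames of `z` or `node_1 ... node_N`).
#' @param n_scans_averaged Number of scans averaged into `z`.
#' @return An object of class `connectome`.
#' @export
new_connectome <- function(z, subject_id, node_ids = NULL, n_scans_averaged = 1L) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("`z` must be a square matrix", call. = FALSE)
  }
  n <- nrow(z)
  if (is.null(node_ids)) {
    node_ids <- if (!is.null(rownames(z))) rownames(z) else paste0("node_", seq_len(n))
  }
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop("`node_ids` must be unique and match the matrix dimension", call. = FALSE)
  }
  if (any(abs(diag(z)) > 0)) stop("connectome diagonal must be 0", call. = FALSE)
  if (!isTRUE(all.equal(z, t(z), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("connectome matrix must be symmetric", call. = FALSE)
  }
  if (!all(is.finite(z))) stop("connectome values must be finite", call. = FALSE)
  dimnames(z) <- list(node_ids, node_ids)
  structure(
    list(subject_id = as.character(subject_id), z = z,
         node_ids = as.character(node_ids),
         n_scans_averaged = as.integer(n_scans_averaged)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s: %d nodes, %d edges, %d scan(s) averaged\n",
              x$subject_id, length(x$node_ids), n_edges(length(x$node_ids)),
              x$n_scans_averaged))
  invisible(x)
}

#' Compute a Fisher-z connectome from node time series
#'
#' Correlates the time series of every node pair (Pearson) and applies the
#' Fisher z transform, `z = atanh(r)`. Correlations are clipped to
#' `+/- (1 - clip_margin)` beforehand so that perfect (anti)correlations map
#' to large finite values rather than infinity.
#'
#' @param ts T x N numeric matrix of node time series (T timepoints,
#'   N nodes), or a data.frame coercible to one. Column names are used as
#'   node identifiers when present.
#' @param subject_id Subject identifier stored in the result.
#' @param clip_margin Margin for clipping correlations away from +/-1.
#' @return A [new_connectome()] object with `n_scans_averaged = 1`.
#' @details A node with zero temporal variance has no defined correlation
#'   and indicates corrupt input; it raises an error naming the node. At
#'   least 3 timepoints are required.
#' @examples
#' ts <- matrix(rnorm(200), 50, 4)
#' compute_connectome(ts, subject_id = "s01")
#' @export
compute_connectome <- function(ts, subject_id = "subject", clip_margin = 1e-7) {
  ts <- as.matrix(ts)
  storage.mode(ts) <- "double"
  if (nrow(ts) < 3L) {
    stop("at least 3 timepoints are required to correlate node time series",
         call. = FALSE)
  }
  if (ncol(ts) < 2L) stop("at least 2 nodes are required", call. = FALSE)
  if (!all(is.finite(ts))) stop("time series contain non-finite values", call. = FALSE)
  if (!(clip_margin > 0 && clip_margin < 1)) {
    stop("`clip_margin` must be in (0, 1)", call. = FALSE)
  }
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    ids <- colnames(ts)
    if (is.null(ids)) ids <- paste0("node_", seq_len(ncol(ts)))
    stop(sprintf("zero-variance node(s): %s",
                 paste(ids[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- cor(ts)
  lim <- 1 - clip_margin
  r[r > lim] <- lim
  r[r < -lim] <- -lim
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry against rounding
  new_connectome(z, subject_id, node_ids = colnames(ts), n_scans_averaged = 1L)
}

#' Average the connectomes of one subject across scans
#'
#' Scans of valid data for a subject are combined by an unweighted
#' elementwise mean of the Fisher-z matrices; the number of scans averaged
#' is recorded for audit.
#'
#' @param connectomes Non-empty list of [new_connectome()] objects with
#'   identical subject, dimension and node order.
#' @return A single `connectome` whose `z` is the elementwise mean.
#' @export
average_connectomes <- function(connectomes) {
  if (length(connectomes) == 0L) stop("no connectomes to average", call. = FALSE)
  if (!all(vapply(connectomes, inherits, logical(1), "connectome"))) {
    stop("all elements must be connectome objects", call. = FALSE)
  }
  ref <- connectomes[[1L]]
  for (c_i in connectomes[-1L]) {
    if (!identical(c_i$node_ids, ref$node_ids)) {
      stop("connectomes have mismatched node sets or ordering", call. = FALSE)
    }
    if (!identical(c_i$subject_id, ref$subject_id)) {
      stop("connectomes belong to different subjects", call. = FALSE)
    }
  }
  z <- Reduce(`+`, lapply(connectomes, `[[`, "z")) / length(connectomes)
  new_connectome(z, ref$subject_id, ref$node_ids,
                 n_scans_averaged = length(connectomes))
}
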