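#' Canonical network labels
#'
#' The ten canonical functional networks used throughout: anterior and
#' posterior default mode (aDMN, pDMN), central executive (CEN), motor
#' sensory (MSN), visual 1 and 2 (VI, VII), visual association (VAs),
#' salience (SAL), subcortical (SC), and cerebellar (CBL).
#' @export
NETWORK_LABELS <- c("aDMN", "pDMN", "CEN", "MSN", "VI", "VII", "VAs",
                    "SAL", "SC", "CBL")

#' Validate a node-to-network atlas
#'
#' @param atlas data.frame with columns `node_id` and `network`, one row
#'   per node, in node order.
#' @param n_nodes Optional expected node count.
#' @return The atlas (invisibly checked): every node labeled exactly once.
#' @export
validate_atlas <- function(atlas, n_nodes = NULL) {
  if (!all(c("node_id", "network") %in% names(atlas))) {
    stop("atlas needs columns `node_id` and `network`", call. = FALSE)
  }
  if (anyDuplicated(atlas$node_id)) {
    stop("atlas labels some node more than once", call. = FALSE)
  }
  if (anyNA(atlas$network)) stop("atlas has unlabeled nodes", call. = FALSE)
  if (!is.null(n_nodes) && nrow(atlas) != n_nodes) {
    stop(sprintf("atlas has %d nodes; expected %d", nrow(atlas), n_nodes),
         call. = FALSE)
  }
  atlas
}

#' Virtual-lesion edge mask for one network
#'
#' Keeps every edge with at least one endpoint in the network of interest
#' (its within-network and between-network connections); all other edges
#' are lesioned out. Masks for different networks overlap on the edges
#' spanning the two networks.
#'
#' @param atlas Node-to-network atlas ([validate_atlas()] format), rows in
#'   node order.
#' @param network Network label present in the atlas.
#' @return Logical edge vector of length N(N-1)/2 in canonical order.
#' @export
lesion_mask <- function(atlas, network) {
  validate_atlas(atlas)
  if (!network %in% atlas$network) {
    stop(sprintf("network %s not present in atlas", network), call. = FALSE)
  }
  in_net <- atlas$network == network
  pairs <- edge_pairs(nrow(atlas))
  in_net[pairs$i] | in_net[pairs$j]
}

#' Virtual lesion analysis over all networks
#'
#' Reruns the full cross-validated CPM once per network with the edge
#' universe restricted to that network's [lesion_mask()], alongside the
#' whole-brain run. All runs share identical fold assignments (same seed),
#' so per-network scores are directly comparable to the whole-brain score.
#' Networks whose median rho exceeds the whole-brain median are flagged as
#' driving the prediction.
#'
#' @inheritParams run_cv
#' @param atlas Node-to-network atlas covering all nodes, rows in node
#'   order; edge columns must follow [edge_pairs()] over those nodes.
#' @param networks Networks to lesion (default: every label in the atlas).
#' @return Object of class `lesion_result`: `whole_brain` ([run_cv()]
#'   object), `per_network` (named list of `cpm_cv`), `summary`
#'   (data.frame network / median_rho / n_edges / driving),
#'   `whole_brain_median`, `driving_networks`.
#' @export
run_lesion_cpm <- function(edges, y, X = NULL, atlas, networks = NULL,
                           k = 10L, repeats = 100L, alpha = 0.05,
                           variant = c("combined", "positive", "negative"),
                           seed = 1L) {
  variant <- match.arg(variant)
  edges <- as.matrix(edges)
  validate_atlas(atlas)
  if (n_edges(nrow(atlas)) != ncol(edges)) {
    stop("edge matrix width does not match the atlas node count", call. = FALSE)
  }
  if (is.null(networks)) networks <- unique(atlas$network)
  folds <- make_folds(nrow(edges), k, repeats, seed)
  whole <- run_cv(edges, y, X, k = k, repeats = repeats, alpha = alpha,
                  variant = variant, seed = seed, folds = folds)
  per_network <- lapply(networks, function(net) {
    mask <- lesion_mask(atlas, net)
    run_cv(edges[, mask, drop = FALSE], y, X, k = k, repeats = repeats,
           alpha = alpha, variant = variant, seed = seed, folds = folds)
  })
  names(per_network) <- networks
  medians <- vapply(per_network, cv_score, numeric(1))
  wb <- cv_score(whole)
  summary <- data.frame(
    network = networks,
    median_rho = unname(medians),
    n_edges = vapply(networks, function(net) sum(lesion_mask(atlas, net)), integer(1)),
    driving = unname(medians > wb),
    row.names = NULL
  )
  structure(
    list(whole_brain = whole, per_network = per_network, summary = summary,
         whole_brain_median = wb,
         driving_networks = summary$network[summary$driving]),
    class = "lesion_result"
  )
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> whole-brain median rho = %.3f\n", x$whole_brain_median))
  print(x$summary)
  invisible(x)
}

#' Degree centrality of selected predictive edges
#'
#' Per node, the count of selected edges of the given sign incident to it.
#' Summed over nodes, degrees equal twice the number of selected edges
#' (each edge has two endpoints).
#'
#' @param selection [select_edges()] object, or a logical edge mask.
#' @param sign `"positive"` or `"negative"` (ignored when `selection` is
#'   already a mask).
#' @param n_nodes Number of nodes N consistent with the edge vector.
#' @return Integer vector of length N of per-node degrees.
#' @export
degree_centrality <- function(selection, sign = c("negative", "positive"),
                              n_nodes) {
  sign <- match.arg(sign)
  mask <- if (inherits(selection, "edge_selection")) {
    if (sign == "positive") selection$pos_mask else selection$neg_mask
  } else {
    as.logical(selection)
  }
  if (length(mask) != n_edges(n_nodes)) {
    stop("mask length does not match `n_nodes`", call. = FALSE)
  }
  pairs <- edge_pairs(n_nodes)
  deg <- integer(n_nodes)
  tab_i <- tabulate(pairs$i[mask], nbins = n_nodes)
  tab_j <- tabulate(pairs$j[mask], nbins = n_nodes)
  deg + tab_i + tab_j
}

#' Network-pair contribution matrix of selected edges
#'
#' Counts selected edges within each network (diagonal) and between each
#' network pair (off-diagonal), plus a density-normalized variant: each
#' count divided by the number of possible node pairs spanning the pair
#' (`n_a * n_b` for distinct networks, `n_a (n_a - 1) / 2` on the
#' diagonal). The sum of raw counts over unique pairs equals the total
#' number of selected edges.
#'
#' @inheritParams degree_centrality
#' @param atlas Node-to-network atlas covering all nodes, rows in node
#'   order.
#' @return Object of class `contribution_matrix`: `counts` and `density`,
#'   both symmetric matrices over the atlas's networks, and `n_selected`.
#' @export
network_contribution <- function(selection, sign = c("negative", "positive"),
                                 atlas) {
  sign <- match.arg(sign)
  validate_atlas(atlas)
  mask <- if (inherits(selection, "edge_selection")) {
    if (sign == "positive") selection$pos_mask else selection$neg_mask
  } else {
    as.logical(selection)
  }
  n_nodes <- nrow(atlas)
  if (length(mask) != n_edges(n_nodes)) {
    stop("mask length does not match the atlas node count", call. = FALSE)
  }
  nets <- unique(atlas$network)
  m <- length(nets)
  node_net <- match(atlas$network, nets)
  pairs <- edge_pairs(n_nodes)
  counts <- matrix(0, m, m, dimnames = list(nets, nets))
  sel_i <- node_net[pairs$i[mask]]
  sel_j <- node_net[pairs$j[mask]]
  for (e in seq_along(sel_i)) {
    a <- sel_i[e]; b <- sel_j[e]
    counts[a, b] <- counts[a, b] + 1
    if (a != b) counts[b, a] <- counts[b, a] + 1
  }
  sizes <- tabulate(node_net, nbins = m)
  possible <- outer(sizes, sizes)
  diag(possible) <- sizes * (sizes - 1) / 2
  density <- ifelse(possible > 0, counts / possible, 0)
  dimnames(density) <- dimnames(counts)
  structure(
    list(counts = counts, density = density, n_selected = sum(mask),
         networks = nets, network_sizes = setNames(sizes, nets)),
    class = "contribution_matrix"
  )
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf("<contribution_matrix> %d selected edges over %d networks\n",
              x$n_selected, length(x$networks)))
  print(round(x$density, 4))
  invisible(x)
}
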