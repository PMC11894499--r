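#' Longitudinal symptom-trajectory mixture model
#'
#' Five latent trajectory classes of post-traumatic symptom development
#' over the 1-, 6- and 14-month assessments, with mixture weights
#' defaulting to the prevalences reported for the first year after trauma:
#' low 64.5%, remitting 16.9%, moderate 6.7%, high 6.5%, delayed 5.5%
#' (the printed percentages sum to 100.1%, so the defaults are normalized
#' to sum exactly to 1). Each class has a mean latent-severity profile (in latent SD units)
#' whose shape matches the class semantics (remitting decreases over time,
#' delayed increases); a subject-level Gaussian deviation is shared across
#' timepoints.
#'
#' @param weights Named mixture weights over the five classes (sum to 1).
#' @param profiles 5 x 3 matrix of class-mean latent severity at 1, 6 and
#'   14 months (rows in class order low, remitting, moderate, high,
#'   delayed).
#' @param subject_sd SD of the subject-level deviation around the class
#'   profile.
#' @return Object of class `trajectory_model`.
#' @export
trajectory_model <- function(weights = c(low = 0.645, remitting = 0.169,
                                         moderate = 0.067, high = 0.065,
                                         delayed = 0.055) / 1.001,
                             profiles = NULL, subject_sd = 0.3) {
  classes <- c("low", "remitting", "moderate", "high", "delayed")
  if (!setequal(names(weights), classes)) {
    stop("`weights` must be named low/remitting/moderate/high/delayed", call. = FALSE)
  }
  weights <- weights[classes]
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("trajectory weights must sum to 1", call. = FALSE)
  }
  if (is.null(profiles)) {
    profiles <- rbind(
      low       = c(-0.8, -1.0, -1.1),
      remitting = c( 1.0,  0.2, -0.4),
      moderate  = c( 0.3,  0.3,  0.3),
      high      = c( 1.6,  1.7,  1.8),
      delayed   = c(-0.2,  0.6,  1.4))
  }
  profiles <- as.matrix(profiles)
  if (!identical(dim(profiles), c(5L, 3L))) {
    stop("`profiles` must be a 5 x 3 matrix (classes x timepoints)", call. = FALSE)
  }
  rownames(profiles) <- classes
  colnames(profiles) <- c("m1", "m6", "m14")
  if (!(profiles["remitting", 1] > profiles["remitting", 3])) {
    stop("remitting profile must decrease over time", call. = FALSE)
  }
  if (!(profiles["delayed", 3] > profiles["delayed", 1])) {
    stop("delayed profile must increase over time", call. = FALSE)
  }
  structure(list(classes = classes, weights = weights, profiles = profiles,
                 subject_sd = subject_sd),
            class = "trajectory_model")
}

#' Sample trajectory classes and latent severities
#'
#' Draws `n` subjects iid from the mixture; each subject's latent severity
#' at the three timepoints is the class profile plus a shared subject-level
#' Gaussian deviation.
#'
#' @param n Number of subjects.
#' @param model A [trajectory_model()].
#' @param seed Integer seed.
#' @return List with `class` (factor of length n) and `latent` (n x 3
#'   matrix, columns m1/m6/m14).
#' @export
sample_trajectories <- function(n, model = trajectory_model(), seed = 1L) {
  stopifnot(inherits(model, "trajectory_model"), n >= 1)
  set.seed(seed)
  cls <- sample(model$classes, n, replace = TRUE, prob = model$weights)
  dev <- rnorm(n, 0, model$subject_sd)
  latent <- model$profiles[cls, , drop = FALSE] + dev
  rownames(latent) <- NULL
  list(class = factor(cls, levels = model$classes), latent = latent)
}

#' CAPS-5 item configuration
#'
#' The instrument has 20 items rated 0 (absent) to 4 (extreme or
#' incapacitating), total range 0-80, grouped into DSM-5 clusters
#' B (intrusion, 5 items), C (avoidance, 2), D (negative mood/cognition,
#' 7), E (hyperarousal, 6) -- the standard 20-item structure.
#'
#' @param items_per_cluster Named integer vector over B/C/D/E summing
#'   to 20.
#' @param thresholds Four increasing cutpoints on the latent-plus-noise
#'   scale separating item ratings 0|1|2|3|4.
#' @param item_noise_sd SD of per-item Gaussian noise around the latent
#'   severity.
#' @return List of class `caps_config`.
#' @export
caps_config <- function(items_per_cluster = c(B = 5L, C = 2L, D = 7L, E = 6L),
                        thresholds = c(0.5, 1.2, 2.0, 2.8),
                        item_noise_sd = 1) {
  if (!setequal(names(items_per_cluster), c("B", "C", "D", "E"))) {
    stop("`items_per_cluster` must be named B, C, D, E", call. = FALSE)
  }
  items_per_cluster <- items_per_cluster[c("B", "C", "D", "E")]
  if (sum(items_per_cluster) != 20L) {
    stop("cluster item counts must sum to 20", call. = FALSE)
  }
  if (length(thresholds) != 4L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be 4 strictly increasing cutpoints", call. = FALSE)
  }
  structure(list(items_per_cluster = items_per_cluster,
                 thresholds = thresholds, item_noise_sd = item_noise_sd),
            class = "caps_config")
}

#' Simulate CAPS-5 item, cluster and total scores from latent severity
#'
#' Each of the 20 items at each timepoint is an ordinal 0-4 obtained by
#' thresholding the subject's latent severity plus item-level Gaussian
#' noise; totals are item sums (0-80) and cluster scores are within-cluster
#' sums, so cluster scores add up to the total by construction.
#'
#' @param latent n x 3 matrix of latent severities (from
#'   [sample_trajectories()]).
#' @param config A [caps_config()].
#' @param seed Integer seed.
#' @return List with `total` (n x 3), `clusters` (list of n x 4 matrices
#'   per timepoint, columns B/C/D/E), and `items` (n x 20 x 3 array).
#' @export
simulate_caps <- function(latent, config = caps_config(), seed = 1L) {
  stopifnot(inherits(config, "caps_config"))
  latent <- as.matrix(latent)
  n <- nrow(latent)
  n_tp <- ncol(latent)
  set.seed(seed)
  items <- array(0L, dim = c(n, 20L, n_tp))
  for (tp in seq_len(n_tp)) {
    u <- latent[, tp] + matrix(rnorm(n * 20L, 0, config$item_noise_sd), n, 20L)
    items[, , tp] <- matrix(findInterval(u, config$thresholds), n, 20L)
  }
  cl_index <- rep(names(config$items_per_cluster), config$items_per_cluster)
  total <- apply(items, c(1L, 3L), sum)
  clusters <- lapply(seq_len(n_tp), function(tp) {
    sapply(c("B", "C", "D", "E"), function(cl) {
      rowSums(items[, cl_index == cl, tp, drop = FALSE])
    })
  })
  colnames(total) <- c("m1", "m6", "m14")[seq_len(n_tp)]
  names(clusters) <- colnames(total)
  list(total = total, clusters = clusters, items = items)
}

#' Evenly sized synthetic network atlas
#'
#' Assigns `n_nodes` nodes round-robin-free (contiguous blocks) to the
#' given networks; block sizes differ by at most one node. This is a
#' synthetic stand-in for an anatomical atlas, used by the generator and
#' tests.
#'
#' @param n_nodes Number of nodes.
#' @param networks Network labels (default the ten canonical labels).
#' @return Atlas data.frame (`node_id`, `network`) in node order.
#' @export
synthetic_atlas <- function(n_nodes = 60L, networks = NETWORK_LABELS) {
  sizes <- rep(n_nodes %/% length(networks), length(networks))
  extra <- n_nodes %% length(networks)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  data.frame(node_id = paste0("node_", seq_len(n_nodes)),
             network = rep(networks, sizes))
}

#' Default configuration for planted connectome effects
#'
#' @param n_planted Number of edges carrying a severity effect.
#' @param beta Effect magnitude in z-units per SD of 1-month latent
#'   severity; planted edges are shifted by `-beta` per latent SD
#'   (decreased connectivity with more severe symptoms) except for a small
#'   positive fraction.
#' @param target_networks Networks in which planted edges concentrate.
#' @param concentration Fraction of planted edges with at least one
#'   endpoint in a target network.
#' @param pos_fraction Fraction of planted edges with a positive effect.
#' @param pop_mean,pop_sd Population mean / between-edge SD of baseline
#'   Fisher-z connectivity.
#' @param subject_sd Between-subject SD of each edge around its population
#'   mean.
#' @param scan_sd Within-subject, between-scan noise SD (reliability
#'   parameter); 0 makes the three scans identical.
#' @param n_scans Scans per subject (default 3: rest, face matching,
#'   shape-recognition task).
#' @return List of class `truth_config`.
#' @export
truth_config <- function(n_planted = 50L, beta = 0.15,
                         target_networks = "aDMN", concentration = 0.9,
                         pos_fraction = 0.02, pop_mean = 0.25, pop_sd = 0.1,
                         subject_sd = 0.1, scan_sd = 0.2, n_scans = 3L) {
  stopifnot(n_planted >= 0, beta >= 0, concentration >= 0, concentration <= 1,
            pos_fraction >= 0, pos_fraction <= 1, scan_sd >= 0, n_scans >= 1)
  structure(as.list(environment()), class = "truth_config")
}

#' Simulate per-subject scan connectomes with planted severity effects
#'
#' Each edge's Fisher-z value is a population mean plus subject-level
#' noise; a configured set of planted edges is additionally shifted by
#' `-beta` z-units per SD of standardized 1-month latent severity (a small
#' fraction positively). Each of the `n_scans` scans is the subject's
#' connectome plus independent scan noise, and the averaged connectome is
#' their mean.
#'
#' @param latent_m1 Length-n vector of 1-month latent severities.
#' @param atlas Atlas data.frame defining the node set and networks.
#' @param config A [truth_config()].
#' @param seed Integer seed.
#' @return List with `edges` (n x E averaged edge matrix), `scan_edges`
#'   (list of n x E matrices, one per scan), and `ground_truth` (class
#'   `ground_truth`: `planted_edges` indices, signed `effects`,
#'   `target_networks`, `target_mask`).
#' @export
simulate_connectomes <- function(latent_m1, atlas, config = truth_config(),
                                 seed = 1L) {
  stopifnot(inherits(config, "truth_config"))
  validate_atlas(atlas)
  n <- length(latent_m1)
  n_nodes <- nrow(atlas)
  if (n_nodes < 10L) stop("need at least 10 nodes", call. = FALSE)
  if (!all(config$target_networks %in% atlas$network)) {
    stop("target network(s) absent from atlas", call. = FALSE)
  }
  E <- n_edges(n_nodes)
  target_mask <- Reduce(`|`, lapply(config$target_networks, lesion_mask,
                                    atlas = atlas))
  n_in <- round(config$concentration * config$n_planted)
  n_out <- config$n_planted - n_in
  if (n_in > sum(target_mask) || n_out > sum(!target_mask)) {
    stop("planted-edge concentration infeasible for this atlas", call. = FALSE)
  }
  set.seed(seed)
  planted <- c(sample(which(target_mask), n_in),
               sample(which(!target_mask), n_out))
  n_pos <- round(config$pos_fraction * config$n_planted)
  signs <- rep(-1, config$n_planted)
  if (n_pos > 0) signs[sample.int(config$n_planted, n_pos)] <- 1
  effects <- signs * config$beta

  sev <- if (sd(latent_m1) > 0) (latent_m1 - mean(latent_m1)) / sd(latent_m1)
         else rep(0, n)
  pop <- rnorm(E, config$pop_mean, config$pop_sd)
  subj <- matrix(pop, n, E, byrow = TRUE) +
    matrix(rnorm(n * E, 0, config$subject_sd), n, E)
  if (config$n_planted > 0) {
    subj[, planted] <- subj[, planted] + outer(sev, effects)
  }
  scan_edges <- lapply(seq_len(config$n_scans), function(s) {
    subj + matrix(rnorm(n * E, 0, config$scan_sd), n, E)
  })
  edges <- Reduce(`+`, scan_edges) / config$n_scans
  truth <- structure(
    list(planted_edges = planted, effects = effects,
         target_networks = config$target_networks, target_mask = target_mask,
         config = config),
    class = "ground_truth")
  list(edges = edges, scan_edges = scan_edges, ground_truth = truth)
}

#' Mask follow-up outcomes by random dropout
#'
#' Retention at 6 and 14 months is Bernoulli per subject at the configured
#' marginal rates (defaults 84.0% and 82.1%); by default 14-month
#' completers are a subset of 6-month completers, and dropout is
#' independent of trajectory class (missing completely at random). An
#' informative mode makes dropout probability increase with 1-month latent
#' severity for robustness studies.
#'
#' @param phenotype Phenotype data.frame (see [generate_cohort()]).
#' @param retention_6m,retention_14m Marginal retention fractions in
#'   (0, 1].
#' @param nested Should 14-month completers be a subset of 6-month
#'   completers?
#' @param informative Optional numeric; if nonzero, log-odds of retention
#'   decrease by this amount per SD of 1-month severity.
#' @param latent_m1 Required when `informative != 0`.
#' @param seed Integer seed.
#' @return The phenotype with 6m/14m outcome columns set `NA` for dropped
#'   subjects, plus logical columns `retained_6m`, `retained_14m`.
#' @export
apply_dropout <- function(phenotype, retention_6m = 0.84, retention_14m = 0.821,
                          nested = TRUE, informative = 0, latent_m1 = NULL,
                          seed = 1L) {
  stopifnot(retention_6m > 0, retention_6m <= 1,
            retention_14m > 0, retention_14m <= 1)
  n <- nrow(phenotype)
  set.seed(seed)
  keep_prob6 <- rep(retention_6m, n)
  keep_prob14 <- rep(retention_14m, n)
  if (informative != 0) {
    if (is.null(latent_m1)) stop("informative dropout needs `latent_m1`", call. = FALSE)
    s <- as.numeric(scale(latent_m1))
    adj <- function(p) stats::plogis(stats::qlogis(p) - informative * s)
    keep_prob6 <- adj(keep_prob6)
    keep_prob14 <- adj(keep_prob14)
  }
  r6 <- runif(n) < keep_prob6
  r14 <- if (nested) {
    cond <- pmin(1, keep_prob14 / keep_prob6)
    r6 & (runif(n) < cond)
  } else {
    runif(n) < keep_prob14
  }
  cols6 <- grep("_6m$", names(phenotype), value = TRUE)
  cols14 <- grep("_14m$", names(phenotype), value = TRUE)
  phenotype[!r6, cols6] <- NA
  phenotype[!r14, cols14] <- NA
  phenotype$retained_6m <- r6
  phenotype$retained_14m <- r14
  phenotype
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Composes the trajectory mixture, CAPS-5 simulator, covariate draws,
#' planted-effect connectome simulator and follow-up dropout into one
#' cohort that every pipeline stage accepts directly. Bit-reproducible
#' from `seed`.
#'
#' The default scale (160 subjects, 60 nodes in 10 networks of 6) keeps a
#' full CPM with permutations fast; pass `n_nodes = 268` for a
#' full-resolution connectome.
#'
#' @param n Number of subjects (default 160).
#' @param n_nodes Number of nodes (default 60).
#' @param trajectory A [trajectory_model()].
#' @param caps A [caps_config()].
#' @param truth A [truth_config()].
#' @param atlas Optional atlas; defaults to [synthetic_atlas()] over the
#'   ten canonical networks.
#' @param retention_6m,retention_14m,dropout_nested Dropout settings; see
#'   [apply_dropout()]. Use `retention_6m = 1, retention_14m = 1` for a
#'   complete cohort.
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort`: `phenotype` (data.frame),
#'   `edges` (n x E averaged edge matrix), `scan_edges`, `atlas`,
#'   `ground_truth`, `latent`, `trajectory_class`, `config`, `seed`.
#' @export
generate_cohort <- function(n = 160L, n_nodes = 60L,
                            trajectory = trajectory_model(),
                            caps = caps_config(), truth = truth_config(),
                            atlas = NULL,
                            retention_6m = 0.84, retention_14m = 0.821,
                            dropout_nested = TRUE, seed = 1L) {
  if (is.null(atlas)) atlas <- synthetic_atlas(n_nodes)
  atlas <- validate_atlas(atlas)
  n_nodes <- nrow(atlas)

  traj <- sample_trajectories(n, trajectory, seed = seed + 1L)
  scores <- simulate_caps(traj$latent, caps, seed = seed + 2L)

  set.seed(seed + 3L)
  age <- round(pmax(18, rnorm(n, 33.9, 11.5)), 1)
  sex <- rbinom(n, 1L, 0.494)
  motion <- round(exp(rnorm(n, log(0.08), 0.4)), 4)

  sim <- simulate_connectomes(traj$latent[, "m1"], atlas, truth,
                              seed = seed + 4L)

  phenotype <- data.frame(
    subject_id = sprintf("sub_%03d", seq_len(n)),
    age = age, sex = sex, motion = motion,
    caps_total_1m = scores$total[, "m1"],
    caps_B_1m = scores$clusters$m1[, "B"], caps_C_1m = scores$clusters$m1[, "C"],
    caps_D_1m = scores$clusters$m1[, "D"], caps_E_1m = scores$clusters$m1[, "E"],
    caps_total_6m = scores$total[, "m6"],
    caps_B_6m = scores$clusters$m6[, "B"], caps_C_6m = scores$clusters$m6[, "C"],
    caps_D_6m = scores$clusters$m6[, "D"], caps_E_6m = scores$clusters$m6[, "E"],
    caps_total_14m = scores$total[, "m14"],
    caps_B_14m = scores$clusters$m14[, "B"], caps_C_14m = scores$clusters$m14[, "C"],
    caps_D_14m = scores$clusters$m14[, "D"], caps_E_14m = scores$clusters$m14[, "E"]
  )
  phenotype <- apply_dropout(phenotype, retention_6m, retention_14m,
                             nested = dropout_nested, seed = seed + 5L)
  rownames(sim$edges) <- phenotype$subject_id

  structure(
    list(phenotype = phenotype, edges = sim$edges,
         scan_edges = sim$scan_edges, atlas = atlas,
         ground_truth = sim$ground_truth, latent = traj$latent,
         trajectory_class = traj$class,
         config = list(n = n, n_nodes = n_nodes, trajectory = trajectory,
                       caps = caps, truth = truth,
                       retention_6m = retention_6m,
                       retention_14m = retention_14m,
                       dropout_nested = dropout_nested),
         seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d nodes (%d edges), seed %d\n",
              nrow(x$phenotype), nrow(x$atlas), ncol(x$edges), x$seed))
  cat(sprintf("  planted: %d edges in %s (beta = %g)\n",
              length(x$ground_truth$planted_edges),
              paste(x$ground_truth$target_networks, collapse = "/"),
              x$ground_truth$config$beta))
  invisible(x)
}

#' Modeled rows of a cohort for one target timepoint
#'
#' Subsets a cohort to the subjects with a non-missing outcome at the
#' target timepoint (dropout excluded, never imputed) and assembles the
#' outcome and covariate matrix. For the 6- and 14-month targets the
#' baseline (1-month) total is appended to the covariates, mirroring
#' confound control for initial severity.
#'
#' @param cohort A [generate_cohort()] object (or a list with `phenotype`
#'   and `edges`).
#' @param target `"1m"`, `"6m"` or `"14m"`.
#' @param covariates Phenotype columns used as confounds (default age,
#'   sex, motion).
#' @param include_baseline Append `caps_total_1m` for follow-up targets
#'   (default `TRUE`).
#' @param outcome `"total"` or a cluster label `"B"/"C"/"D"/"E"`.
#' @return List: `edges`, `y`, `X`, `subject_id`, `target`.
#' @export
model_frame <- function(cohort, target = c("1m", "6m", "14m"),
                        covariates = c("age", "sex", "motion"),
                        include_baseline = TRUE,
                        outcome = "total") {
  target <- match.arg(target)
  ph <- cohort$phenotype
  col <- if (outcome == "total") sprintf("caps_total_%s", target)
         else sprintf("caps_%s_%s", outcome, target)
  if (!col %in% names(ph)) stop(sprintf("phenotype lacks column %s", col), call. = FALSE)
  keep <- !is.na(ph[[col]])
  X <- if (length(covariates)) as.matrix(ph[keep, covariates, drop = FALSE]) else NULL
  if (include_baseline && target != "1m") {
    X <- cbind(X, baseline = ph$caps_total_1m[keep])
  }
  list(edges = cohort$edges[keep, , drop = FALSE],
       y = ph[[col]][keep],
       X = X,
       subject_id = ph$subject_id[keep],
       target = target, outcome = outcome)
}
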