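#' Default pipeline configuration
#'
#' @param targets Timepoints to model (subset of `"1m"`, `"6m"`, `"14m"`).
#' @param covariates Confound columns of the phenotype table.
#' @param include_baseline Add 1-month total severity as a confound for
#'   follow-up targets.
#' @param alpha Edge-selection threshold.
#' @param k,repeats Cross-validation folds and repeated divisions.
#' @param n_perm,perm_repeats Permutation-null settings.
#' @param variant Model form (`"combined"`, `"positive"`, `"negative"`).
#' @param consensus_threshold Fraction of training fits an edge must be
#'   selected in to count as a consensus predictive edge.
#' @param run_clusters,run_lesion Toggle the symptom-cluster models and
#'   the virtual lesion analysis.
#' @param seed Integer seed (mandatory for a run).
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(targets = c("1m", "6m", "14m"),
                            covariates = c("age", "sex", "motion"),
                            include_baseline = TRUE, alpha = 0.05,
                            k = 10L, repeats = 100L, n_perm = 1000L,
                            perm_repeats = 10L,
                            variant = c("combined", "positive", "negative"),
                            consensus_threshold = 1,
                            run_clusters = TRUE, run_lesion = TRUE,
                            seed = 1L) {
  variant <- match.arg(variant)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, per target timepoint: repeated cross-validated CPM of the
#' total symptom score, permutation significance, symptom-cluster models
#' with FDR correction, and virtual lesion network attribution with
#' per-sign degree centrality and network contribution matrices. The
#' bundle carries a provenance block (config, seed, package version) and
#' is deterministic given the seed.
#'
#' @param cohort A [generate_cohort()] object or a list with `phenotype`
#'   (validated), `edges` and `atlas`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, results are written as
#'   JSON/CSV via [write_results()].
#' @param verbose Log each stage.
#' @return Object of class `results_bundle`: per-target list of
#'   `cpm` (`cpm_cv`), `permutation`, `clusters` (data.frame),
#'   `lesion` (`lesion_result`), `consensus`, `degree` and `contribution`;
#'   plus `provenance`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort$edges) || is.null(cohort$phenotype)) {
    stop("cohort must provide `edges` and `phenotype`", call. = FALSE)
  }
  if ((isTRUE(config$run_lesion)) && is.null(cohort$atlas)) {
    stop("lesion analysis requested but cohort provides no atlas", call. = FALSE)
  }
  validate_phenotype(cohort$phenotype)
  say <- function(...) if (verbose) message(sprintf(...))
  n_nodes <- if (!is.null(cohort$atlas)) nrow(cohort$atlas) else
    (1 + sqrt(1 + 8 * ncol(cohort$edges))) / 2

  per_target <- list()
  for (tp in config$targets) {
    t0 <- Sys.time()
    mf <- model_frame(cohort, tp, covariates = config$covariates,
                      include_baseline = config$include_baseline)
    say("[%s] modeling %d subjects, seed %d", tp, length(mf$y), config$seed)
    perm <- permutation_test(mf$edges, mf$y, mf$X, k = config$k,
                             repeats = config$repeats, alpha = config$alpha,
                             variant = config$variant, n_perm = config$n_perm,
                             perm_repeats = config$perm_repeats,
                             seed = config$seed)
    cpm <- perm$observed_run
    cons <- consensus_edges(cpm, config$consensus_threshold)
    say("[%s] median rho = %.3f, permutation p = %.4g (%d shuffles)",
        tp, perm$observed, perm$p_one_tailed, perm$n_perm)

    clusters <- NULL
    if (isTRUE(config$run_clusters)) {
      cs <- data.frame(
        B = cohort$phenotype[[sprintf("caps_B_%s", tp)]],
        C = cohort$phenotype[[sprintf("caps_C_%s", tp)]],
        D = cohort$phenotype[[sprintf("caps_D_%s", tp)]],
        E = cohort$phenotype[[sprintf("caps_E_%s", tp)]])
      keep <- stats::complete.cases(cs) &
        !is.na(cohort$phenotype[[sprintf("caps_total_%s", tp)]])
      ph <- cohort$phenotype[keep, , drop = FALSE]
      Xc <- as.matrix(ph[, config$covariates, drop = FALSE])
      if (config$include_baseline && tp != "1m") {
        Xc <- cbind(Xc, baseline = ph$caps_total_1m)
      }
      clusters <- cluster_models(cohort$edges[keep, , drop = FALSE],
                                 cs[keep, , drop = FALSE], Xc,
                                 k = config$k, repeats = config$repeats,
                                 alpha = config$alpha, n_perm = config$n_perm,
                                 perm_repeats = config$perm_repeats,
                                 seed = config$seed, variant = config$variant)
      say("[%s] cluster models done (min FDR p = %.4g)", tp, min(clusters$p_fdr))
    }

    lesion <- degree <- contribution <- NULL
    if (isTRUE(config$run_lesion)) {
      lesion <- run_lesion_cpm(mf$edges, mf$y, mf$X, cohort$atlas,
                               k = config$k, repeats = config$repeats,
                               alpha = config$alpha, variant = config$variant,
                               seed = config$seed)
      say("[%s] lesion analysis: driving network(s): %s", tp,
          paste(lesion$driving_networks, collapse = ", "))
      degree <- data.frame(
        node_id = cohort$atlas$node_id,
        network = cohort$atlas$network,
        degree_neg = degree_centrality(cons$neg, n_nodes = n_nodes),
        degree_pos = degree_centrality(cons$pos, n_nodes = n_nodes))
      contribution <- list(
        negative = network_contribution(cons$neg, atlas = cohort$atlas),
        positive = network_contribution(cons$pos, atlas = cohort$atlas))
    }
    say("[%s] stage complete in %.1f s", tp,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    per_target[[tp]] <- list(cpm = cpm, permutation = perm,
                             clusters = clusters, lesion = lesion,
                             consensus = cons, degree = degree,
                             contribution = contribution)
  }

  bundle <- structure(
    list(targets = per_target,
         provenance = list(
           config = unclass(config),
           config_hash = config_hash(config),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("connpred")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "results_bundle")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

config_hash <- function(config) {
  # stable digest of the configuration for provenance
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a results bundle as JSON and CSV files
#'
#' Per target: `cpm_<tp>.json` (rho per repeat, median, selection
#' frequencies, consensus counts), `predictions_<tp>.csv` (out-of-fold
#' predictions), `permutation_<tp>.json`, `clusters_<tp>.csv`,
#' `lesion_<tp>.json`/`.csv`, `degree_<tp>.csv`,
#' `contribution_<sign>_<tp>.csv`; plus `provenance.json`.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(bundle$targets)) {
    res <- bundle$targets[[tp]]
    cpm <- res$cpm
    jsonlite::write_json(
      list(median_rho = cv_score(cpm), rho_per_repeat = cpm$rho_per_repeat,
           k = cpm$k, repeats = cpm$repeats, seed = cpm$seed,
           selection_freq_pos = cpm$selection_freq_pos,
           selection_freq_neg = cpm$selection_freq_neg,
           n_models = cpm$n_models,
           consensus = list(threshold = res$consensus$threshold,
                            n_pos = res$consensus$n_pos,
                            n_neg = res$consensus$n_neg)),
      file.path(dir, sprintf("cpm_%s.json", tp)), auto_unbox = TRUE, digits = NA)
    pred <- data.frame(repeat_ = rep(seq_len(cpm$repeats), each = cpm$n),
                       subject = rep(seq_len(cpm$n), cpm$repeats),
                       predicted = as.vector(cpm$predictions))
    write.csv(pred, file.path(dir, sprintf("predictions_%s.csv", tp)),
              row.names = FALSE)
    perm <- res$permutation
    jsonlite::write_json(
      list(observed = perm$observed, p_one_tailed = perm$p_one_tailed,
           n_perm = perm$n_perm, perm_repeats = perm$perm_repeats,
           seed = perm$seed, null_rhos = perm$null_rhos),
      file.path(dir, sprintf("permutation_%s.json", tp)),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(res$clusters)) {
      write.csv(res$clusters, file.path(dir, sprintf("clusters_%s.csv", tp)),
                row.names = FALSE)
    }
    if (!is.null(res$lesion)) {
      les <- res$lesion
      jsonlite::write_json(
        list(whole_brain_median = les$whole_brain_median,
             driving_networks = les$driving_networks,
             per_network = lapply(les$per_network, function(r)
               list(median_rho = cv_score(r), rho_per_repeat = r$rho_per_repeat))),
        file.path(dir, sprintf("lesion_%s.json", tp)),
        auto_unbox = TRUE, digits = NA)
      write.csv(les$summary, file.path(dir, sprintf("lesion_%s.csv", tp)),
                row.names = FALSE)
      write.csv(res$degree, file.path(dir, sprintf("degree_%s.csv", tp)),
                row.names = FALSE)
      for (sign in names(res$contribution)) {
        write.csv(res$contribution[[sign]]$density,
                  file.path(dir, sprintf("contribution_%s_%s.csv", sign, tp)))
      }
    }
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
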