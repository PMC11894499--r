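#' Read a node time-series table
#'
#' One delimited file per subject-scan: T rows (timepoints) x N columns
#' (nodes), header row of node identifiers. Delimiter is inferred from the
#' extension (`.tsv` tab, `.csv` comma).
#'
#' @param path File path.
#' @return Numeric T x N matrix with node ids as column names.
#' @export
read_time_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("time-series file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(sprintf("%s: non-numeric or missing values", path), call. = FALSE)
  m
}

#' Write a node time-series table
#' @param ts T x N numeric matrix with node-id column names.
#' @param path Output path (`.tsv` or `.csv`).
#' @export
write_time_series <- function(ts, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(ts, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scan manifest
#'
#' The manifest lists every subject-scan file: columns `subject_id`,
#' `scan_label` (rest / face_matching / srdc), `path` (relative to the
#' manifest's directory), `valid` (0/1 or TRUE/FALSE). Referenced files
#' must exist.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every valid scan's file exists.
#' @return data.frame with an added `abs_path` column.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "scan_label", "path", "valid")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$valid <- as.logical(df$valid)
  df$abs_path <- file.path(dirname(path), df$path)
  if (check_files) {
    gone <- df$abs_path[df$valid & !file.exists(df$abs_path)]
    if (length(gone)) {
      stop(sprintf("manifest references missing file(s): %s",
                   paste(gone, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Write a connectome as a delimited matrix with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the node order, subject id and the
#' number of scans averaged, so the matrix round-trips losslessly.
#'
#' @param connectome A [new_connectome()] object.
#' @param path Output path for the N x N tab-delimited matrix.
#' @export
write_connectome <- function(connectome, path) {
  stopifnot(inherits(connectome, "connectome"))
  utils::write.table(format(connectome$z, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(subject_id = connectome$subject_id,
         node_ids = connectome$node_ids,
         n_scans_averaged = connectome$n_scans_averaged),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a connectome written by [write_connectome()]
#' @param path Matrix path (sidecar `<path>.json` must exist).
#' @return A `connectome` object.
#' @export
read_connectome <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop(sprintf("connectome files not found: %s (+ .json sidecar)", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  z <- as.matrix(read.delim(path, header = FALSE, sep = "\t"))
  storage.mode(z) <- "double"
  dimnames(z) <- NULL
  new_connectome(z, meta$subject_id, meta$node_ids, meta$n_scans_averaged)
}

#' Read the phenotype table
#'
#' Columns: `subject_id`, covariates (`age`, `sex`, `motion`), and per
#' timepoint (`1m`, `6m`, `14m`) a CAPS-5 total `caps_total_<tp>` plus
#' cluster scores `caps_B_<tp>` ... `caps_E_<tp>`. Validation enforces the
#' instrument ranges (totals 0-80) and that cluster scores sum to the
#' total at every non-missing timepoint.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop(sprintf("phenotype file not found: %s", path), call. = FALSE)
  validate_phenotype(read.csv(path, stringsAsFactors = FALSE), file = path)
}

#' Validate phenotype invariants
#' @param df Phenotype data.frame.
#' @param file Label used in error messages.
#' @return `df`, invisibly validated.
#' @export
validate_phenotype <- function(df, file = "phenotype") {
  if (!"subject_id" %in% names(df)) {
    stop(sprintf("%s: missing column subject_id", file), call. = FALSE)
  }
  for (tp in c("1m", "6m", "14m")) {
    tot_col <- sprintf("caps_total_%s", tp)
    cl_cols <- sprintf("caps_%s_%s", c("B", "C", "D", "E"), tp)
    if (!tot_col %in% names(df)) next
    tot <- df[[tot_col]]
    bad_range <- which(!is.na(tot) & (tot < 0 | tot > 80))
    if (length(bad_range)) {
      stop(sprintf("%s: row %d, column %s: total outside 0-80", file,
                   bad_range[1L], tot_col), call. = FALSE)
    }
    if (all(cl_cols %in% names(df))) {
      cl_sum <- rowSums(df[, cl_cols, drop = FALSE])
      bad <- which(!is.na(tot) & !is.na(cl_sum) & cl_sum != tot)
      if (length(bad)) {
        stop(sprintf("%s: row %d, column %s: cluster scores sum to %d, total is %d",
                     file, bad[1L], tot_col, cl_sum[bad[1L]], tot[bad[1L]]),
             call. = FALSE)
      }
    }
  }
  df
}

#' Read a node-to-network atlas CSV
#' @param path CSV with columns `node_id`, `network`, rows in node order.
#' @return Validated atlas data.frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop(sprintf("atlas file not found: %s", path), call. = FALSE)
  validate_atlas(read.csv(path, stringsAsFactors = FALSE))
}

#' Read / write a cohort edges table
#'
#' Subjects x edges tab-delimited table; first column `subject_id`, then
#' one column per edge in canonical order (see [edge_pairs()]).
#'
#' @param edges n x E numeric matrix with subject ids as rownames.
#' @param path Output path.
#' @export
write_edges_table <- function(edges, path) {
  df <- data.frame(subject_id = rownames(edges) %||% paste0("sub_", seq_len(nrow(edges))),
                   format(edges, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("subject_id", paste0("e", seq_len(ncol(edges))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edges_table
#' @return `read_edges_table()`: numeric matrix with subject-id rownames.
#' @export
read_edges_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("edges table not found: %s", path), call. = FALSE)
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  ids <- df$subject_id
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes `phenotype.csv`, `atlas.csv`, `edges.tsv` (averaged connectome
#' edge table), `ground_truth.json` and `cohort.json` (generation seed and
#' scale) under `dir`; with `scans = TRUE` also one connectome matrix per
#' subject-scan plus a `manifest.csv` referencing them.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @param scans Also write per-scan connectome matrices and a manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, scans = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"), row.names = FALSE)
  write.csv(cohort$atlas, file.path(dir, "atlas.csv"), row.names = FALSE)
  write_edges_table(cohort$edges, file.path(dir, "edges.tsv"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(planted_edges = gt$planted_edges, effects = gt$effects,
         target_networks = gt$target_networks,
         beta = gt$config$beta, n_planted = gt$config$n_planted),
    file.path(dir, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(
    list(n = nrow(cohort$phenotype), n_nodes = nrow(cohort$atlas),
         seed = cohort$seed),
    file.path(dir, "cohort.json"), auto_unbox = TRUE)
  if (scans) {
    n_nodes <- nrow(cohort$atlas)
    rows <- list()
    for (s in seq_along(cohort$scan_edges)) {
      lab <- c("rest", "face_matching", "srdc")[((s - 1L) %% 3L) + 1L]
      for (i in seq_len(nrow(cohort$phenotype))) {
        id <- cohort$phenotype$subject_id[i]
        fn <- sprintf("%s_%s.tsv", id, lab)
        cn <- new_connectome(devectorize_edges(cohort$scan_edges[[s]][i, ], n_nodes),
                             id, cohort$atlas$node_id)
        write_connectome(cn, file.path(dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, scan_label = lab, path = fn, valid = TRUE)
      }
    }
    write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return List with `phenotype`, `atlas`, `edges` (and `seed`, `n_nodes`).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  list(phenotype = read_phenotype(file.path(dir, "phenotype.csv")),
       atlas = read_atlas(file.path(dir, "atlas.csv")),
       edges = read_edges_table(file.path(dir, "edges.tsv")),
       seed = meta$seed, n_nodes = meta$n_nodes)
}

#' Percentage of a count, rounded as reported
#'
#' @param count Numerator count(s).
#' @param total Denominator count.
#' @param digits Decimal places (default 1, the usual reporting precision).
#' @return `round(100 * count / total, digits)`.
#' @examples
#' count_pct(136, 162)  # 84.0
#' @export
count_pct <- function(count, total, digits = 1) {
  if (total <= 0) stop("`total` must be positive", call. = FALSE)
  round(100 * count / total, digits)
}

#' Cohort-flow arithmetic summary
#'
#' Given the assessed count, exclusion counts and follow-up completer
#' counts, recomputes the post-exclusion sample size and the retention and
#' attrition percentages used in cohort-flow reporting.
#'
#' @param n_assessed Subjects assessed at baseline.
#' @param n_excluded Named or unnamed vector of exclusion counts.
#' @param n_completed_6m,n_completed_14m Follow-up completer counts.
#' @return List: `n_final`, `retention_6m_pct`, `retention_14m_pct`,
#'   `lost_pct`.
#' @export
cohort_flow <- function(n_assessed, n_excluded, n_completed_6m, n_completed_14m) {
  n_final <- n_assessed - sum(n_excluded)
  list(n_final = n_final,
       retention_6m_pct = count_pct(n_completed_6m, n_final),
       retention_14m_pct = count_pct(n_completed_14m, n_final),
       lost_pct = count_pct(n_final - n_completed_14m, n_final))
}
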