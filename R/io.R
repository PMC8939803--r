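series_header <- c("time_s", "n_clusters_per_mm2", "mean_cluster_size_cells",
                   "n_platelet_per_ul")

#' Write / read a deposition series as CSV
#'
#' The on-disk format is a strict four-column CSV (`time_s`,
#' `n_clusters_per_mm2`, `mean_cluster_size_cells`, `n_platelet_per_ul`).
#' `write_series()` also writes a JSON sidecar `<path>.json` with the series
#' metadata when present.
#'
#' @param series a `"deposition_series"`.
#' @param path output CSV path.
#' @return `write_series()` the path invisibly; `read_series()` a validated
#'   `"deposition_series"`.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)[series_header]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- attr(series, "meta")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), series_header))
    stop("bad series header in ", path, ": expected ",
         paste(series_header, collapse = ", "), call. = FALSE)
  for (cn in series_header) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad))
      stop("non-numeric or missing value in column ", cn, ", row ", bad[1],
           " of ", path, call. = FALSE)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    ord <- which(diff(df$time_s) <= 0)[1] + 1
    stop("times not strictly increasing at row ", ord, " of ", path,
         call. = FALSE)
  }
  if (any(df$n_clusters_per_mm2 < 0) || any(df$mean_cluster_size_cells < 0) ||
      any(df$n_platelet_per_ul < 0))
    stop("negative observable in ", path, call. = FALSE)
  meta_path <- paste0(path, ".json")
  class(df) <- c("deposition_series", "data.frame")
  if (file.exists(meta_path))
    attr(df, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df
}

#' Write a cohort to a directory / read a cohort manifest
#'
#' `write_cohort()` writes one series CSV per subject plus a manifest CSV
#' (`subject_id`, `group`, `series_path`, true parameter columns when
#' recorded).  `read_cohort_manifest()` loads and validates the manifest
#' and all series, enforcing a common observation grid and unique subject
#' ids.
#'
#' @param cohort a `"cohort_dataset"` with simulated series.
#' @param dir output directory (created if missing).
#' @param path manifest CSV path.
#' @return `write_cohort()` the manifest path invisibly;
#'   `read_cohort_manifest()` a `"cohort_dataset"`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"), !is.null(cohort$series))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subjects$subject_id, ".csv"))
  for (i in seq_along(cohort$series))
    write_series(cohort$series[[i]], paths[i])
  manifest <- cbind(cohort$subjects,
                    series_path = basename(paths),
                    as.data.frame(cohort$true_params, row.names = FALSE))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname write_cohort
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "series_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject_id in manifest: ",
         man$subject_id[duplicated(man$subject_id)][1], call. = FALSE)
  base <- dirname(path)
  series <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sp <- man$series_path[i]
    if (!file.exists(file.path(base, sp)) && !file.exists(sp))
      stop("missing series file for subject ", man$subject_id[i], ": ", sp,
           call. = FALSE)
    series[[i]] <- read_series(if (file.exists(file.path(base, sp)))
      file.path(base, sp) else sp)
  }
  names(series) <- man$subject_id
  t0 <- series[[1]]$time_s
  for (i in seq_along(series))
    if (!isTRUE(all.equal(series[[i]]$time_s, t0)))
      stop("subject ", man$subject_id[i],
           " has an inconsistent observation grid", call. = FALSE)
  tp <- NULL
  if (all(param_names() %in% names(man)))
    tp <- as.matrix(man[param_names()])
  structure(list(subjects = man[c("subject_id", "group")], series = series,
                 true_params = tp, spec = NULL),
            class = "cohort_dataset")
}

#' Serialize / load a summary projection as JSON
#'
#' @param proj a `"summary_projection"`.
#' @param path JSON file path.
#' @return `write_projection()` the path invisibly; `read_projection()` the
#'   restored `"summary_projection"`.
#' @export
write_projection <- function(proj, path) {
  payload <- list(L = proj$L,
                  expansion = unclass(proj$expansion),
                  constants = proj$constants,
                  k_neighbors = proj$k_neighbors,
                  regularization = proj$regularization,
                  objective = proj$objective,
                  input_dim = proj$input_dim)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  exp <- feature_expansion(orders = p$expansion$orders,
                           cross_products = p$expansion$cross_products,
                           standardize = p$expansion$standardize)
  structure(list(L = matrix(unlist(p$L), nrow = nrow(p$L), byrow = FALSE),
                 expansion = exp, constants = p$constants,
                 k_neighbors = p$k_neighbors,
                 regularization = p$regularization,
                 objective = p$objective, input_dim = p$input_dim),
            class = "summary_projection")
}

#' Write / read posterior samples as CSV
#'
#' One row per sample: the seven parameter columns plus the final summary
#' distance.
#'
#' @param samples a `"posterior_samples"` (or `"abc_fit"`).
#' @param path CSV path.
#' @return `write_posterior()` the path invisibly; `read_posterior()` a
#'   `"posterior_samples"`.
#' @export
write_posterior <- function(samples, path) {
  if (inherits(samples, "abc_fit")) samples <- samples$posterior
  df <- as.data.frame(samples$samples)
  df$distance <- samples$distances
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  df <- utils::read.csv(path)
  if (!all(param_names() %in% names(df)))
    stop("posterior CSV must contain the 7 parameter columns", call. = FALSE)
  new_posterior_samples(as.matrix(df[param_names()]),
                        if ("distance" %in% names(df)) df$distance else
                          rep(NA_real_, nrow(df)),
                        epsilon_schedule = NA_real_,
                        acceptance_rate = NA_real_, method = "loaded",
                        subject_id = NULL, seed = NULL)
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seeds, input file hashes
#' and package version of a pipeline invocation, so that reruns with an
#' identical manifest reproduce outputs bit-for-bit for deterministic
#' stages.
#'
#' @param path output JSON path.
#' @param command the command or stage name.
#' @param config any serializable configuration snapshot.
#' @param seed the seed(s) in use.
#' @param inputs character vector of input file paths (hashed if present).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, config = NULL, seed = NULL,
                               inputs = character(0)) {
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_, "")
  manifest <- list(command = command, config = config, seed = seed,
                   inputs = as.list(hashes),
                   package_version = as.character(
                     utils::packageVersion("plateletABC")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
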