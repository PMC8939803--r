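#' Specification of a synthetic cohort
#'
#' Describes a labelled cohort in which every subject's true parameter
#' vector is drawn from a group-specific centre with small dispersion, the
#' working assumption behind group-level comparison of per-subject
#' estimates.  Parameters are drawn from independent normal distributions
#' truncated to `[0, inf)` and to the prior support, so a cohort is a
#' plausible draw from the hierarchical picture the group tests assume.
#'
#' The default groups mimic a three-arm study (healthy volunteers, dialysis
#' patients, COPD patients) whose centres differ mainly in the aggregation
#' rate `p_Ag`, the albumin attenuation `a_T` and the non-activated platelet
#' speed `vzNAP` — the biologically discriminating parameters — with
#' dispersions chosen so that the group distributions overlap partially.
#'
#' @param groups named list; each element is a list with elements `center`
#'   (a [deposition_params()]) and `dispersion` (named per-parameter
#'   standard deviations; parameters omitted get 0).
#' @param n_per_group subjects per group.
#' @param config the [device_config()] used to simulate every subject.
#' @param prior a [prior_spec()]; centres must lie inside its support, and
#'   draws are truncated to it.
#' @param seed integer seed making the cohort reproducible.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups = default_cohort_groups(), n_per_group = 16,
                        config = device_config(), prior = prior_spec(),
                        seed = 1) {
  stopifnot(length(groups) >= 1, n_per_group >= 1)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list", call. = FALSE)
  for (g in names(groups)) {
    center <- as_params(groups[[g]]$center)
    disp <- groups[[g]]$dispersion
    if (is.null(disp)) disp <- numeric(0)
    if (any(disp < 0)) stop("dispersions must be >= 0", call. = FALSE)
    full <- stats::setNames(numeric(7), param_names())
    full[names(disp)] <- disp
    lo <- prior$bounds[, "low"]; hi <- prior$bounds[, "high"]
    if (any(center < lo) || any(center > hi))
      stop("group centre for '", g, "' lies outside the prior support",
           call. = FALSE)
    groups[[g]]$center <- center
    groups[[g]]$dispersion <- full
  }
  structure(list(groups = groups, n_per_group = n_per_group, config = config,
                 prior = prior, seed = seed), class = "cohort_spec")
}

#' Default group centres of the synthetic cohort
#'
#' Three parameter centres differing mainly in `p_Ag` (aggregation), `a_T`
#' (albumin attenuation) and `vzNAP` (non-activated platelet speed);
#' adhesion, on-top deposition, albumin fill rate and activated-platelet
#' speed are shared.
#'
#' @return A named list of group definitions usable as the `groups` argument
#'   of [cohort_spec()].
#' @export
default_cohort_groups <- function() {
  # Centres sit in the albumin-competition regime (fast albumin fill,
  # strong attenuation) where adhesion and aggregation compete with surface
  # fouling over the whole run -- the regime in which the deposition data
  # actually inform p_Ag and a_T rather than being transport-limited.
  disp <- c(p_Ad = 4, p_Ag = 3, p_T = 0.15, p_F = 0.02, a_T = 0.4,
            vzAP = 5e-5, vzNAP = 3e-5)
  list(
    healthy = list(
      center = deposition_params(50, 15, 1.0, 0.2, 6.0, 6e-4, 3.5e-4),
      dispersion = disp),
    dialysis = list(
      center = deposition_params(50, 18, 1.0, 0.2, 8.0, 6e-4, 2.5e-4),
      dispersion = disp),
    copd = list(
      center = deposition_params(50, 60, 1.0, 0.2, 6.5, 6e-4, 5.0e-4),
      dispersion = disp)
  )
}

# one-sided rejection sampler for a normal truncated to [lo, hi]
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Draw true parameter vectors for one group
#'
#' @param group a single element of `spec$groups`.
#' @param n number of subjects.
#' @param prior a [prior_spec()] supplying truncation bounds.
#' @return An `n x 7` matrix of parameter vectors.
#' @export
draw_group_params <- function(group, n, prior = prior_spec()) {
  center <- as_params(group$center)
  disp <- stats::setNames(numeric(7), param_names())
  disp[names(group$dispersion)] <- group$dispersion
  lo <- prior$bounds[, "low"]; hi <- prior$bounds[, "high"]
  out <- matrix(NA_real_, n, 7, dimnames = list(NULL, param_names()))
  for (j in seq_len(7))
    out[, j] <- rtruncnorm1(n, center[[j]], disp[[j]],
                            max(0, lo[[j]]), hi[[j]])
  out
}

#' Generate a labelled synthetic cohort
#'
#' For every group draws `n_per_group` true parameter vectors around the
#' group centre and (optionally) forward-simulates one deposition time
#' series per subject.  The true parameters are recorded so that parameter
#' recovery can be verified downstream.
#'
#' @param spec a [cohort_spec()].
#' @param simulate simulate the series (`TRUE`) or return parameters only?
#' @return A list of class `"cohort_dataset"` with elements `subjects`
#'   (data frame: `subject_id`, `group`), `series` (list of
#'   `"deposition_series"`, `NULL` when `simulate = FALSE`), `true_params`
#'   (n x 7 matrix) and `spec`.
#' @examples
#' sp <- cohort_spec(n_per_group = 2,
#'                   config = device_config(scale = 0.05, dt = 0.1,
#'                                          end_time = 20,
#'                                          obs_times = c(0, 10, 20)))
#' generate_cohort(sp)
#' @export
generate_cohort <- function(spec, simulate = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  labels <- names(spec$groups)
  n <- spec$n_per_group * length(labels)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(labels, each = spec$n_per_group),
    stringsAsFactors = FALSE)
  tp <- do.call(rbind, lapply(labels, function(g)
    draw_group_params(spec$groups[[g]], spec$n_per_group, spec$prior)))
  rownames(tp) <- subjects$subject_id
  sim_seeds <- sample.int(.Machine$integer.max, n)
  series <- NULL
  if (simulate) {
    series <- lapply(seq_len(n), function(i)
      simulate_deposition(as_params(tp[i, ]), spec$config,
                          seed = sim_seeds[i]))
    names(series) <- subjects$subject_id
  }
  structure(list(subjects = subjects, series = series, true_params = tp,
                 spec = spec, sim_seeds = sim_seeds),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic deposition cohort: ", nrow(x$subjects), " subjects in ",
      length(unique(x$subjects$group)), " groups (",
      paste(table(x$subjects$group), collapse = "/"), ")\n", sep = "")
  if (is.null(x$series)) cat("  (parameters only, no simulated series)\n")
  invisible(x)
}

# n x 12 matrix of flattened series, rows = subjects
cohort_feature_matrix <- function(cohort) {
  if (is.null(cohort$series))
    stop("cohort has no simulated series", call. = FALSE)
  t(vapply(cohort$series, series_to_vector,
           numeric(3 * length(cohort$series[[1]]$time_s))))
}
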