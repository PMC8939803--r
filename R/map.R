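#' MAP estimate from an ABC posterior sample cloud
#'
#' Smooths the posterior sample cloud with a Gaussian kernel density
#' estimator (bandwidth 0.45 on per-coordinate standardized samples, since
#' the raw coordinates span ~1e-4 to ~1e2) and reports the mode, located by
#' Nelder-Mead started from the highest-density samples, as the parameter
#' estimate.  Under a uniform prior this mode is also the approximate
#' maximum likelihood estimate.
#'
#' @param samples a `"posterior_samples"` (or `"abc_fit"`) with at least 10
#'   samples.
#' @param bandwidth kernel bandwidth on the standardized scale.
#' @param prior optional [prior_spec()]; the mode is clipped back to its
#'   support (with a warning) if the optimizer exits it.
#' @param n_starts number of highest-density samples used as Nelder-Mead
#'   starting points (the best result is kept; the search is local).
#' @return A list of class `"map_estimate"` with `theta_hat`
#'   (a [deposition_params()]), `log_density`, `bandwidth` and the
#'   optimizer iteration count.
#' @export
map_estimate <- function(samples, bandwidth = 0.45, prior = NULL,
                         n_starts = 5) {
  if (inherits(samples, "abc_fit")) samples <- samples$posterior
  subject_id <- if (inherits(samples, "posterior_samples"))
    samples$subject_id else NULL
  x <- if (inherits(samples, "posterior_samples")) samples$samples else
    as.matrix(samples)
  z <- nrow(x)
  if (z < 10) stop("need at least 10 posterior samples", call. = FALSE)
  d <- ncol(x)

  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  fixed <- sc == 0 | !is.finite(sc)
  sc[fixed] <- 1
  zs <- sweep(sweep(x, 2, ctr), 2, sc, "/")
  free <- which(!fixed)

  # log of the product-Gaussian KDE on standardized coordinates (additive
  # constants dropped; only the argmax matters)
  log_kde <- function(u_free) {
    u <- numeric(d)
    u[free] <- u_free
    sq <- colSums((t(zs) - u)[free, , drop = FALSE]^2)
    m <- -sq / (2 * bandwidth^2)
    mx <- max(m)
    mx + log(sum(exp(m - mx)))
  }

  wrap_theta <- function(theta) {
    if (length(theta) == 7 && identical(names(theta), param_names()))
      as_params(theta)
    else theta
  }
  if (length(free) == 0) {
    theta <- ctr
    return(structure(list(theta_hat = wrap_theta(theta), log_density = Inf,
                          bandwidth = bandwidth, iterations = 0L,
                          subject_id = subject_id),
                     class = "map_estimate"))
  }

  dens_at <- apply(zs[, free, drop = FALSE], 1, log_kde)
  starts <- order(dens_at, decreasing = TRUE)[seq_len(min(n_starts, z))]
  best <- NULL
  iters <- 0L
  if (length(free) == 1) {
    # one free coordinate: golden-section search over the sample range
    rng <- range(zs[, free]) + c(-1, 1) * bandwidth
    o <- stats::optimize(function(u) -log_kde(u), interval = rng,
                         tol = 1e-10)
    best <- list(par = o$minimum, value = o$objective)
    iters <- NA_integer_
  } else {
    for (s in starts) {
      o <- stats::optim(zs[s, free], function(u) -log_kde(u),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
      iters <- iters + o$counts[[1]]
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  u <- numeric(d)
  u[free] <- best$par
  theta <- u * sc + ctr
  theta[fixed] <- ctr[fixed]
  names(theta) <- colnames(x)
  if (!is.null(prior)) {
    b <- prior$bounds
    clipped <- theta < b[, "low"] | theta > b[, "high"]
    if (any(clipped)) {
      warning("MAP left the prior support for ",
              paste(names(theta)[clipped], collapse = ", "),
              "; clipped back", call. = FALSE)
      theta <- pmin(pmax(theta, b[, "low"]), b[, "high"])
    }
  }
  structure(list(theta_hat = wrap_theta(theta), log_density = -best$value,
                 bandwidth = bandwidth, iterations = iters,
                 subject_id = subject_id),
            class = "map_estimate")
}

#' @export
print.map_estimate <- function(x, ...) {
  cat("MAP estimate (KDE bandwidth ", x$bandwidth, " on standardized ",
      "coordinates):\n", sep = "")
  print(signif(unclass(x$theta_hat), 4))
  invisible(x)
}

#' MAP estimates for a whole cohort
#'
#' Runs per-subject ABC inference and MAP estimation across a cohort,
#' producing the table consumed by the group analysis.
#'
#' @param cohort a `"cohort_dataset"` with simulated series.
#' @param proj a `"summary_projection"` (or `NULL` for raw distance).
#' @param prior a [prior_spec()].
#' @param config simulation configuration for the inference runs (defaults
#'   to the cohort's own).
#' @param method inference engine: per-subject SABC (`"sabc"`), per-subject
#'   rejection ABC (`"rejection"`), or `"table_sabc"` — a shared
#'   prior-predictive screening pool warm-starts an independent per-subject
#'   SABC refresh (the cohort-scale workhorse).
#' @param ... passed to the underlying sampler ([sabc_sample()] /
#'   [abc_rejection()]).
#' @param table_n,n_accept screening-pool size and per-subject warm-start
#'   size for `"table_sabc"`.
#' @param seed master seed; per-subject seeds are derived from it, so
#'   subject-level inference is order-independent.
#' @param verbose print one line per subject?
#' @return A data frame (class `"map_table"`): `subject_id`, `group`, one
#'   column per parameter.
#' @export
cohort_map_estimates <- function(cohort, proj = NULL, prior = prior_spec(),
                                 config = NULL,
                                 method = c("sabc", "rejection",
                                            "table_sabc"), ...,
                                 table_n = 600, n_accept = 32, seed = 1,
                                 verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  method <- match.arg(method)
  if (is.null(config)) config <- cohort$spec$config
  n <- nrow(cohort$subjects)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  table_seed <- sample.int(.Machine$integer.max, 1)
  res <- matrix(NA_real_, n, 7, dimnames = list(NULL, param_names()))
  tab <- NULL
  if (method == "table_sabc") {
    # one shared prior-predictive screening pool initializes every
    # subject's particle population; the per-subject annealing then
    # re-simulates independently, so subjects remain exchangeable
    tab <- reference_table(prior = prior, config = config, n = table_n,
                           seed = table_seed)
  }
  for (i in seq_len(n)) {
    if (method == "table_sabc") {
      init <- abc_rejection_table(cohort$series[[i]], tab, proj = proj,
                                  n_accept = n_accept)
      post <- sabc_sample(cohort$series[[i]], prior = prior, proj = proj,
                          config = config, ..., init_samples = init,
                          seed = sub_seeds[i],
                          subject_id = cohort$subjects$subject_id[i])
      res[i, ] <- unclass(map_estimate(post, prior = prior)$theta_hat)
    } else {
      fit <- abc_fit(cohort$series[[i]], prior = prior, proj = proj,
                     config = config, method = method, ...,
                     seed = sub_seeds[i],
                     subject_id = cohort$subjects$subject_id[i])
      res[i, ] <- coef(fit)
    }
    if (verbose)
      cat(sprintf("  %s (%s): done\n", cohort$subjects$subject_id[i],
                  cohort$subjects$group[i]))
  }
  out <- cbind(cohort$subjects, as.data.frame(res))
  class(out) <- c("map_table", "data.frame")
  out
}
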