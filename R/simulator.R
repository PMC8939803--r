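#' @useDynLib plateletABC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Initialize a simulation state
#'
#' Builds the particle and substrate state for a fresh run: activated and
#' non-activated platelets are placed uniformly at random in the chamber,
#' the substrate is empty and the albumin surface density is zero.  Particle
#' counts are the initial concentrations times the simulated volume, rounded
#' to the nearest integer.
#'
#' @param config a [device_config()].
#' @return A list of class `"sim_state"` with elements `ap`, `nap` (n x 3
#'   position matrices, micrometres), `trapped_ap`, `trapped_nap`,
#'   `substrate` (integer grid matrices), `rho_al` (numeric grid matrix),
#'   `deposited_ap`, `deposited_nap` and the clock `t`.
#' @export
init_state <- function(config) {
  validate_config(config)
  g <- grid_geometry(config)
  n_ap <- as.integer(round(config$init_AP * g$volume_ul))
  n_nap <- as.integer(round(config$init_NAP * g$volume_ul))
  if (n_ap + n_nap == 0L)
    stop("initial particle counts are zero at this scale; increase `scale`",
         call. = FALSE)
  rand_pos <- function(n) {
    cbind(x = stats::runif(n, 0, g$nx * g$side),
          y = stats::runif(n, 0, g$ny * g$side),
          z = stats::runif(n, 0, config$height))
  }
  structure(list(
    ap = rand_pos(n_ap), nap = rand_pos(n_nap),
    trapped_ap = matrix(0L, g$nx, g$ny), trapped_nap = matrix(0L, g$nx, g$ny),
    substrate = matrix(0L, g$nx, g$ny), rho_al = matrix(0, g$nx, g$ny),
    deposited_ap = 0L, deposited_nap = 0L, t = 0,
    n_ap0 = n_ap, n_nap0 = n_nap
  ), class = "sim_state")
}

#' One transport step of the bulk platelets
#'
#' Advances every bulk platelet by one random-walk jump superimposed on the
#' shear flow: `dz = lambda*v_z*|s|*dt`, `dx = v_xy*|s|*cos(2*pi*r)*dt +
#' shear*z*dt`, `dy = v_xy*|s|*sin(2*pi*r)*dt`, with `lambda = +/-1`
#' equiprobable, `s` standard normal and `r` uniform; one shared `|s|` draw
#' per particle serves the vertical and horizontal jumps, and `v_xy = v_z`
#' per species.  x and y are periodic, the top wall reflects, and platelets
#' crossing `z = 0` are removed from the bulk and become trapped deposition
#' candidates of the substrate cell beneath them (they are never
#' re-injected).
#'
#' @param state a `"sim_state"`.
#' @param params a [deposition_params()].
#' @param config a [device_config()].
#' @return The advanced `"sim_state"` (input is not modified).
#' @export
step_transport <- function(state, params, config) {
  params <- as_params(params)
  g <- grid_geometry(config)
  res <- cpp_transport(state$ap, state$nap,
                       params[["vzAP"]] * 1e6, params[["vzNAP"]] * 1e6,
                       config$shear_rate, config$dt, config$height,
                       state$trapped_ap, state$trapped_nap, g$side)
  state$ap <- res$ap
  state$nap <- res$nap
  state$trapped_ap <- res$trapped_ap
  state$trapped_nap <- res$trapped_nap
  state$t <- state$t + config$dt
  state
}

#' One deposition sweep over the substrate
#'
#' Applies, in order: (a) the mean-field albumin update
#' `rho_al <- rho_al + p_F*(rho_max - rho_al)*dt`; (b) adhesion - each
#' trapped activated platelet over a platelet-free cell seeds a new cluster
#' with probability `p_Ad*exp(-a_T*rho_al/rho_max)*dt`; (c) aggregation -
#' trapped platelets of either species over a free cell adjacent to a
#' deposit join it with probability `p_Ag*exp(-a_T*rho_al/rho_max)*dt`;
#' (d) on-top deposition with probability `p_T*dt`, incrementing the stack
#' height.  Probabilities are clamped to `[0, 1]` (a warning is raised when
#' clamping occurs); failed candidates remain trapped and deposited
#' platelets are permanently removed from the trapped pool.
#'
#' @inheritParams step_transport
#' @return The advanced `"sim_state"`.
#' @export
step_deposition <- function(state, params, config) {
  params <- as_params(params)
  res <- cpp_deposit(state$trapped_ap, state$trapped_nap, state$substrate,
                     state$rho_al, params[["p_Ad"]], params[["p_Ag"]],
                     params[["p_T"]], params[["p_F"]], params[["a_T"]],
                     config$dt, config$rho_max, config$connectivity)
  if (isTRUE(res$clamped))
    warning("a deposition probability exceeded 1 and was clamped; ",
            "consider a smaller dt", call. = FALSE)
  state$trapped_ap <- res$trapped_ap
  state$trapped_nap <- res$trapped_nap
  state$substrate <- res$substrate
  state$rho_al <- res$rho_al
  state$deposited_ap <- state$deposited_ap + res$deposited_ap
  state$deposited_nap <- state$deposited_nap + res$deposited_nap
  state
}

#' Cluster statistics of a substrate occupancy grid
#'
#' Connected components of cells with stack height >= 1 under the configured
#' adjacency (wrapping periodically in x and y to match the transport
#' boundary conditions unless `wrap = FALSE`).
#'
#' @param substrate integer matrix of per-cell stack heights.
#' @param config a [device_config()]; supplies the adjacency and the cell
#'   area used for the per-mm2 normalization.
#' @param wrap should adjacency wrap around the grid edges?
#' @return A list with `n_clusters` (component count), `n_clusters_per_mm2`
#'   (count divided by the grid area) and `mean_cluster_size_cells`
#'   (mean component size; 0 for an empty substrate).
#' @export
cluster_statistics <- function(substrate, config, wrap = TRUE) {
  stopifnot(is.matrix(substrate), all(substrate >= 0))
  res <- cpp_cluster_stats(matrix(as.integer(substrate), nrow(substrate)),
                           config$connectivity, wrap)
  area_mm2 <- nrow(substrate) * ncol(substrate) * config$cell_area / 1e6
  list(n_clusters = res$n_clusters,
       n_clusters_per_mm2 = res$n_clusters / area_mm2,
       mean_cluster_size_cells = res$mean_size)
}

#' Forward-simulate the platelet deposition experiment
#'
#' Runs the full stochastic model from `t = 0` to `end_time`, alternating
#' transport and deposition sweeps, and records the three observables at the
#' configured observation times: the number of aggregation clusters per mm2,
#' their mean size (in substrate cells of `cell_area` each), and the number
#' of non-activated platelets per microlitre still in suspension (see
#' `count_trapped`).
#'
#' @param params a [deposition_params()] (or coercible named vector).
#' @param config a [device_config()].
#' @param seed optional integer seed; falls back to `config$seed`.  With a
#'   seed the run is fully reproducible.
#' @param count_trapped count platelets trapped at the cell-free layer (but
#'   not yet deposited) as still in suspension?  The default `FALSE`
#'   reports only the bulk: trapped platelets sit at the wall and would not
#'   appear in a recovered suspension sample, and counting them hides the
#'   arrival flux that identifies `vzNAP`.
#' @param keep_state return the final `"sim_state"` as attribute `"state"`?
#' @return A data frame of class `"deposition_series"` with columns
#'   `time_s`, `n_clusters_per_mm2`, `mean_cluster_size_cells`,
#'   `n_platelet_per_ul`, and attribute `meta` (initial concentrations,
#'   volume, counts, clamping flag).
#' @examples
#' cfg <- device_config(scale = 0.05, dt = 0.1, end_time = 20,
#'                      obs_times = c(0, 10, 20))
#' th <- deposition_params(40, 20, 1, 5e-3, 3, 2e-4, 8e-5)
#' simulate_deposition(th, cfg, seed = 1)
#' @export
simulate_deposition <- function(params, config, seed = NULL,
                                count_trapped = FALSE, keep_state = FALSE) {
  params <- as_params(params)
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  g <- grid_geometry(config)
  n_steps_real <- config$end_time / config$dt
  n_steps <- as.integer(round(n_steps_real))
  if (abs(n_steps_real - n_steps) > 1e-8)
    warning("end_time is not a multiple of dt; using ", n_steps, " steps",
            call. = FALSE)
  n_ap <- as.integer(round(config$init_AP * g$volume_ul))
  n_nap <- as.integer(round(config$init_NAP * g$volume_ul))
  if (n_ap + n_nap == 0L)
    stop("initial particle counts are zero at this scale; increase `scale`",
         call. = FALSE)
  obs_steps <- as.integer(round(config$obs_times / config$dt))
  res <- cpp_simulate(n_ap, n_nap, params[["vzAP"]] * 1e6,
                      params[["vzNAP"]] * 1e6, config$shear_rate, config$dt,
                      n_steps, config$height, g$nx, g$ny, g$side,
                      params[["p_Ad"]], params[["p_Ag"]], params[["p_T"]],
                      params[["p_F"]], params[["a_T"]], config$rho_max,
                      config$connectivity, obs_steps, g$area_mm2, g$volume_ul,
                      count_trapped)
  out <- data.frame(time_s = config$obs_times,
                    n_clusters_per_mm2 = res$n_clusters,
                    mean_cluster_size_cells = res$mean_cluster_size,
                    n_platelet_per_ul = res$n_platelet)
  class(out) <- c("deposition_series", "data.frame")
  attr(out, "meta") <- list(init_NAP = config$init_NAP,
                            init_AP = config$init_AP,
                            init_albumin = config$init_albumin,
                            volume_ul = g$volume_ul,
                            n_ap0 = n_ap, n_nap0 = n_nap,
                            deposited_ap = res$deposited_ap,
                            deposited_nap = res$deposited_nap,
                            clamped = isTRUE(res$clamped), seed = seed)
  if (keep_state)
    attr(out, "state") <- res[c("substrate", "rho_al", "trapped_ap",
                                "trapped_nap", "bulk_ap", "bulk_nap")]
  out
}

#' @export
print.deposition_series <- function(x, ...) {
  cat("Platelet deposition time series:\n")
  print.data.frame(x, row.names = FALSE, ...)
  m <- attr(x, "meta")
  if (!is.null(m))
    cat(sprintf("  (volume %.4g ul; %d AP + %d NAP simulated)\n",
                m$volume_ul, m$n_ap0, m$n_nap0))
  invisible(x)
}

# Flattens the three observables into the vector fed to feature expansion;
# column-major over (observable, time): all cluster counts, then sizes,
# then platelet counts.
series_to_vector <- function(series) {
  v <- c(series$n_clusters_per_mm2, series$mean_cluster_size_cells,
         series$n_platelet_per_ul)
  names(v) <- c(paste0("nclust_t", series$time_s),
                paste0("size_t", series$time_s),
                paste0("nplat_t", series$time_s))
  v
}
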