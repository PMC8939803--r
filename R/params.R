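#' Parameter vector of the stochastic platelet deposition model
#'
#' Bundles the seven biologically meaningful parameters governing platelet
#' transport and deposition in the shear device: adhesion of activated
#' platelets onto free substrate, aggregation beside and on top of existing
#' deposits, albumin surface fouling, and the characteristic vertical speeds
#' of activated (AP) and non-activated (NAP) platelets.
#'
#' @param p_Ad adhesion rate of AP onto platelet-free substrate, 1/s.
#' @param p_Ag aggregation rate beside an already deposited platelet, 1/s.
#' @param p_T rate of depositing on top of an existing cluster, 1/s.
#' @param p_F albumin fill rate, 1/s: the per-cell albumin density relaxes to
#'   its saturation value `rho_max` as `rho_max * (1 - exp(-p_F * t))`.
#' @param a_T attenuation factor, dimensionless: platelet adhesion and
#'   aggregation probabilities are damped by `exp(-a_T * rho_al/rho_max)`,
#'   i.e. by `exp(-a_T)` at full albumin coverage.
#' @param vzAP,vzNAP characteristic vertical speeds of AP and NAP, m/s.
#'
#' @return A named numeric vector of class `"deposition_params"` with
#'   elements in the order `p_Ad, p_Ag, p_T, p_F, a_T, vzAP, vzNAP`.
#' @examples
#' deposition_params(p_Ad = 40, p_Ag = 20, p_T = 1, p_F = 5e-3,
#'                   a_T = 3, vzAP = 2e-4, vzNAP = 8e-5)
#' @export
deposition_params <- function(p_Ad, p_Ag, p_T, p_F, a_T, vzAP, vzNAP) {
  theta <- c(p_Ad = p_Ad, p_Ag = p_Ag, p_T = p_T, p_F = p_F, a_T = a_T,
             vzAP = vzAP, vzNAP = vzNAP)
  validate_params(theta)
  structure(theta, class = "deposition_params")
}

#' @export
print.deposition_params <- function(x, ...) {
  cat("Platelet deposition parameters (theta):\n")
  print(unclass(x), ...)
  invisible(x)
}

param_names <- function() {
  c("p_Ad", "p_Ag", "p_T", "p_F", "a_T", "vzAP", "vzNAP")
}

validate_params <- function(theta) {
  if (length(theta) != 7L)
    stop("theta must have exactly 7 components", call. = FALSE)
  if (!identical(names(theta), param_names()))
    stop("theta components must be named ", paste(param_names(), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(theta)))
    stop("all parameters must be finite", call. = FALSE)
  if (any(theta < 0))
    stop("all parameters must be >= 0 (got ",
         paste(names(theta)[theta < 0], collapse = ", "), " negative)",
         call. = FALSE)
  invisible(theta)
}

as_params <- function(x) {
  if (inherits(x, "deposition_params")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 7L) names(x) <- param_names()
  do.call(deposition_params, as.list(x[param_names()]))
}

#' Configuration of the simulated shear device
#'
#' Geometry, discretization and initial concentrations of the cone-and-plate
#' deposition chamber.  Defaults reproduce the full-size observation window
#' (1 x 1 mm, 0.82 mm high) at a reduced linear scale so that a single
#' forward run takes milliseconds rather than minutes; `scale = 1` restores
#' the full geometry.
#'
#' @param height chamber height, micrometres.
#' @param window_side side of the square observation window, micrometres.
#' @param shear_rate imposed shear rate, 1/s.
#' @param dt simulation time step, seconds.  All rate-times-dt deposition
#'   probabilities are clamped to `[0, 1]`; clamping is reported via the
#'   `clamped` attribute of the simulated series.
#' @param cell_area substrate cell area, square micrometres (one deposited
#'   platelet footprint).
#' @param rho_max maximum number of albumin particles per substrate cell.
#' @param init_NAP,init_AP initial non-activated / activated platelet
#'   concentrations, per microlitre.
#' @param init_albumin initial albumin concentration, per microlitre
#'   (metadata; albumin is modelled as a mean-field surface density).
#' @param obs_times observation times, seconds, sorted, within `[0, end_time]`.
#' @param end_time total simulated time, seconds.
#' @param scale linear scale factor of the simulated window; the simulated
#'   area scales as `scale^2` and particle counts with it.
#' @param seed optional integer seed used by [simulate_deposition()] when no
#'   explicit seed is given.
#' @param connectivity cluster adjacency on the substrate grid: 4 or 8.
#'
#' @return A list of class `"device_config"`.
#' @export
device_config <- function(height = 820, window_side = 1000, shear_rate = 100,
                          dt = 0.01, cell_area = 5, rho_max = 1e5,
                          init_NAP = 172200, init_AP = 4808,
                          init_albumin = 2.69e13,
                          obs_times = c(0, 20, 120, 300), end_time = 300,
                          scale = 0.1, seed = NULL, connectivity = 8) {
  cfg <- list(height = height, window_side = window_side,
              shear_rate = shear_rate, dt = dt, cell_area = cell_area,
              rho_max = rho_max, init_NAP = init_NAP, init_AP = init_AP,
              init_albumin = init_albumin, obs_times = obs_times,
              end_time = end_time, scale = scale, seed = seed,
              connectivity = connectivity)
  validate_config(cfg)
  structure(cfg, class = "device_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$height > 0, cfg$window_side > 0, cfg$dt > 0,
            cfg$cell_area > 0, cfg$scale > 0, cfg$rho_max >= 1,
            cfg$init_NAP >= 0, cfg$init_AP >= 0, cfg$end_time > 0,
            cfg$shear_rate >= 0)
  if (!cfg$connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (is.unsorted(cfg$obs_times, strictly = TRUE))
    stop("obs_times must be strictly increasing", call. = FALSE)
  if (any(cfg$obs_times < 0) || any(cfg$obs_times > cfg$end_time))
    stop("obs_times must lie within [0, end_time]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.device_config <- function(x, ...) {
  g <- grid_geometry(x)
  cat("Shear-device configuration:\n")
  cat(sprintf("  window %.0f x %.0f um (scale %.3g), height %.0f um\n",
              g$nx * g$side, g$ny * g$side, x$scale, x$height))
  cat(sprintf("  grid %d x %d cells of %.3g um^2, dt = %.3g s, T = %.4g s\n",
              g$nx, g$ny, x$cell_area, x$dt, x$end_time))
  cat(sprintf("  NAP %.4g /ul, AP %.4g /ul, shear %.4g /s, connectivity %d\n",
              x$init_NAP, x$init_AP, x$shear_rate, x$connectivity))
  invisible(x)
}

# Derived discretization: square cells of side sqrt(cell_area); the physical
# xy-domain is quantized to an integer number of cells, and the per-mm2 and
# per-ul normalizations use that quantized area/volume for consistency.
grid_geometry <- function(config) {
  side <- sqrt(config$cell_area)
  n <- max(1L, as.integer(round(config$window_side * config$scale / side)))
  area_mm2 <- (n * side)^2 / 1e6
  volume_ul <- (n * side)^2 * config$height / 1e9
  list(nx = n, ny = n, side = side, area_mm2 = area_mm2, volume_ul = volume_ul)
}
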