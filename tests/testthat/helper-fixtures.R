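# Shared fixtures: a desk-scale configuration fast enough for simulation-
# heavy tests, reference parameter vectors inside the identifiable regime,
# and brute-force oracles.

fast_config <- function(...) {
  device_config(scale = 0.05, dt = 0.1, ...)
}

base_params <- function(...) {
  th <- c(p_Ad = 50, p_Ag = 15, p_T = 1, p_F = 0.2, a_T = 6,
          vzAP = 6e-4, vzNAP = 3.5e-4)
  over <- c(...)
  th[names(over)] <- over
  do.call(deposition_params, as.list(th))
}

# a bare simulation state for targeted physics tests
manual_state <- function(config, ap = NULL, nap = NULL) {
  g <- plateletABC:::grid_geometry(config)
  empty <- matrix(numeric(0), 0, 3)
  structure(list(
    ap = if (is.null(ap)) empty else ap,
    nap = if (is.null(nap)) empty else nap,
    trapped_ap = matrix(0L, g$nx, g$ny),
    trapped_nap = matrix(0L, g$nx, g$ny),
    substrate = matrix(0L, g$nx, g$ny),
    rho_al = matrix(0, g$nx, g$ny),
    deposited_ap = 0L, deposited_nap = 0L, t = 0
  ), class = "sim_state")
}

# brute-force flood-fill oracle for cluster statistics (pure R)
oracle_clusters <- function(substrate, connectivity = 8, wrap = TRUE) {
  nx <- nrow(substrate); ny <- ncol(substrate)
  seen <- matrix(FALSE, nx, ny)
  offs <- if (connectivity == 8) {
    cbind(c(1, -1, 0, 0, 1, 1, -1, -1), c(0, 0, 1, -1, 1, -1, 1, -1))
  } else {
    cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  }
  sizes <- integer(0)
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (substrate[i0, j0] <= 0 || seen[i0, j0]) next
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        ii <- cur[1] + offs[k, 1]; jj <- cur[2] + offs[k, 2]
        if (wrap) {
          ii <- ((ii - 1) %% nx) + 1; jj <- ((jj - 1) %% ny) + 1
        } else if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        if (substrate[ii, jj] > 0 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(n = length(sizes), mean_size = if (length(sizes)) mean(sizes) else 0)
}

# 1-D Gaussian toy forward model on the 7-parameter interface: only the
# first coordinate matters, y ~ N(theta[1], 1)
toy_gaussian_simulator <- function(theta) stats::rnorm(1, theta[[1]], 1)

toy_prior <- function() {
  prior_spec(p_Ad = c(0, 20), p_Ag = c(0, 1), p_T = c(0, 1), p_F = c(0, 1),
             a_T = c(0, 1), vzAP = c(1e-6, 1e-2), vzNAP = c(1e-6, 1e-2))
}

# identity summary projection on z-scored raw features, built from a
# reference feature matrix
identity_projection <- function(x) {
  s <- plateletABC:::safe_scale(x)
  structure(list(
    L = diag(ncol(x)),
    expansion = feature_expansion(orders = 1, cross_products = FALSE,
                                  standardize = TRUE),
    constants = list(center_raw = s$center, scale_raw = s$scale,
                     center_exp = rep(0, ncol(x)),
                     scale_exp = rep(1, ncol(x))),
    k_neighbors = NA, regularization = NA, objective = NA,
    input_dim = ncol(x)), class = "summary_projection")
}
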