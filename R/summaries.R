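#' Polynomial feature expansion recipe
#'
#' The raw per-subject observable vector (three observables at each
#' observation time) is expanded into elementwise powers plus pairwise
#' cross products of the first-order features before the discriminative
#' projection is learned on top.
#'
#' @param orders integer set of elementwise polynomial powers; must contain 1.
#' @param cross_products include pairwise products of the order-1 features?
#' @param standardize z-score the raw vector (using training statistics)
#'   before powers and products are formed, and the expanded vector after.
#'   Without standardization the cubes of disparate observables (platelet
#'   counts ~1e5, cluster sizes ~1e1) would dominate every distance.
#' @return A list of class `"feature_expansion"`.
#' @export
feature_expansion <- function(orders = c(1, 2, 3), cross_products = TRUE,
                              standardize = TRUE) {
  orders <- sort(unique(as.integer(orders)))
  if (!1L %in% orders) stop("orders must contain 1", call. = FALSE)
  structure(list(orders = orders, cross_products = cross_products,
                 standardize = standardize), class = "feature_expansion")
}

# raw expansion without any standardization: [x^1 | x^2 | ... | cross]
expand_raw <- function(x, expansion) {
  if (any(!is.finite(x))) stop("non-finite input to feature expansion",
                               call. = FALSE)
  out <- unlist(lapply(expansion$orders, function(o) x^o), use.names = FALSE)
  if (expansion$cross_products && length(x) >= 2) {
    idx <- utils::combn(length(x), 2)
    out <- c(out, x[idx[1, ]] * x[idx[2, ]])
  }
  out
}

#' Expand a flattened series into polynomial features
#'
#' Concatenates the elementwise powers of `x` in increasing order and then
#' the pairwise cross products of the order-1 features, optionally
#' z-scoring with training constants carried by a fitted projection.
#'
#' @param x numeric vector (typically a flattened deposition series).
#' @param expansion a [feature_expansion()].
#' @param constants optional standardization constants (list with
#'   `center_raw`, `scale_raw`, `center_exp`, `scale_exp`) as stored in a
#'   fitted [fit_discriminative_projection()] object; required when
#'   `expansion$standardize` is `TRUE`.
#' @return Numeric feature vector of deterministic length.
#' @examples
#' expand_features(c(2, 3), feature_expansion(standardize = FALSE))
#' @export
expand_features <- function(x, expansion, constants = NULL) {
  x <- as.numeric(x)
  if (!expansion$standardize) return(expand_raw(x, expansion))
  if (is.null(constants))
    stop("standardizing expansion needs training constants; ",
         "fit a projection first or set standardize = FALSE", call. = FALSE)
  z <- (x - constants$center_raw) / constants$scale_raw
  e <- expand_raw(z, expansion)
  (e - constants$center_exp) / constants$scale_exp
}

# column scale with zero-variance guard
safe_scale <- function(m) {
  ctr <- colMeans(m)
  sc <- apply(m, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  list(center = ctr, scale = sc)
}

#' Learn a discriminative summary projection by large-margin metric learning
#'
#' Learns the linear map `L` (rows = summary dimensions) minimizing the
#' large-margin nearest neighbor (LMNN) objective on the expanded cohort
#' features: the pull term sums squared distances to each subject's
#' `k_neighbors` same-group target neighbours, and the push term penalizes,
#' with weight `regularization`, every impostor that comes within the unit
#' margin of a target-neighbour distance via the hinge
#' `[1 + d2(i,j) - d2(i,l)]+`.  The induced Mahalanobis matrix is
#' `M = L'L`, and the Euclidean distance between projected features is the
#' summary distance used for ABC.
#'
#' Optimization is (sub)gradient descent with an adaptive step size from a
#' principal-component initialization; target neighbours are fixed in the
#' input metric, impostors are re-detected every iteration.
#'
#' @param cohort a `"cohort_dataset"` with simulated series, or a list with
#'   elements `x` (n x p raw feature matrix) and `group` (labels) for
#'   pre-flattened data.
#' @param expansion a [feature_expansion()].
#' @param k_neighbors number of same-group target neighbours.
#' @param regularization weight of the push (impostor) term.
#' @param out_dim dimension of the summary space.
#' @param n_iter maximum gradient iterations.
#' @param seed seed controlling the (deterministic up to BLAS) fit.
#' @return A list of class `"summary_projection"` with the map `L`, the
#'   expansion recipe, the training standardization constants, and the
#'   final objective trajectory.
#' @export
fit_discriminative_projection <- function(cohort,
                                          expansion = feature_expansion(),
                                          k_neighbors = 3,
                                          regularization = 0.5,
                                          out_dim = 2, n_iter = 200,
                                          seed = 1) {
  if (inherits(cohort, "cohort_dataset")) {
    x_raw <- cohort_feature_matrix(cohort)
    y <- cohort$subjects$group
  } else {
    x_raw <- cohort$x
    y <- cohort$group
  }
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("need at least 2 groups to learn a discriminative projection",
         call. = FALSE)
  if (min(table(y)) <= k_neighbors)
    stop("k_neighbors must be smaller than the smallest group",
         call. = FALSE)
  set.seed(seed)

  # standardize raw -> expand -> standardize expanded (training constants)
  constants <- NULL
  if (expansion$standardize) {
    s1 <- safe_scale(x_raw)
    z <- sweep(sweep(x_raw, 2, s1$center), 2, s1$scale, "/")
  } else {
    z <- x_raw
  }
  e <- t(apply(z, 1, expand_raw, expansion = expansion))
  if (expansion$standardize) {
    s2 <- safe_scale(e)
    e <- sweep(sweep(e, 2, s2$center), 2, s2$scale, "/")
    constants <- list(center_raw = s1$center, scale_raw = s1$scale,
                      center_exp = s2$center, scale_exp = s2$scale)
  }
  n <- nrow(e); p <- ncol(e)
  out_dim <- min(out_dim, p)

  # fixed target neighbours in the input metric
  d_in <- as.matrix(stats::dist(e))
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    same <- setdiff(which(y == y[i]), i)
    targets[[i]] <- same[order(d_in[i, same])][seq_len(k_neighbors)]
  }
  diff_idx <- lapply(seq_len(n), function(i) which(y != y[i]))

  # PCA initialization (deterministic)
  pc <- stats::prcomp(e, center = FALSE, scale. = FALSE)
  L <- t(pc$rotation[, seq_len(out_dim), drop = FALSE])

  objective <- function(P) {
    # P: n x out_dim projected points
    pull <- 0; push <- 0
    for (i in seq_len(n)) {
      dij <- rowSums((P[targets[[i]], , drop = FALSE] -
                        matrix(P[i, ], k_neighbors, out_dim, byrow = TRUE))^2)
      pull <- pull + sum(dij)
      dil <- rowSums((P[diff_idx[[i]], , drop = FALSE] -
                        matrix(P[i, ], length(diff_idx[[i]]), out_dim,
                               byrow = TRUE))^2)
      for (jj in seq_along(dij))
        push <- push + sum(pmax(0, 1 + dij[jj] - dil))
    }
    pull + regularization * push
  }

  gradient <- function(L) {
    P <- e %*% t(L)
    G <- matrix(0, p, p) # gradient in M-space: sum of outer products
    add_pair <- function(G, i, j, w) {
      v <- e[i, ] - e[j, ]
      G + w * tcrossprod(v)
    }
    for (i in seq_len(n)) {
      dij <- rowSums((P[targets[[i]], , drop = FALSE] -
                        matrix(P[i, ], k_neighbors, out_dim, byrow = TRUE))^2)
      dil <- rowSums((P[diff_idx[[i]], , drop = FALSE] -
                        matrix(P[i, ], length(diff_idx[[i]]), out_dim,
                               byrow = TRUE))^2)
      for (jj in seq_len(k_neighbors)) {
        j <- targets[[i]][jj]
        G <- add_pair(G, i, j, 1)
        active <- which(1 + dij[jj] - dil > 0)
        for (l in diff_idx[[i]][active]) {
          G <- add_pair(G, i, j, regularization)
          G <- add_pair(G, i, l, -regularization)
        }
      }
    }
    2 * (L %*% G)
  }

  lr <- 1e-4
  obj <- objective(e %*% t(L))
  trace <- numeric(0)
  best_L <- L; best_obj <- obj
  for (it in seq_len(n_iter)) {
    Gr <- gradient(L)
    L_new <- L - lr * Gr
    obj_new <- objective(e %*% t(L_new))
    if (is.finite(obj_new) && obj_new <= obj) {
      L <- L_new; obj <- obj_new; lr <- lr * 1.05
      if (obj < best_obj) { best_obj <- obj; best_L <- L }
    } else {
      lr <- lr / 2
      if (lr < 1e-12) break
    }
    trace <- c(trace, obj)
    if (length(trace) > 10 &&
        abs(trace[length(trace) - 10] - obj) < 1e-8 * (1 + abs(obj))) break
  }
  structure(list(L = best_L, expansion = expansion, constants = constants,
                 k_neighbors = k_neighbors, regularization = regularization,
                 objective = best_obj, trace = trace,
                 input_dim = ncol(x_raw)),
            class = "summary_projection")
}

#' @export
print.summary_projection <- function(x, ...) {
  cat(sprintf(paste0("Discriminative summary projection: %d raw features ",
                     "-> %d expanded -> %d summary dims\n"),
              x$input_dim, ncol(x$L), nrow(x$L)))
  cat(sprintf("  k_neighbors = %d, push weight = %.3g, objective = %.4g\n",
              x$k_neighbors, x$regularization, x$objective))
  invisible(x)
}

#' Project one series (or raw feature vector) into the summary space
#'
#' @param x a `"deposition_series"` or numeric vector.
#' @param proj a fitted `"summary_projection"`.
#' @return Numeric vector of length `nrow(proj$L)`.
#' @export
project_summary <- function(x, proj) {
  if (inherits(x, "deposition_series")) x <- series_to_vector(x)
  f <- expand_features(as.numeric(x), proj$expansion, proj$constants)
  unname(drop(proj$L %*% f))
}

#' Summary distance between two series
#'
#' Euclidean distance between the projected expanded features,
#' `|| L (phi(x1) - phi(x2)) ||_2` — the Mahalanobis distance with
#' `M = L'L` on the expanded feature space.  This is the metric used by the
#' ABC acceptance kernel.
#'
#' @param x1,x2 `"deposition_series"` objects (sharing observation times) or
#'   numeric vectors of equal length.
#' @param proj a `"summary_projection"`, or `NULL` for plain Euclidean
#'   distance on the raw vectors (ablation).
#' @return Non-negative scalar.
#' @export
summary_distance <- function(x1, x2, proj = NULL) {
  if (inherits(x1, "deposition_series") && inherits(x2, "deposition_series")) {
    if (!isTRUE(all.equal(x1$time_s, x2$time_s)))
      stop("series have different observation time grids", call. = FALSE)
    x1 <- series_to_vector(x1); x2 <- series_to_vector(x2)
  }
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  if (length(x1) != length(x2))
    stop("inputs have different lengths", call. = FALSE)
  if (is.null(proj)) return(sqrt(sum((x1 - x2)^2)))
  sqrt(sum((project_summary(x1, proj) - project_summary(x2, proj))^2))
}

#' Identity summary projection on standardized observables
#'
#' Builds the ablation distance the samplers accept in place of a learned
#' projection: the identity map on per-feature z-scored raw observables
#' (no polynomial expansion, no dimension reduction).  The discriminative
#' 2-D projection is tuned for group separation; for per-subject parameter
#' estimation the full standardized observable vector is typically the
#' more informative metric.
#'
#' @param reference a `"cohort_dataset"` with simulated series, or a
#'   numeric matrix (subjects x features) supplying the standardization
#'   constants.
#' @return A `"summary_projection"` with `L = I`.
#' @export
raw_projection <- function(reference) {
  x <- if (inherits(reference, "cohort_dataset"))
    cohort_feature_matrix(reference) else as.matrix(reference)
  s <- safe_scale(x)
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

#' Rand index between two partitions
#'
#' Fraction of the `choose(n, 2)` subject pairs on which two partitions
#' agree (both together or both apart).
#'
#' @param a,b cluster label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ut <- upper.tri(matrix(0, length(a), length(a)))
  mean((outer(a, a, "==") == outer(b, b, "=="))[ut])
}

# cluster projected points by agglomerative hierarchical clustering
# (Ward linkage on Euclidean distances) and score against true labels
cluster_rand_index <- function(points, labels) {
  k <- length(unique(labels))
  cl <- stats::cutree(stats::hclust(stats::dist(points), method = "ward.D2"),
                      k = k)
  rand_index(cl, labels)
}

#' Tune the summary projection by clustering agreement
#'
#' Grid search over candidate hyperparameters: each candidate projection is
#' fitted, the projected cohort is clustered into as many clusters as there
#' are groups by agglomerative hierarchical clustering (Ward linkage,
#' Euclidean distance), and the candidate maximizing the Rand index against
#' the true labels wins (ties resolved by grid order).
#'
#' @param cohort a `"cohort_dataset"` (or `list(x, group)`).
#' @param candidates list of candidate argument lists; each may supply
#'   `k_neighbors`, `regularization`, `expansion`, `out_dim`.
#' @param seed seed passed to every fit.
#' @param validate `"insample"` scores the clustering of the training
#'   cohort itself (the procedure used on a one-off cohort);
#'   `"split"` fits each candidate on a stratified half and scores the
#'   clustering of the held-out half, which protects the score against the
#'   metric memorizing noise directions when features outnumber subjects.
#' @return A list with the winning `projection` (refitted on the full
#'   cohort), its `rand_index`, the winning `candidate` index and the
#'   per-candidate score table.
#' @export
tune_projection_by_rand_index <- function(cohort,
                                          candidates = default_tuning_grid(),
                                          seed = 1,
                                          validate = c("insample", "split")) {
  validate <- match.arg(validate)
  if (length(candidates) < 1) stop("empty candidate grid", call. = FALSE)
  if (inherits(cohort, "cohort_dataset")) {
    x_raw <- cohort_feature_matrix(cohort)
    labels <- cohort$subjects$group
  } else {
    x_raw <- cohort$x; labels <- as.character(cohort$group)
  }
  # drop candidates whose neighbourhood cannot fit in the smallest group
  min_grp <- min(table(labels))
  feasible <- vapply(candidates, function(cand) {
    k <- if (is.null(cand$k_neighbors)) 3 else cand$k_neighbors
    k < (if (validate == "split") ceiling(min_grp / 2) else min_grp)
  }, logical(1))
  if (!any(feasible))
    stop("no candidate has k_neighbors below the smallest group size",
         call. = FALSE)
  candidates <- candidates[feasible]
  if (validate == "split") {
    set.seed(seed)
    train <- unlist(lapply(split(seq_along(labels), labels), function(idx)
      sample(idx, ceiling(length(idx) / 2))))
    test <- setdiff(seq_along(labels), train)
  }
  scores <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    if (validate == "insample") {
      args <- c(list(cohort = list(x = x_raw, group = labels), seed = seed),
                candidates[[i]])
      fit <- do.call(fit_discriminative_projection, args)
      pts <- t(apply(x_raw, 1, project_summary, proj = fit))
      scores[i] <- cluster_rand_index(pts, labels)
    } else {
      args <- c(list(cohort = list(x = x_raw[train, , drop = FALSE],
                                   group = labels[train]), seed = seed),
                candidates[[i]])
      fit <- do.call(fit_discriminative_projection, args)
      pts <- t(apply(x_raw[test, , drop = FALSE], 1, project_summary,
                     proj = fit))
      scores[i] <- cluster_rand_index(pts, labels[test])
    }
  }
  best <- which.max(scores) # which.max takes the first maximum: grid order
  args <- c(list(cohort = list(x = x_raw, group = labels), seed = seed),
            candidates[[best]])
  list(projection = do.call(fit_discriminative_projection, args),
       rand_index = scores[best], candidate = best,
       table = data.frame(candidate = seq_along(candidates),
                          rand_index = scores))
}

#' Default hyperparameter grid for [tune_projection_by_rand_index()]
#' @return List of candidate argument lists.
#' @export
default_tuning_grid <- function() {
  grid <- expand.grid(k = c(2, 3, 5), reg = c(0.2, 0.5, 1))
  lapply(seq_len(nrow(grid)), function(i)
    list(k_neighbors = grid$k[i], regularization = grid$reg[i]))
}
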