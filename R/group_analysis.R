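#' Kruskal-Wallis H-test on a list of samples
#'
#' Rank-based k-sample test of the null hypothesis that all group medians
#' are equal, with tie correction and the chi-square approximation on
#' `k - 1` degrees of freedom.  Thin wrapper over [stats::kruskal.test()]
#' returning just the statistic and p-value.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return Named numeric vector `c(H = ..., p = ...)`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9)) # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    stop("all values identical across groups; H is undefined", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`p * m / rank` with running
#' minimum enforcement, capped at 1), returned in input order.  Wraps
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Identify discriminating parameters across patient groups
#'
#' For each of the seven model parameters, tests equality of group medians
#' of the per-subject MAP estimates: first across all groups, then for each
#' pair of groups (post-hoc).  P-values are Benjamini-Hochberg-adjusted
#' within each comparison family (the 7 parameters of one comparison
#' column), and a parameter is flagged discriminating for a comparison when
#' its adjusted p-value is strictly below `alpha`.
#'
#' @param map_table data frame with columns `group` and the seven parameter
#'   columns (as returned by [cohort_map_estimates()]).
#' @param alpha significance cutoff on adjusted p-values.
#' @param family `"per_comparison"` adjusts the 7 parameters within each
#'   comparison column; `"global"` adjusts all tests together.
#' @return A data frame of class `"group_tests"` with one row per parameter
#'   x comparison: `parameter`, `comparison`, `H`, `p`, `p_adj`,
#'   `significant`.  Attribute `"discriminating"` holds, per comparison, the
#'   flagged parameter names.
#' @export
identify_discriminating_parameters <- function(map_table, alpha = 0.05,
                                               family = c("per_comparison",
                                                          "global")) {
  family <- match.arg(family)
  stopifnot("group" %in% names(map_table))
  pars <- param_names()
  if (!all(pars %in% names(map_table)))
    stop("map_table must contain the 7 parameter columns", call. = FALSE)
  labs <- unique(as.character(map_table$group))
  if (length(labs) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(map_table$group) < 2))
    stop("need at least 2 subjects per group", call. = FALSE)

  comparisons <- list(all = labs)
  if (length(labs) > 2) {
    prs <- utils::combn(labs, 2, simplify = FALSE)
    names(prs) <- vapply(prs, paste, "", collapse = " vs ")
    comparisons <- c(comparisons, prs)
  }

  rows <- list()
  for (cmp in names(comparisons)) {
    members <- comparisons[[cmp]]
    sub <- map_table[map_table$group %in% members, , drop = FALSE]
    hw <- t(vapply(pars, function(p) {
      kruskal_wallis(split(sub[[p]], factor(sub$group, levels = members)))
    }, numeric(2)))
    rows[[cmp]] <- data.frame(parameter = pars, comparison = cmp,
                              H = hw[, 1], p = hw[, 2],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (family == "per_comparison") {
    out$p_adj <- stats::ave(out$p, out$comparison, FUN = bh_adjust)
  } else {
    out$p_adj <- bh_adjust(out$p)
  }
  out$significant <- out$p_adj < alpha
  disc <- lapply(split(out, out$comparison),
                 function(d) d$parameter[d$significant])
  attr(out, "discriminating") <- disc[unique(out$comparison)]
  class(out) <- c("group_tests", "data.frame")
  out
}

#' @export
print.group_tests <- function(x, ...) {
  cat("Kruskal-Wallis tests on MAP estimates (BH-adjusted):\n")
  df <- as.data.frame(x)
  df$H <- signif(df$H, 3); df$p <- signif(df$p, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  disc <- attr(x, "discriminating")
  cat("\nDiscriminating parameters:\n")
  for (cmp in names(disc))
    cat("  ", cmp, ": ",
        if (length(disc[[cmp]])) paste(disc[[cmp]], collapse = ", ") else
          "(none)", "\n", sep = "")
  invisible(x)
}

#' Nearest-median pathology classification
#'
#' Assigns a subject to the healthy or the diseased group according to
#' which group median of the discriminating parameter the subject's MAP
#' estimate is closer to.  Equidistant values are labelled healthy (the
#' conservative convention).
#'
#' @param value numeric MAP value(s) of the discriminating parameter.
#' @param healthy_median,disease_median the two group medians (finite,
#'   distinct).
#' @param labels length-2 character: the healthy and disease labels.
#' @return Character vector of labels, one per value.
#' @export
classify_pathology <- function(value, healthy_median, disease_median,
                               labels = c("healthy", "disease")) {
  if (!is.finite(healthy_median) || !is.finite(disease_median))
    stop("medians must be finite", call. = FALSE)
  if (healthy_median == disease_median)
    stop("group medians are equal; the test is undefined", call. = FALSE)
  ifelse(abs(value - healthy_median) <= abs(value - disease_median),
         labels[1], labels[2])
}

#' Sensitivity and specificity of binary predictions
#'
#' @param predictions,truth equal-length label vectors.
#' @param disease_label the label counted as positive.
#' @return Named numeric vector `c(sensitivity = TP/(TP+FN),
#'   specificity = TN/(TN+FP))`.
#' @export
sensitivity_specificity <- function(predictions, truth, disease_label) {
  stopifnot(length(predictions) == length(truth))
  pos <- truth == disease_label
  if (!any(pos) || all(pos))
    stop("truth must contain both classes", call. = FALSE)
  sens <- mean(predictions[pos] == disease_label)
  spec <- mean(predictions[!pos] != disease_label)
  c(sensitivity = sens, specificity = spec)
}

#' Run the nearest-median pathology test on a cohort MAP table
#'
#' Computes the two group medians of one discriminating parameter and
#' classifies every subject of the two groups by nearest median.  Medians
#' are computed in-sample by default (as on a small cohort where a held-out
#' median is not available); `leave_one_out = TRUE` recomputes the medians
#' without the subject under test, avoiding the leakage of the in-sample
#' convention.
#'
#' @param map_table a MAP table (see [cohort_map_estimates()]).
#' @param parameter name of the discriminating parameter column.
#' @param healthy_label,disease_label the two group labels to compare.
#' @param leave_one_out recompute medians without the test subject?
#' @return A list with `predictions` (per subject), `truth`, the medians
#'   used, and `metrics` (`sensitivity`, `specificity`).
#' @export
pathology_test <- function(map_table, parameter, healthy_label,
                           disease_label, leave_one_out = FALSE) {
  stopifnot(parameter %in% names(map_table))
  sub <- map_table[map_table$group %in% c(healthy_label, disease_label), ,
                   drop = FALSE]
  v <- sub[[parameter]]
  grp <- as.character(sub$group)
  med_h <- stats::median(v[grp == healthy_label])
  med_d <- stats::median(v[grp == disease_label])
  n <- nrow(sub)
  preds <- character(n)
  for (i in seq_len(n)) {
    if (leave_one_out) {
      mh <- stats::median(v[grp == healthy_label & seq_len(n) != i])
      md <- stats::median(v[grp == disease_label & seq_len(n) != i])
    } else {
      mh <- med_h; md <- med_d
    }
    preds[i] <- classify_pathology(v[i], mh, md,
                                   labels = c(healthy_label, disease_label))
  }
  list(predictions = stats::setNames(preds, sub$subject_id), truth = grp,
       healthy_median = med_h, disease_median = med_d,
       parameter = parameter,
       metrics = sensitivity_specificity(preds, grp, disease_label))
}
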