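#' Quartile summary of a numeric vector
#'
#' Linear-interpolation convention between order statistics
#' (`stats::quantile` type 7), the common default in mainstream statistical
#' environments.
#'
#' @param values Numeric vector, length >= 3.
#' @return One-row tibble with `q1`, `q2`, `q3`, `n`.
#' @export
quartile_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) tlb_stop("Need at least 3 values for quartiles.")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(q1 = q[1], q2 = q[2], q3 = q[3], n = length(values))
}

#' Adapted Cohen d effect size
#'
#' Difference between group medians normalized by the size-weighted pooled
#' interquartile range:
#' \deqn{d = \frac{\mathrm{med}(a) - \mathrm{med}(b)}
#'   {(n_a \mathrm{IQR}_a + n_b \mathrm{IQR}_b) / (n_a + n_b)}.}
#' Robust analogue of the classic standardized mean difference; invariant
#' under a common shift, equivariant under positive scaling, antisymmetric
#' under swapping the groups.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @return The effect size `d`.
#' @export
cohen_d_adapted <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    tlb_stop("Both groups need at least 3 values.")
  }
  pooled <- (length(a) * IQR(a, type = 7) + length(b) * IQR(b, type = 7)) /
    (length(a) + length(b))
  if (pooled <= 0) tlb_compute_stop("Pooled IQR is zero.")
  (median(a) - median(b)) / pooled
}

#' ROC analysis with the Youden cut-off
#'
#' Scans every candidate cut-off (midpoints between consecutive sorted unique
#' values) in both orientations and returns the one maximizing the Youden
#' index
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity, then lower threshold, then the "healthy-above" orientation.
#'
#' Positives are the diseased (non-healthy) subjects: sensitivity is the
#' fraction of diseased classified diseased, specificity the fraction of
#' healthy classified healthy. `direction = "healthy-above"` means subjects
#' with values above the threshold are called healthy.
#'
#' @param values Numeric parameter values, one per subject.
#' @param healthy Logical vector (`TRUE` = healthy) or any vector paired with
#'   `healthy_label`.
#' @param healthy_label Value of `healthy` marking the healthy class when
#'   `healthy` is not logical.
#' @return One-row tibble of class `tlb_roc`: `threshold`, `sensitivity`,
#'   `specificity`, `success_rate` (all percentages), `youden_j`,
#'   `direction`, `n`.
#' @export
roc_youden <- function(values, healthy, healthy_label = "HC") {
  if (!is.logical(healthy)) healthy <- healthy == healthy_label
  keep <- !is.na(values) & !is.na(healthy)
  values <- values[keep]; healthy <- healthy[keep]
  if (!any(healthy) || all(healthy)) {
    tlb_stop("Both classes must be present for ROC analysis.")
  }
  u <- sort(unique(values))
  cand <- if (length(u) == 1) u else (head(u, -1) + tail(u, -1)) / 2
  n_dis <- sum(!healthy)
  n_hc <- sum(healthy)
  grid <- tidyr::expand_grid(
    threshold = cand,
    direction = c("healthy-above", "healthy-below")
  )
  eval_one <- function(threshold, direction) {
    called_healthy <- if (direction == "healthy-above") {
      values > threshold
    } else {
      values < threshold
    }
    sens <- sum(!healthy & !called_healthy) / n_dis
    spec <- sum(healthy & called_healthy) / n_hc
    c(sens = sens, spec = spec)
  }
  m <- purrr::map2(grid$threshold, grid$direction, eval_one)
  grid$sensitivity <- vapply(m, `[[`, numeric(1), "sens") * 100
  grid$specificity <- vapply(m, `[[`, numeric(1), "spec") * 100
  grid$youden_j <- (grid$sensitivity + grid$specificity) / 100 - 1
  grid <- dplyr::arrange(
    grid, dplyr::desc(.data$youden_j), dplyr::desc(.data$specificity),
    .data$threshold, dplyr::desc(.data$direction == "healthy-above")
  )
  best <- grid[1, ]
  out <- tibble(
    threshold = best$threshold,
    sensitivity = best$sensitivity,
    specificity = best$specificity,
    success_rate = 100 *
      (best$sensitivity / 100 * n_dis + best$specificity / 100 * n_hc) /
      (n_dis + n_hc),
    youden_j = best$youden_j,
    direction = best$direction,
    n = n_dis + n_hc
  )
  class(out) <- c("tlb_roc", class(out))
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over `stats::kruskal.test` (rank-based H with tie
#' correction, chi-square reference with k - 1 degrees of freedom). When
#' every observation is identical the test is degenerate; by convention
#' H = 0 and p = 1 are returned.
#'
#' @param values Numeric vector, or a list of numeric vectors (one per
#'   group) with `groups` omitted.
#' @param groups Group labels matching `values`.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) tlb_stop("Need at least 2 groups.")
  if (length(values) < 3) tlb_stop("Need at least 3 observations in total.")
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = nlevels(groups) - 1L, p_value = 1,
                  n = length(values)))
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(values))
}

#' Fisher's exact independence test
#'
#' Two-sided exact test on an r x c contingency table of non-negative
#' integer counts (`stats::fisher.test`; hypergeometric for 2 x 2, network
#' enumeration otherwise).
#'
#' @param tab Matrix or table of counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    tlb_stop("Counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    tlb_stop("Every row and column margin must be positive.")
  }
  fisher.test(tab, workspace = 2e7)$p.value
}

#' Per-parameter quartile table by group
#'
#' Summary in the style of a per-parameter quartile report: one row per
#' (parameter, group) with `q1`, `q2`, `q3`, `n`.
#'
#' @param features Cohort feature tibble including `group`.
#' @param params Feature columns to summarize (default: all 14).
#' @return A tibble.
#' @export
quartile_table <- function(features, params = model_parameters(3)) {
  purrr::map_dfr(params, function(p) {
    purrr::map_dfr(unique(features$group), function(g) {
      dplyr::bind_cols(
        tibble(parameter = p, group = g),
        quartile_summary(features[[p]][features$group == g])
      )
    })
  })
}

#' Per-parameter effect-size table
#'
#' Adapted Cohen d (healthy minus diseased) per feature.
#'
#' @inheritParams quartile_table
#' @param healthy_label Group value marking healthy subjects.
#' @return A tibble with `parameter` and `cohen_d`.
#' @export
cohen_d_table <- function(features, params = model_parameters(3),
                          healthy_label = "HC") {
  hc <- features$group == healthy_label
  tibble(
    parameter = params,
    cohen_d = vapply(params, function(p)
      cohen_d_adapted(features[[p]][hc], features[[p]][!hc]), numeric(1))
  )
}

#' Per-parameter ROC/Youden table
#'
#' One Youden-optimized ROC row per feature.
#'
#' @inheritParams cohen_d_table
#' @return A tibble with one `tlb_roc` row per parameter.
#' @export
roc_table <- function(features, params = model_parameters(3),
                      healthy_label = "HC") {
  purrr::map_dfr(params, function(p) {
    dplyr::bind_cols(
      tibble(parameter = p),
      roc_youden(features[[p]], features$group, healthy_label)
    )
  })
}
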