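#' Plot a deconvolution: data, fit and components
#'
#' @param object A `tlb_deconvolution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tlb_deconvolution <- function(object, ...) {
  comp <- purrr::map_dfr(seq_len(nrow(object$peaks)), function(i) {
    tibble(
      peak = factor(object$peaks$peak[i], levels = 1:6),
      temperature = object$data$temperature,
      cp = hubbert_cp(object$data$temperature, object$peaks[i, ],
                      object$offset)
    )
  })
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$temperature, y = .data$cp)) +
    ggplot2::geom_point(size = 0.4, colour = "grey55") +
    ggplot2::geom_line(
      data = comp,
      ggplot2::aes(colour = .data$peak), linetype = "dashed"
    ) +
    ggplot2::geom_line(
      data = tibble(temperature = object$data$temperature,
                    cp = object$fitted),
      linewidth = 0.7
    ) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Excess heat capacity (a.u.)",
      colour = "Transition",
      title = "Six-transition Hubbert deconvolution"
    ) +
    ggplot2::theme_minimal()
}

#' Plot group mean thermograms with dispersion bands
#'
#' Pointwise mean curve per group with a +/- 1 SD ribbon; visualizes the
#' homogeneity of the healthy group against the heterogeneity of the
#' patient group.
#'
#' @param object A `tlb_cohort` from [generate_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tlb_cohort <- function(object, ...) {
  joined <- dplyr::left_join(
    object$thermograms,
    dplyr::select(object$metadata, "subject_id", "group"),
    by = "subject_id"
  )
  summ <- joined |>
    dplyr::group_by(.data$group, .data$temperature) |>
    dplyr::summarise(
      mean_cp = mean(.data$cp), sd_cp = stats::sd(.data$cp),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$temperature,
                                     y = .data$mean_cp,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_cp - .data$sd_cp,
                   ymax = .data$mean_cp + .data$sd_cp),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "Excess heat capacity (a.u.)",
                  title = "Group mean thermograms (±1 SD)") +
    ggplot2::theme_minimal()
}

#' Plot the probability-score distribution by group
#'
#' Histograms of PS per group with the decision threshold marked; scores
#' near 1 indicate unaltered (healthy-like) thermograms, near 0 altered
#' ones.
#'
#' @param ps Tibble with columns `ps` and `group` (e.g. `tidy()` of a
#'   [loo_cv()] result).
#' @param threshold Decision threshold to mark (default 0.5).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_ps_distribution <- function(ps, threshold = 0.5, bins = 25) {
  if (!all(c("ps", "group") %in% names(ps))) {
    tlb_stop("`ps` needs columns `ps` and `group`.")
  }
  ggplot2::ggplot(ps, ggplot2::aes(x = .data$ps, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dotted") +
    ggplot2::labs(x = "Probability score (PS)", y = "Subjects",
                  title = "PS distribution by group") +
    ggplot2::theme_minimal()
}

#' Plot per-parameter effect sizes
#'
#' Bar chart of the adapted Cohen d per TLB parameter with guide lines at
#' +/- 0.25.
#'
#' @param features Cohort feature tibble including `group`.
#' @param ... Passed to [cohen_d_table()].
#' @return A ggplot object.
#' @export
plot_cohen_d <- function(features, ...) {
  d <- cohen_d_table(features, ...)
  d$parameter <- factor(d$parameter, levels = d$parameter)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$cohen_d)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.25, 0.25), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "Adapted Cohen d (HC − LCP)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
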