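#' Average temperature (first moment) of a thermogram
#'
#' Treats the heat-capacity trace as a density over temperature:
#' \deqn{T_{av} = \sum_j C_P(T_j) T_j / \sum_j C_P(T_j).}
#' Computed from the measured points, not the fitted model.
#'
#' @param tg A thermogram tibble on the canonical grid.
#' @return `T_av` in degrees Celsius.
#' @export
average_temperature <- function(tg) {
  tg <- as_thermogram(tg)
  s <- sum(tg$cp)
  if (abs(s) < .Machine$double.eps * nrow(tg)) {
    tlb_compute_stop("Zero total heat capacity: T_av undefined.")
  }
  sum(tg$cp * tg$temperature) / s
}

#' Weighted skewness of a thermogram
#'
#' Dimensionless asymmetry of the heat-capacity-weighted temperature
#' distribution: with weighted central moments
#' \eqn{m_k = \sum_j C_P(T_j)(T_j - T_{av})^k / \sum_j C_P(T_j)},
#' the skewness is \eqn{G_1 = m_3 / m_2^{3/2}}.
#'
#' @inheritParams average_temperature
#' @return `G_1`, dimensionless.
#' @export
thermogram_skewness <- function(tg) {
  tg <- as_thermogram(tg)
  t_av <- average_temperature(tg)
  s <- sum(tg$cp)
  m2 <- sum(tg$cp * (tg$temperature - t_av)^2) / s
  m3 <- sum(tg$cp * (tg$temperature - t_av)^3) / s
  if (m2 <= 0) tlb_compute_stop("Zero weighted variance: skewness undefined.")
  m3 / m2^1.5
}

# Peak heights with degeneracy guard: normalizing by a near-zero fitted
# height would silently blow a feature up.
peak_height <- function(dec, i) {
  if (!i %in% 2:5) tlb_stop("Peak index `i` must be in 2..5.")
  h <- dec$peaks$height
  a <- h[dec$peaks$peak == i]
  if (a < 1e-8 * max(h)) {
    tlb_compute_stop(sprintf("Peak %d height is degenerate (%.3g).", i, a))
  }
  a
}

#' Area under the thermogram normalized by a peak height
#'
#' Plain sum of the heat capacity over the canonical grid divided by the
#' fitted height of peak `i`: \eqn{AUC_{ni} = \sum_j C_P(T_j) / A_i}
#' (dimensionless; invariant to a global rescaling of the trace). The
#' absolute magnitude depends on the configured grid density, which is
#' irrelevant downstream because the grid is shared cohort-wide.
#'
#' @param tg A thermogram tibble on the canonical grid.
#' @param dec The subject's `tlb_deconvolution`.
#' @param i Peak index, 2 to 5.
#' @return `AUC_ni`, dimensionless.
#' @export
auc_normalized <- function(tg, dec, i) {
  tg <- as_thermogram(tg)
  sum(tg$cp) / peak_height(dec, i)
}

#' Height-polygon area normalized by a squared peak height
#'
#' The six fitted heights, placed on six radial axes 60 degrees apart,
#' define an irregular hexagon of area
#' \eqn{(\sqrt{3}/4) \sum_{s=1}^{6} A_s A_{s+1}} (cyclic, \eqn{A_7 = A_1});
#' dividing by \eqn{A_i^2} makes it scale-free:
#' \eqn{AP_{ni} = (\sqrt{3}/4) \sum_s A_s A_{s+1} / A_i^2}.
#'
#' @inheritParams auc_normalized
#' @return `AP_ni`, dimensionless.
#' @export
polygon_area_normalized <- function(dec, i) {
  a <- peak_height(dec, i)
  h <- dec$peaks$height[order(dec$peaks$peak)]
  s <- sum(h * h[c(2:6, 1)])
  (sqrt(3) / 4) * s / a^2
}

#' Healthy-cohort reference statistics
#'
#' Component-wise medians of `T_av`, `AUC_ni` and `AP_ni` (i = 2..5) over the
#' healthy-control subjects. These anchor the relative-distance features.
#'
#' @param hc_features A feature tibble (rows = HC subjects) containing
#'   columns `t_av`, `auc_n2..auc_n5`, `ap_n2..ap_n5`.
#' @return An object of class `tlb_reference`: list with `t_av_ref`,
#'   `auc_n_ref` (named vector, i2..i5), `ap_n_ref`, `n_subjects`.
#' @export
compute_reference <- function(hc_features) {
  need <- c("t_av", paste0("auc_n", 2:5), paste0("ap_n", 2:5))
  if (!is.data.frame(hc_features) || !all(need %in% names(hc_features))) {
    tlb_stop("`hc_features` must contain t_av, auc_n2..5, ap_n2..5.")
  }
  if (nrow(hc_features) < 3) {
    tlb_stop("At least 3 healthy subjects are required for a reference.")
  }
  ref <- structure(
    list(
      t_av_ref = median(hc_features$t_av),
      auc_n_ref = vapply(2:5, function(i)
        median(hc_features[[paste0("auc_n", i)]]), numeric(1)) |>
        setNames(paste0("i", 2:5)),
      ap_n_ref = vapply(2:5, function(i)
        median(hc_features[[paste0("ap_n", i)]]), numeric(1)) |>
        setNames(paste0("i", 2:5)),
      n_subjects = nrow(hc_features)
    ),
    class = "tlb_reference"
  )
  if (ref$t_av_ref <= 0 || any(ref$auc_n_ref <= 0) || any(ref$ap_n_ref <= 0)) {
    tlb_compute_stop("Reference medians must be positive.")
  }
  ref
}

#' @export
print.tlb_reference <- function(x, ...) {
  cat(sprintf("Healthy reference (n = %d): T_av = %.3f\n",
              x$n_subjects, x$t_av_ref))
  cat("  AUC_n:", sprintf("%.3f", x$auc_n_ref), "\n")
  cat("  AP_n: ", sprintf("%.3f", x$ap_n_ref), "\n")
  invisible(x)
}

#' Relative distance from the healthy reference
#'
#' Euclidean distance of a subject's \eqn{(T_{av}, AUC_{ni}, AP_{ni})} from
#' the healthy-cohort medians, each axis expressed as a relative deviation:
#' \deqn{Dv_i = \sqrt{\left(\frac{T_{av}-\bar T_{av}}{\bar T_{av}}\right)^2 +
#'   \left(\frac{AUC_{ni}-\bar{AUC}_{ni}}{\bar{AUC}_{ni}}\right)^2 +
#'   \left(\frac{AP_{ni}-\bar{AP}_{ni}}{\bar{AP}_{ni}}\right)^2}.}
#'
#' @param fv A one-row feature table (or named list) with `t_av`,
#'   `auc_n<i>`, `ap_n<i>`.
#' @param ref A `tlb_reference`.
#' @param i Peak index, 2 to 5.
#' @return `Dv_i >= 0`, dimensionless.
#' @export
distance_value <- function(fv, ref, i) {
  if (!inherits(ref, "tlb_reference")) tlb_stop("`ref` must be tlb_reference.")
  if (!i %in% 2:5) tlb_stop("Peak index `i` must be in 2..5.")
  key <- paste0("i", i)
  sqrt(
    ((fv[["t_av"]] - ref$t_av_ref) / ref$t_av_ref)^2 +
      ((fv[[paste0("auc_n", i)]] - ref$auc_n_ref[[key]]) /
         ref$auc_n_ref[[key]])^2 +
      ((fv[[paste0("ap_n", i)]] - ref$ap_n_ref[[key]]) /
         ref$ap_n_ref[[key]])^2
  )
}

#' Compute the 14-parameter TLB feature vector for one subject
#'
#' Assembles `T_av`, `G_1`, `AUC_n2..AUC_n5`, `AP_n2..AP_n5` and, when a
#' healthy reference is supplied, `Dv_2..Dv_5`. All 14 values are invariant
#' to a global positive rescaling of the heat capacity.
#'
#' @param tg The subject's thermogram on the canonical grid.
#' @param dec The subject's `tlb_deconvolution`.
#' @param ref Optional `tlb_reference`; without it the `dv_*` columns are
#'   `NA` (they are filled cohort-wide once the healthy medians exist).
#' @return A one-row tibble with 14 feature columns.
#' @export
compute_features <- function(tg, dec, ref = NULL) {
  tg <- as_thermogram(tg)
  stopifnot(inherits(dec, "tlb_deconvolution"))
  fv <- tibble(
    t_av = average_temperature(tg),
    g1 = thermogram_skewness(tg)
  )
  for (i in 2:5) fv[[paste0("auc_n", i)]] <- auc_normalized(tg, dec, i)
  for (i in 2:5) fv[[paste0("ap_n", i)]] <- polygon_area_normalized(dec, i)
  for (i in 2:5) {
    fv[[paste0("dv_", i)]] <-
      if (is.null(ref)) NA_real_ else distance_value(fv, ref, i)
  }
  fv
}

#' Feature column names used by the score models
#'
#' Variant 1 uses the ten direct parameters (`t_av`, `g1`, `auc_n2..5`,
#' `ap_n2..5`); variant 2 the four distances (`dv_2..5`); variant 3 all 14.
#'
#' @param variant 1, 2 or 3.
#' @return Character vector of column names.
#' @export
model_parameters <- function(variant) {
  base <- c("t_av", "g1", paste0("auc_n", 2:5), paste0("ap_n", 2:5))
  dv <- paste0("dv_", 2:5)
  switch(as.character(variant),
         "1" = base,
         "2" = dv,
         "3" = c(base, dv),
         tlb_stop("`variant` must be 1, 2 or 3."))
}

#' Add (or refresh) the distance features on a cohort feature table
#'
#' @param features Feature tibble with the ten direct parameters.
#' @param ref A `tlb_reference`.
#' @return `features` with `dv_2..dv_5` recomputed.
#' @export
add_distance_features <- function(features, ref) {
  rel_t <- (features$t_av - ref$t_av_ref) / ref$t_av_ref
  for (i in 2:5) {
    key <- paste0("i", i)
    rel_auc <- (features[[paste0("auc_n", i)]] - ref$auc_n_ref[[key]]) /
      ref$auc_n_ref[[key]]
    rel_ap <- (features[[paste0("ap_n", i)]] - ref$ap_n_ref[[key]]) /
      ref$ap_n_ref[[key]]
    features[[paste0("dv_", i)]] <- sqrt(rel_t^2 + rel_auc^2 + rel_ap^2)
  }
  features
}

#' Featurize a cohort of thermograms
#'
#' Runs the per-subject pipeline (deconvolution then feature extraction) over
#' a long thermogram table, computes the healthy reference from the HC
#' subjects, and fills the distance features.
#'
#' @param thermograms Long tibble with columns `subject_id`, `temperature`,
#'   `cp` (each subject already on the shared canonical grid).
#' @param metadata Cohort metadata tibble with `subject_id` and `group`.
#' @param fits Optional named list of precomputed `tlb_deconvolution`
#'   objects (names = subject ids); missing subjects are fitted here.
#' @param ... Passed to [fit_thermogram()].
#' @return A list of class `tlb_feature_set`: `features` (tibble with
#'   `subject_id`, `group` and the 14 feature columns), `reference`
#'   (`tlb_reference`), and `fits` (named list of deconvolutions).
#' @export
featurize_cohort <- function(thermograms, metadata, fits = NULL, ...) {
  metadata <- validate_cohort_metadata(metadata)
  if (!all(c("subject_id", "temperature", "cp") %in% names(thermograms))) {
    tlb_stop("`thermograms` needs subject_id, temperature, cp columns.")
  }
  ids <- unique(thermograms$subject_id)
  missing_md <- setdiff(ids, metadata$subject_id)
  if (length(missing_md)) {
    tlb_stop(sprintf("Subjects missing from metadata: %s",
                     paste(head(missing_md, 5), collapse = ", ")))
  }
  fits <- fits %||% list()
  traces <- split(
    tibble(temperature = thermograms$temperature, cp = thermograms$cp),
    thermograms$subject_id
  )[ids]
  for (id in ids) {
    if (is.null(fits[[id]])) fits[[id]] <- fit_thermogram(traces[[id]], ...)
  }
  base <- purrr::map_dfr(ids, function(id) {
    dplyr::bind_cols(tibble(subject_id = id),
                     compute_features(traces[[id]], fits[[id]]))
  })
  base <- dplyr::left_join(
    base, dplyr::select(metadata, "subject_id", "group"), by = "subject_id"
  )
  base <- dplyr::relocate(base, "subject_id", "group")
  ref <- compute_reference(dplyr::filter(base, .data$group == "HC"))
  features <- add_distance_features(base, ref)
  structure(list(features = features, reference = ref, fits = fits),
            class = "tlb_feature_set")
}

#' @export
print.tlb_feature_set <- function(x, ...) {
  cat(sprintf("TLB feature set: %d subjects (%d HC, %d LCP)\n",
              nrow(x$features),
              sum(x$features$group == "HC"),
              sum(x$features$group == "LCP")))
  print(x$reference)
  invisible(x)
}

#' Write a cohort feature table
#' @param features Feature tibble (one row per subject).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a cohort feature table
#' @param path Path to a CSV written by [write_features()].
#' @return Feature tibble.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) tlb_stop(sprintf("File not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE)
}
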