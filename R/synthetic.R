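#' Canonical six-transition serum profile
#'
#' Default generating peaks for the synthetic cohorts: six transitions
#' spanning 50-84 degrees Celsius with the dominant one in the low 60s,
#' chosen to emulate the qualitative shape of a healthy serum thermogram
#' (a stylization, not values from any measured cohort; real serum
#' transitions overlap more strongly).
#'
#' @return A six-row peak tibble (see [hubbert_peaks()]).
#' @export
canonical_serum_peaks <- function() {
  hubbert_peaks(
    height = c(0.30, 0.70, 1.00, 0.60, 0.45, 0.20),
    center = c(50.0, 57.0, 64.0, 70.5, 77.0, 84.0),
    width  = c(1.5, 1.8, 1.7, 1.8, 1.8, 2.0)
  )
}

#' Configuration for the synthetic-cohort generator
#'
#' Defines the study conditions every simulated cohort is drawn under:
#' cohort sizes matching the clinical groups (85 healthy controls, 114 lung
#' cancer patients), a canonical healthy profile with modest between-subject
#' variability (homogeneous HC group), and a disease perturbation of
#' magnitude `delta` applied through a three-mode mixture (heterogeneous
#' LCP group). `delta = 0` makes the two groups exchangeable.
#'
#' The three LCP perturbation modes, on top of a common albumin-loss /
#' globulin-gain component, are: `transfer` (extra height moved from the
#' dominant transition to its upper neighbor), `shift` (upper-transition
#' centers displaced to higher temperature), and `hightail` (gain in the
#' two hottest transitions). LCP between-subject dispersions are inflated
#' by `1 + lcp_dispersion_factor * delta`.
#'
#' @param n_hc,n_lcp Group sizes.
#' @param peaks Canonical peak tibble.
#' @param offset Constant offset of the canonical curve.
#' @param height_cv Between-subject coefficient of variation of peak heights
#'   (lognormal, mean-preserving).
#' @param center_sd Gaussian jitter SD of peak centers (degrees Celsius).
#' @param width_sd Gaussian jitter SD of peak widths (degrees Celsius).
#' @param noise_sd Measurement noise SD as a fraction of the subject's
#'   maximum peak height.
#' @param delta Disease effect size (>= 0).
#' @param mixture_weights Probabilities of the three LCP perturbation modes
#'   (`transfer`, `shift`, `hightail`); must sum to 1.
#' @param lcp_dispersion_factor Extra LCP dispersion per unit `delta`.
#' @param t_min,t_max,step Canonical analysis grid.
#' @param seed Default seed used by [generate_cohort()].
#' @return A validated list of class `tlb_generator_config`.
#' @export
generator_config <- function(n_hc = 85, n_lcp = 114,
                             peaks = canonical_serum_peaks(), offset = 0,
                             height_cv = 0.08, center_sd = 0.25,
                             width_sd = 0.10, noise_sd = 0.005,
                             delta = 0.5,
                             mixture_weights = c(transfer = 0.5,
                                                 shift = 0.25,
                                                 hightail = 0.25),
                             lcp_dispersion_factor = 0.6,
                             t_min = 45, t_max = 90, step = 0.1,
                             seed = 20190701) {
  peaks <- validate_peaks(peaks)
  if (nrow(peaks) != 6) tlb_stop("The canonical profile needs 6 peaks.")
  if (n_hc < 1 || n_lcp < 1) tlb_stop("Group sizes must be >= 1.")
  if (any(c(height_cv, center_sd, width_sd, noise_sd) < 0)) {
    tlb_stop("Dispersions must be >= 0.")
  }
  if (delta < 0) tlb_stop("`delta` must be >= 0.")
  if (length(mixture_weights) != 3 || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-9) {
    tlb_stop("`mixture_weights` must be 3 non-negative weights summing to 1.")
  }
  if (lcp_dispersion_factor < 0) tlb_stop("Dispersion factor must be >= 0.")
  structure(
    list(
      n_hc = n_hc, n_lcp = n_lcp, peaks = peaks, offset = offset,
      height_cv = height_cv, center_sd = center_sd, width_sd = width_sd,
      noise_sd = noise_sd, delta = delta,
      mixture_weights = mixture_weights,
      lcp_dispersion_factor = lcp_dispersion_factor,
      t_min = t_min, t_max = t_max, step = step, seed = seed
    ),
    class = "tlb_generator_config"
  )
}

# Draw one subject's peak table around a base profile.
draw_subject_peaks <- function(base, config, dispersion_scale = 1) {
  cv <- config$height_cv * dispersion_scale
  sdlog <- sqrt(log(1 + cv^2))
  heights <- base$height *
    rlnorm(6, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  centers <- base$center +
    rnorm(6, 0, config$center_sd * dispersion_scale)
  widths <- pmax(base$width + rnorm(6, 0, config$width_sd * dispersion_scale),
                 0.3)
  tibble(height = heights, center = centers, width = widths)
}

render_subject <- function(peaks, config) {
  grid <- canonical_grid(config$t_min, config$t_max, config$step)
  cp <- hubbert_cp(grid, peaks, config$offset) +
    rnorm(length(grid), 0, config$noise_sd * max(peaks$height))
  tibble(temperature = grid, cp = cp)
}

lcp_perturb <- function(base, mode, delta) {
  # Common disease component: the dominant (third) transition and its upper
  # neighbor at 77 degC lose height, the transitions flanking them gain, the
  # hottest transition gains most, and all centers drift slightly upward.
  # Magnitudes scale with delta and a subject-specific lognormal factor.
  u <- rlnorm(1, 0, 0.25)
  pk <- base
  pk$height[2] <- pk$height[2] * exp(0.10 * delta * u)
  pk$height[3] <- pk$height[3] * exp(-0.15 * delta * u)
  pk$height[4] <- pk$height[4] * exp(0.12 * delta * u)
  pk$height[5] <- pk$height[5] * exp(-0.15 * delta * u)
  pk$height[6] <- pk$height[6] * exp(0.30 * delta * u)
  pk$center <- pk$center + 0.15 * delta * u
  v <- rlnorm(1, 0, 0.3)
  if (mode == "transfer") {
    pk$height[2] <- pk$height[2] * exp(0.08 * delta * v)
    pk$height[3] <- pk$height[3] * exp(-0.10 * delta * v)
    pk$height[4] <- pk$height[4] * exp(0.08 * delta * v)
  } else if (mode == "shift") {
    pk$center[4:6] <- pk$center[4:6] + 0.9 * delta * v
    pk$width[5] <- pk$width[5] * exp(0.06 * delta * v)
  } else { # hightail
    pk$height[5] <- pk$height[5] * exp(-0.10 * delta * v)
    pk$height[6] <- pk$height[6] * exp(0.35 * delta * v)
  }
  pk
}

sample_metadata <- function(id, group) {
  gender <- sample(c("M", "F"), 1)
  if (group == "HC") {
    tibble(subject_id = id, group = group, gender = gender,
           age = round(runif(1, 25, 70)),
           diagnostic = NA_character_, stage = NA_character_,
           treatment = NA_character_, response = NA_character_)
  } else {
    tibble(
      subject_id = id, group = group, gender = gender,
      age = round(runif(1, 40, 80)),
      diagnostic = sample(c("AC", "SC", "SCLC", "NSLC"), 1,
                          prob = c(0.38, 0.28, 0.30, 0.04)),
      stage = sample(c("II", "III", "IV"), 1, prob = c(0.05, 0.26, 0.69)),
      treatment = sample(c("ACT", "NACT", "PCT", "RCT"), 1),
      response = sample(c("SD", "D", "P", "CR", "PR"), 1)
    )
  }
}

generate_group <- function(config, n, group, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  delta <- if (group == "LCP") config$delta else 0
  dispersion_scale <- 1 + config$lcp_dispersion_factor * delta
  modes <- names(config$mixture_weights) %||% c("transfer", "shift",
                                                "hightail")
  out <- purrr::map(seq_len(n), function(i) {
    id <- sprintf("%s%03d", group, i)
    base <- config$peaks
    mode <- NA_character_
    if (group == "LCP") {
      mode <- sample(modes, 1, prob = config$mixture_weights)
      base <- lcp_perturb(base, mode, delta)
    }
    pk <- draw_subject_peaks(base, config,
                             if (group == "LCP") dispersion_scale else 1)
    tg <- render_subject(pk, config)
    truth <- flatten_deconvolution(
      structure(list(
        peaks = dplyr::bind_cols(tibble(peak = 1:6), pk),
        offset = config$offset, rss = 0, converged = TRUE
      ), class = "tlb_deconvolution"),
      subject_id = id
    )
    truth$mode <- mode
    list(
      thermogram = dplyr::bind_cols(tibble(subject_id = id), tg),
      metadata = sample_metadata(id, group),
      truth = truth
    )
  })
  list(
    thermograms = purrr::map_dfr(out, "thermogram"),
    metadata = purrr::map_dfr(out, "metadata"),
    truth = purrr::map_dfr(out, "truth")
  )
}

#' Generate healthy-control subjects
#'
#' Each subject's peak heights are drawn lognormally around the canonical
#' profile (mean-preserving, stated CV), centers and widths get Gaussian
#' jitter, the mixture curve is rendered on the canonical grid and Gaussian
#' measurement noise is added. Deterministic given `seed`.
#'
#' @param config A `tlb_generator_config`.
#' @param n Number of subjects (default `config$n_hc`).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return List with long `thermograms`, `metadata`, `truth` tibbles.
#' @export
generate_hc <- function(config = generator_config(), n = config$n_hc,
                        seed = NULL) {
  generate_group(config, n, "HC", seed)
}

#' Generate lung-cancer-patient subjects
#'
#' Like [generate_hc()] but each subject is perturbed by one of three
#' disease modes (sampled with `config$mixture_weights`) on top of a common
#' albumin-loss / globulin-gain component, all scaled by `config$delta`, and
#' with inflated between-subject dispersion. `delta = 0` reduces exactly to
#' the healthy generator.
#'
#' @inheritParams generate_hc
#' @param n Number of subjects (default `config$n_lcp`).
#' @return List with long `thermograms`, `metadata`, `truth` tibbles.
#' @export
generate_lcp <- function(config = generator_config(), n = config$n_lcp,
                         seed = NULL) {
  generate_group(config, n, "LCP", seed)
}

#' Generate a full labeled synthetic cohort
#'
#' Combines both groups under a single seeded RNG stream and keeps the true
#' generating parameters for recovery tests.
#'
#' @param config A `tlb_generator_config`.
#' @param seed Integer seed (default `config$seed`).
#' @return Object of class `tlb_cohort`: list with `thermograms` (long
#'   tibble), `metadata`, `truth`, and the `config` used.
#' @export
generate_cohort <- function(config = generator_config(),
                            seed = config$seed) {
  withr::local_seed(seed)
  hc <- generate_hc(config, config$n_hc, seed = NULL)
  lcp <- generate_lcp(config, config$n_lcp, seed = NULL)
  structure(
    list(
      thermograms = dplyr::bind_rows(hc$thermograms, lcp$thermograms),
      metadata = dplyr::bind_rows(hc$metadata, lcp$metadata),
      truth = dplyr::bind_rows(hc$truth, lcp$truth),
      config = config,
      seed = seed
    ),
    class = "tlb_cohort"
  )
}

#' @export
print.tlb_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic TLB cohort: %d HC + %d LCP subjects (delta = %g, seed = %s)\n",
    sum(x$metadata$group == "HC"), sum(x$metadata$group == "LCP"),
    x$config$delta, format(x$seed)
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same formats the reading functions consume: one two-column
#' thermogram file per subject under `dir/thermograms/`, `metadata.csv`,
#' and the ground-truth generating parameters in `truth.csv`.
#'
#' @param cohort A `tlb_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tlb_cohort"))
  tg_dir <- file.path(dir, "thermograms")
  dir.create(tg_dir, recursive = TRUE, showWarnings = FALSE)
  split_tg <- split(cohort$thermograms, cohort$thermograms$subject_id)
  for (id in names(split_tg)) {
    write_thermogram(split_tg[[id]], file.path(tg_dir, paste0(id, ".csv")))
  }
  write_cohort_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
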