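#' Construct a table of Hubbert (logistic) peaks
#'
#' Each transition in a serum thermogram is modeled by a Hubbert function
#' \deqn{C_P(T) = 4A \, e^{-x} / (1 + e^{-x})^2, \quad x = (T - T_c)/w,}
#' where the factor 4 makes `A` the apex height: the curve equals `A` at
#' `T = T_c`, approximately `0.786 A` at `T_c +/- w`, and approximately
#' `0.420 A` at `T_c +/- 2w`.
#'
#' @param height Apex heights `A` (heat-capacity units, > 0).
#' @param center Peak centers `T_c` (degrees Celsius).
#' @param width Peak widths `w` (degrees Celsius, > 0).
#' @return A tibble with columns `height`, `center`, `width`.
#' @export
hubbert_peaks <- function(height, center, width) {
  pk <- tibble(height = as.numeric(height), center = as.numeric(center),
               width = as.numeric(width))
  validate_peaks(pk)
}

validate_peaks <- function(peaks, allow_zero_height = TRUE) {
  if (!is.data.frame(peaks) ||
      !all(c("height", "center", "width") %in% names(peaks))) {
    tlb_stop("`peaks` must have columns height, center, width.")
  }
  peaks <- as_tibble(peaks)
  if (!all(is.finite(peaks$height)) || !all(is.finite(peaks$center)) ||
      !all(is.finite(peaks$width))) {
    tlb_stop("Peak parameters must be finite.")
  }
  if (any(peaks$width <= 0)) tlb_stop("Peak widths must be > 0.")
  if (any(peaks$height < 0) ||
      (!allow_zero_height && any(peaks$height <= 0))) {
    tlb_stop("Peak heights must be positive.")
  }
  peaks
}

# Workhorse: sum of Hubbert components plus offset, evaluated on a grid.
hubbert_cp <- function(temperature, peaks, offset = 0) {
  peaks <- validate_peaks(peaks)
  cp <- rep(offset, length(temperature))
  for (i in seq_len(nrow(peaks))) {
    x <- exp(-(temperature - peaks$center[i]) / peaks$width[i])
    cp <- cp + 4 * peaks$height[i] * x / (1 + x)^2
  }
  cp
}

#' Evaluate a Hubbert mixture on a temperature grid
#'
#' @param peaks A peak table from [hubbert_peaks()].
#' @param offset Constant heat-capacity offset `C_P0` (default 0), an
#'   adjustable term absorbing residual baseline error.
#' @param temperature Numeric grid of temperatures (degrees Celsius).
#' @return A thermogram tibble with columns `temperature` and `cp`.
#' @export
hubbert_curve <- function(peaks, offset = 0, temperature) {
  if (!is.numeric(temperature) || !all(is.finite(temperature))) {
    tlb_stop("`temperature` must be finite numeric.")
  }
  tibble(temperature = temperature,
         cp = hubbert_cp(temperature, peaks, offset))
}

#' Default anchor temperatures for the six transitions
#'
#' Six centers spread evenly across the interior of the analysis window.
#' Anchors give every subject the same meaning of "peak i": initial centers
#' are seeded here and, by default, each fitted center is constrained to a
#' box around its anchor.
#'
#' @param t_min,t_max Analysis window (degrees Celsius).
#' @return Numeric vector of six temperatures.
#' @export
default_anchors <- function(t_min = 45, t_max = 90) {
  r <- t_max - t_min
  seq(t_min + 0.12 * r, t_max - 0.12 * r, length.out = 6)
}

#' Initial parameter guess for the six-peak fit
#'
#' Centers are seeded at the six anchor temperatures; heights at the local
#' baseline-subtracted heat capacity there (floored at 1 percent of the
#' maximum); widths at 2 degrees Celsius; the offset at the minimum heat
#' capacity.
#'
#' @param tg A thermogram tibble on the analysis grid.
#' @param anchors Six anchor temperatures (default [default_anchors()] over
#'   the data range).
#' @param width_seed Initial width in degrees Celsius.
#' @return Named numeric vector of length 19:
#'   `A1..A6, Tc1..Tc6, w1..w6, Cp0`.
#' @export
initial_guess <- function(tg, anchors = NULL, width_seed = 2) {
  tg <- as_thermogram(tg)
  if (all(tg$cp == 0)) tlb_stop("All-zero trace: nothing to fit.")
  anchors <- anchors %||%
    default_anchors(min(tg$temperature), max(tg$temperature))
  if (length(anchors) != 6) tlb_stop("Need exactly 6 anchor temperatures.")
  offset <- min(tg$cp)
  local_cp <- approx(tg$temperature, tg$cp, xout = anchors, rule = 2)$y
  floor_h <- 0.01 * max(tg$cp - offset)
  heights <- pmax(local_cp - offset, floor_h)
  setNames(
    c(heights, anchors, rep(width_seed, 6), offset),
    c(paste0("A", 1:6), paste0("Tc", 1:6), paste0("w", 1:6), "Cp0")
  )
}

par_to_peaks <- function(par) {
  par <- unname(par)
  list(
    peaks = tibble(height = par[1:6], center = par[7:12], width = par[13:18]),
    offset = par[[19]]
  )
}

#' Deconvolute a thermogram into six Hubbert transitions
#'
#' Bounded Levenberg-Marquardt least squares on the 19-parameter model (six
#' heights, six centers, six widths, one offset). Identifiability across
#' subjects is enforced two ways: initial centers sit at fixed anchor
#' temperatures, and each center is constrained to a box of half-width
#' `center_halfwidth` around its anchor (default: half the anchor spacing).
#' Peaks are sorted by center before return, so "peak i" always means the
#' i-th transition in temperature order.
#'
#' @param tg A thermogram tibble, already resampled onto the analysis grid.
#' @param init Either `"auto"` (use [initial_guess()]) or a named/ordered
#'   numeric vector of 19 parameters (`A1..A6, Tc1..Tc6, w1..w6, Cp0`).
#' @param anchors Six anchor temperatures used for initialization and center
#'   boxes; default [default_anchors()] over the data range.
#' @param center_halfwidth Half-width of the per-peak center box in degrees
#'   Celsius; `Inf` disables the boxes (centers then only bounded by the
#'   window). Default: half the spacing between consecutive anchors.
#' @param width_bounds Lower and upper bounds on widths (degrees Celsius).
#' @param max_iter Maximum optimizer iterations (capped at 1024 by the
#'   underlying optimizer per call; the fit is restarted from the last
#'   estimate until `max_iter` cumulative iterations).
#' @param ftol Relative residual-sum-of-squares convergence tolerance.
#' @return An object of class `tlb_deconvolution`: a list with `peaks` (a
#'   six-row tibble sorted by center, with column `peak` = 1..6), `offset`,
#'   `rss`, `converged`, `n_iter`, plus the input data and fitted values.
#'   Non-convergence is reported via `converged = FALSE`, not an error.
#' @export
fit_thermogram <- function(tg, init = "auto", anchors = NULL,
                           center_halfwidth = NULL,
                           width_bounds = c(0.3, 15),
                           max_iter = 2000, ftol = 1e-10) {
  tg <- as_thermogram(tg, min_points = 25)
  t_min <- min(tg$temperature)
  t_max <- max(tg$temperature)
  anchors <- anchors %||% default_anchors(t_min, t_max)
  if (is.character(init) && identical(init, "auto")) {
    par <- initial_guess(tg, anchors = anchors)
  } else {
    if (!is.numeric(init) || length(init) != 19) {
      tlb_stop("`init` must be \"auto\" or a numeric vector of length 19.")
    }
    par <- as.numeric(init)
    anchors <- par[7:12]
  }
  hw <- center_halfwidth %||% (min(diff(sort(anchors))) / 2)
  lower <- c(rep(0, 6), pmax(anchors - hw, t_min), rep(width_bounds[1], 6),
             -Inf)
  upper <- c(rep(Inf, 6), pmin(anchors + hw, t_max), rep(width_bounds[2], 6),
             Inf)
  par <- pmin(pmax(par, lower), upper)

  y <- tg$cp
  grid <- tg$temperature
  resid_fn <- function(p) {
    pk <- par_to_peaks(p)
    y - hubbert_cp(grid, pk$peaks, pk$offset)
  }

  total_iter <- 0
  info <- -1
  repeat {
    budget <- min(1024, max_iter - total_iter)
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = max(budget, 1), maxfev = 100000,
        ftol = ftol, ptol = ftol
      )
    ))
    par <- fit$par
    total_iter <- total_iter + fit$niter
    info <- fit$info
    if (info != -1 && info != 5 || total_iter >= max_iter) break
  }

  pk <- par_to_peaks(par)
  ord <- order(pk$peaks$center)
  peaks <- pk$peaks[ord, ]
  peaks <- dplyr::bind_cols(tibble(peak = 1:6), peaks)
  fitted_cp <- hubbert_cp(grid, peaks, pk$offset)
  structure(
    list(
      peaks = peaks,
      offset = pk$offset,
      rss = sum((y - fitted_cp)^2),
      converged = info %in% 1:4,
      n_iter = total_iter,
      info = info,
      data = tg,
      fitted = fitted_cp,
      anchors = anchors
    ),
    class = "tlb_deconvolution"
  )
}

#' @export
print.tlb_deconvolution <- function(x, ...) {
  cat("Six-transition Hubbert deconvolution\n")
  cat(sprintf("  rss: %.6g  offset: %.6g  converged: %s (%d iterations)\n",
              x$rss, x$offset, x$converged, x$n_iter))
  print(x$peaks)
  invisible(x)
}

#' @describeIn fit_thermogram Peak parameters as a tibble
#'   (`peak`, `height`, `center`, `width`).
#' @param x,object A `tlb_deconvolution` object.
#' @param ... Unused.
#' @export
tidy.tlb_deconvolution <- function(x, ...) {
  x$peaks
}

#' @describeIn fit_thermogram One-row fit summary
#'   (`rss`, `sigma`, `offset`, `converged`, `n_iter`, `n`).
#' @export
glance.tlb_deconvolution <- function(x, ...) {
  n <- nrow(x$data)
  tibble(rss = x$rss, sigma = sqrt(x$rss / max(n - 19, 1)),
         offset = x$offset, converged = x$converged,
         n_iter = x$n_iter, n = n)
}

#' Flatten a deconvolution result to one row
#'
#' Serialization used for cohort-level tables: columns
#' `A1..A6, Tc1..Tc6, w1..w6, Cp0, rss, converged`.
#'
#' @param dec A `tlb_deconvolution` object.
#' @param subject_id Optional subject id prepended as a column.
#' @return A one-row tibble.
#' @export
flatten_deconvolution <- function(dec, subject_id = NULL) {
  stopifnot(inherits(dec, "tlb_deconvolution"))
  vals <- c(dec$peaks$height, dec$peaks$center, dec$peaks$width, dec$offset)
  out <- as_tibble(as.list(setNames(
    vals, c(paste0("A", 1:6), paste0("Tc", 1:6), paste0("w", 1:6), "Cp0")
  )))
  out$rss <- dec$rss
  out$converged <- dec$converged
  if (!is.null(subject_id)) {
    out <- dplyr::bind_cols(tibble(subject_id = subject_id), out)
  }
  out
}

#' Rebuild a deconvolution-style peak table from a flat row
#'
#' Inverse of [flatten_deconvolution()] for the peak parameters.
#'
#' @param row A one-row data frame with columns `A1..A6, Tc1..Tc6, w1..w6`
#'   and optionally `Cp0`.
#' @return A list with `peaks` (tibble) and `offset`.
#' @export
unflatten_deconvolution <- function(row) {
  need <- c(paste0("A", 1:6), paste0("Tc", 1:6), paste0("w", 1:6))
  if (!all(need %in% names(row))) {
    tlb_stop("Flat record must contain A1..A6, Tc1..Tc6, w1..w6.")
  }
  peaks <- tibble(
    peak = 1:6,
    height = as.numeric(row[paste0("A", 1:6)]),
    center = as.numeric(row[paste0("Tc", 1:6)]),
    width = as.numeric(row[paste0("w", 1:6)])
  )
  list(peaks = peaks, offset = if ("Cp0" %in% names(row))
    as.numeric(row[["Cp0"]]) else 0)
}
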