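#' Validate a thermogram table
#'
#' A thermogram is a tibble with numeric columns `temperature` (degrees
#' Celsius, strictly increasing) and `cp` (excess heat capacity, arbitrary
#' units). Heat-capacity units are arbitrary throughout: every downstream
#' feature is invariant to a global positive rescaling of `cp`, so no unit
#' normalization is attempted.
#'
#' @param tg A data frame with columns `temperature` and `cp`.
#' @param min_points Minimum number of grid points required (default 3; real
#'   DSC traces typically carry hundreds of points).
#' @return The validated thermogram as a tibble, sorted by temperature.
#' @export
as_thermogram <- function(tg, min_points = 3) {
  if (!is.data.frame(tg)) tlb_stop("`tg` must be a data frame.")
  if (!all(c("temperature", "cp") %in% names(tg))) {
    tlb_stop("A thermogram needs `temperature` and `cp` columns.")
  }
  tg <- as_tibble(tg)
  if (!is.numeric(tg$temperature) || !is.numeric(tg$cp)) {
    tlb_stop("`temperature` and `cp` must be numeric.")
  }
  if (nrow(tg) < min_points) {
    tlb_stop(sprintf("Thermogram has %d points; at least %d required.",
                     nrow(tg), min_points))
  }
  if (anyNA(tg$temperature) || anyNA(tg$cp) ||
      !all(is.finite(tg$temperature)) || !all(is.finite(tg$cp))) {
    tlb_stop("Thermogram values must all be finite.")
  }
  tg <- dplyr::arrange(tg, .data$temperature)
  if (anyDuplicated(tg$temperature)) {
    tlb_stop("Duplicated temperatures in thermogram.")
  }
  tg
}

#' Read a thermogram trace from delimited text
#'
#' Expects two numeric columns (temperature in degrees Celsius, excess heat
#' capacity). A header line such as `temperature_C,cp` is detected and
#' skipped; lines starting with `#` are ignored. Rows are sorted by
#' temperature; duplicated temperatures are an error.
#'
#' @param path Path to the file.
#' @param delim Field separator (default `","`).
#' @inheritParams as_thermogram
#' @return A thermogram tibble with columns `temperature` and `cp`.
#' @export
read_thermogram <- function(path, delim = ",", min_points = 3) {
  if (!file.exists(path)) tlb_stop(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) tlb_stop(sprintf("No data rows in %s", path))
  first <- strsplit(lines[[1]], delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- readr::read_delim(
    I(paste(lines, collapse = "\n")),
    delim = delim, col_names = has_header, show_col_types = FALSE,
    trim_ws = TRUE, col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(tab) < 2) tlb_stop(sprintf("Expected two columns in %s", path))
  temperature <- suppressWarnings(as.numeric(tab[[1]]))
  cp <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(temperature) || anyNA(cp)) {
    tlb_stop(sprintf("Non-numeric cells in %s", path))
  }
  as_thermogram(tibble(temperature = temperature, cp = cp),
                min_points = min_points)
}

#' Write a thermogram trace to delimited text
#'
#' Writes the standard two-column format with header `temperature_C,cp`.
#' Values round-trip through [read_thermogram()] at full precision.
#'
#' @param tg A thermogram tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  tg <- as_thermogram(tg)
  readr::write_csv(
    tibble(temperature_C = tg$temperature, cp = tg$cp), path
  )
  invisible(path)
}

#' Resample a thermogram onto a uniform temperature grid
#'
#' Linear interpolation onto `seq(t_min, t_max, by = step)`. The plain sums
#' used by the moment and area features are only comparable across subjects
#' when every trace sits on the same grid, so resampling onto the canonical
#' window (default 45-90 degC, 0.1 degC) is the first pipeline step.
#'
#' @param tg A thermogram tibble.
#' @param t_min,t_max Window bounds in degrees Celsius; must lie within the
#'   measured range.
#' @param step Grid step in degrees Celsius.
#' @return A thermogram tibble on the uniform grid.
#' @export
resample_thermogram <- function(tg, t_min = 45, t_max = 90, step = 0.1) {
  tg <- as_thermogram(tg)
  if (!is_scalar_number(step) || step <= 0) tlb_stop("`step` must be > 0.")
  if (t_min >= t_max) tlb_stop("`t_min` must be below `t_max`.")
  eps <- 1e-9
  if (t_min < min(tg$temperature) - eps || t_max > max(tg$temperature) + eps) {
    tlb_stop(sprintf(
      "Requested window [%g, %g] outside measured range [%g, %g].",
      t_min, t_max, min(tg$temperature), max(tg$temperature)
    ))
  }
  grid <- seq(t_min, t_max, by = step)
  cp <- approx(tg$temperature, tg$cp, xout = grid, rule = 2)$y
  tibble(temperature = grid, cp = cp)
}

#' Subtract a two-anchor linear baseline
#'
#' Fits a straight line through the mean (temperature, cp) point of each of
#' two anchor windows (typically flat pre- and post-transition regions) and
#' subtracts it. Negative heat capacity after correction is retained, not
#' clipped -- clipping would bias the weighted-moment features -- but a
#' warning is emitted when more than 5 percent of points go negative.
#'
#' @param tg A thermogram tibble.
#' @param anchors A list of two numeric ranges `c(lo, hi)` in degrees
#'   Celsius; each window must contain at least two points and the windows
#'   must not overlap.
#' @return The baseline-corrected thermogram tibble.
#' @export
subtract_baseline <- function(tg, anchors) {
  tg <- as_thermogram(tg)
  if (!is.list(anchors) || length(anchors) != 2) {
    tlb_stop("`anchors` must be a list of two c(lo, hi) windows.")
  }
  win <- lapply(anchors, function(a) {
    if (length(a) != 2 || !is.numeric(a) || a[1] >= a[2]) {
      tlb_stop("Each anchor window must be numeric c(lo, hi) with lo < hi.")
    }
    sort(a)
  })
  if (!(win[[1]][2] < win[[2]][1] || win[[2]][2] < win[[1]][1])) {
    tlb_stop("Anchor windows overlap.")
  }
  pts <- lapply(win, function(a) {
    sel <- tg$temperature >= a[1] & tg$temperature <= a[2]
    if (sum(sel) < 2) {
      tlb_stop("Each anchor window must contain at least 2 points.")
    }
    c(t = mean(tg$temperature[sel]), cp = mean(tg$cp[sel]))
  })
  slope <- (pts[[2]]["cp"] - pts[[1]]["cp"]) /
    (pts[[2]]["t"] - pts[[1]]["t"])
  intercept <- pts[[1]]["cp"] - slope * pts[[1]]["t"]
  out <- tibble(
    temperature = tg$temperature,
    cp = tg$cp - (intercept + slope * tg$temperature)
  )
  frac_neg <- mean(out$cp < 0)
  if (frac_neg > 0.05) {
    warn(sprintf(
      "%.0f%% of points negative after baseline correction.", 100 * frac_neg
    ))
  }
  out
}

#' Read a cohort metadata table
#'
#' Delimited text with columns `subject_id`, `group` (HC, LCP or unknown)
#' and optional clinical covariates `gender`, `age`, `diagnostic`, `stage`,
#' `treatment`, `response`. Empty cells are allowed for optional fields.
#'
#' @param path Path to the file.
#' @return A tibble of subject records.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) tlb_stop(sprintf("File not found: %s", path))
  md <- readr::read_csv(path, show_col_types = FALSE)
  validate_cohort_metadata(md)
}

validate_cohort_metadata <- function(md) {
  md <- as_tibble(md)
  if (!all(c("subject_id", "group") %in% names(md))) {
    tlb_stop("Metadata needs `subject_id` and `group` columns.")
  }
  md$subject_id <- as.character(md$subject_id)
  if (anyNA(md$subject_id) || any(!nzchar(md$subject_id))) {
    tlb_stop("`subject_id` must be non-empty.")
  }
  if (anyDuplicated(md$subject_id)) tlb_stop("Duplicated subject ids.")
  md$group <- as.character(md$group)
  bad <- !md$group %in% c("HC", "LCP", "unknown")
  if (anyNA(md$group) || any(bad)) {
    tlb_stop("`group` must be one of HC, LCP, unknown.")
  }
  if ("age" %in% names(md)) {
    age <- suppressWarnings(as.numeric(md$age))
    if (any(!is.na(age) & age < 0)) tlb_stop("`age` must be >= 0.")
    md$age <- age
  }
  md
}

#' Write a cohort metadata table
#' @param md Metadata tibble (see [read_cohort_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_metadata <- function(md, path) {
  readr::write_csv(validate_cohort_metadata(md), path)
  invisible(path)
}
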