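# Shared fixtures. Everything is generated in code; the default-cohort
# pipeline (generate -> deconvolute -> featurize) is cached per test run
# because several files exercise it.

tlb_test_env <- new.env(parent = emptyenv())

test_seed <- 20190701

# Six well-separated peaks used for deconvolution oracles.
test_peaks <- function() canonical_serum_peaks()

test_grid <- function() seq(45, 90, by = 0.1)

make_test_trace <- function(peaks = test_peaks(), offset = 0,
                            noise_sd = 0, seed = 1) {
  tg <- hubbert_curve(peaks, offset, test_grid())
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      tg$cp <- tg$cp + rnorm(nrow(tg), 0, noise_sd)
    })
  }
  tg
}

# Featurized default synthetic cohort at a given delta (cached).
cohort_features <- function(delta = 1) {
  key <- paste0("delta_", delta)
  if (is.null(tlb_test_env[[key]])) {
    cohort <- generate_cohort(generator_config(delta = delta),
                              seed = test_seed)
    fs <- featurize_cohort(cohort$thermograms, cohort$metadata)
    tlb_test_env[[key]] <- list(cohort = cohort, features = fs$features,
                                reference = fs$reference)
  }
  tlb_test_env[[key]]
}

# Independent symbol-by-symbol evaluation of the feature definitions, kept
# deliberately naive (explicit loops, no shared code with the package).
oracle_features <- function(temperature, cp, heights, ref = NULL) {
  s <- 0; st <- 0
  for (j in seq_along(cp)) {
    s <- s + cp[j]
    st <- st + cp[j] * temperature[j]
  }
  t_av <- st / s
  m2 <- 0; m3 <- 0
  for (j in seq_along(cp)) {
    m2 <- m2 + cp[j] * (temperature[j] - t_av)^2
    m3 <- m3 + cp[j] * (temperature[j] - t_av)^3
  }
  m2 <- m2 / s; m3 <- m3 / s
  g1 <- m3 / m2^(3 / 2)
  out <- list(t_av = t_av, g1 = g1)
  hex <- 0
  for (sdx in 1:6) {
    nxt <- if (sdx == 6) 1 else sdx + 1
    hex <- hex + heights[sdx] * heights[nxt]
  }
  for (i in 2:5) {
    out[[paste0("auc_n", i)]] <- s / heights[i]
    out[[paste0("ap_n", i)]] <- (sqrt(3) / 4) * hex / heights[i]^2
  }
  if (!is.null(ref)) {
    for (i in 2:5) {
      key <- paste0("i", i)
      out[[paste0("dv_", i)]] <- sqrt(
        ((t_av - ref$t_av_ref) / ref$t_av_ref)^2 +
          ((out[[paste0("auc_n", i)]] - ref$auc_n_ref[[key]]) /
             ref$auc_n_ref[[key]])^2 +
          ((out[[paste0("ap_n", i)]] - ref$ap_n_ref[[key]]) /
             ref$ap_n_ref[[key]])^2
      )
    }
  }
  out
}

# Brute-force Youden search: every midpoint cut-off, both orientations,
# direct counting.
oracle_youden <- function(values, healthy) {
  u <- sort(unique(values))
  cands <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  best <- NULL
  for (thr in cands) {
    for (dir in c("healthy-above", "healthy-below")) {
      ch <- if (dir == "healthy-above") values > thr else values < thr
      sens <- sum(!healthy & !ch) / sum(!healthy)
      spec <- sum(healthy & ch) / sum(healthy)
      j <- sens + spec - 1
      if (is.null(best) || j > best$j + 1e-12) {
        best <- list(j = j, thr = thr, dir = dir, sens = sens, spec = spec)
      }
    }
  }
  best
}

# Direct -2 log-likelihood of a logit model from its predicted scores.
oracle_neg2ll <- function(ps, y) {
  -2 * sum(ifelse(y == 1, log(ps), log(1 - ps)))
}

# Mock deconvolution object with prescribed peak heights.
mock_deconvolution <- function(heights,
                               centers = test_peaks()$center,
                               widths = test_peaks()$width,
                               offset = 0) {
  structure(
    list(
      peaks = tibble::tibble(peak = 1:6, height = heights, center = centers,
                             width = widths),
      offset = offset, rss = 0, converged = TRUE, n_iter = 0
    ),
    class = "tlb_deconvolution"
  )
}
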