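test_that("average temperature follows the weighted first moment", {
  # symmetric single peak centered at 65
  tg <- make_test_trace(hubbert_peaks(1, 65, 2))
  # restrict to a window symmetric about 65 so the grid itself is symmetric
  sym <- resample_thermogram(tg, 45, 85, 0.1)
  expect_equal(average_temperature(sym), 65, tolerance = 1e-6)

  # two identical peaks at 60 and 70
  two <- hubbert_curve(hubbert_peaks(c(1, 1), c(60, 70), c(2, 2)), 0,
                       seq(40, 90, 0.1))
  expect_equal(average_temperature(two), 65, tolerance = 1e-6)

  # direct evaluation on a 3-point trace
  tri <- tibble::tibble(temperature = c(60, 65, 70), cp = c(1, 2, 3))
  expect_equal(average_temperature(tri), 400 / 6)

  expect_error(
    average_temperature(tibble::tibble(temperature = 1:3, cp = c(0, 0, 0))),
    class = "tlb_computation_error"
  )
})

test_that("weighted skewness matches direct moment arithmetic", {
  tri <- tibble::tibble(temperature = c(60, 65, 70), cp = c(1, 2, 3))
  # m2 = 13.889, m3 = -32.407 computed symbol-by-symbol
  expect_equal(thermogram_skewness(tri), -32.40741 / 13.88889^1.5,
               tolerance = 1e-5)
  expect_equal(thermogram_skewness(tri), -0.626, tolerance = 1e-3)

  # symmetric trace has zero skewness
  tg <- resample_thermogram(make_test_trace(hubbert_peaks(1, 65, 2)),
                            45, 85, 0.1)
  expect_lt(abs(thermogram_skewness(tg)), 1e-10)

  # temperature mirroring flips the sign
  mir <- tibble::tibble(temperature = sort(130 - tri$temperature),
                        cp = rev(tri$cp))
  expect_equal(thermogram_skewness(mir), -thermogram_skewness(tri),
               tolerance = 1e-12)
})

test_that("normalized area is a plain grid sum over a fitted height", {
  dec <- mock_deconvolution(heights = c(1, 2, 1, 1, 1, 1))
  tg <- tibble::tibble(temperature = seq(1, 100), cp = rep(1, 100))
  expect_equal(auc_normalized(tg, dec, 2), 100 / 2)

  # quadrature oracle: a single Hubbert peak integrates to 4*A*w, so the
  # grid sum is close to 4*A*w/step over a wide window
  pk <- hubbert_peaks(1, 0, 2)
  wide <- hubbert_curve(pk, 0, seq(-40, 40, 0.1))
  dec1 <- mock_deconvolution(heights = c(1, 1, 1, 1, 1, 1))
  expect_equal(auc_normalized(wide, dec1, 2), 4 * 1 * 2 / 0.1,
               tolerance = 1e-3)

  expect_error(auc_normalized(tg, dec, 1), class = "tlb_validation_error")
  tiny <- mock_deconvolution(heights = c(1, 1e-12, 1, 1, 1, 1))
  expect_error(auc_normalized(tg, tiny, 2), "degenerate",
               class = "tlb_computation_error")
})

test_that("height-polygon area follows the cyclic hexagon formula", {
  eq <- mock_deconvolution(heights = rep(2, 6))
  for (i in 2:5) {
    expect_equal(polygon_area_normalized(eq, i), 6 * sqrt(3) / 4,
                 tolerance = 1e-12)
  }
  dec <- mock_deconvolution(heights = c(1, 1, 1, 1, 1, 2))
  expect_equal(polygon_area_normalized(dec, 2), sqrt(3) / 4 * 8)
  # scale invariance
  dec10 <- mock_deconvolution(heights = 10 * c(1, 1, 1, 1, 1, 2))
  expect_equal(polygon_area_normalized(dec10, 2),
               polygon_area_normalized(dec, 2))
})

test_that("reference medians and distance values behave as defined", {
  hc <- tibble::tibble(
    t_av = c(67, 68, 69),
    auc_n2 = c(10, 11, 12), auc_n3 = c(10, 11, 12),
    auc_n4 = c(10, 11, 12), auc_n5 = c(10, 11, 12),
    ap_n2 = c(1, 2, 3), ap_n3 = c(1, 2, 3),
    ap_n4 = c(1, 2, 3), ap_n5 = c(1, 2, 3)
  )
  ref <- compute_reference(hc)
  expect_equal(ref$t_av_ref, 68)
  expect_equal(unname(ref$auc_n_ref["i3"]), 11)

  # subject at the reference has zero distance
  at_ref <- tibble::tibble(t_av = 68, auc_n3 = 11, ap_n3 = 2)
  expect_equal(distance_value(at_ref, ref, 3), 0)
  # doubling one coordinate gives a unit relative deviation
  doubled <- tibble::tibble(t_av = 2 * 68, auc_n3 = 11, ap_n3 = 2)
  expect_equal(distance_value(doubled, ref, 3), 1)
  # (0.1, 0.2, 0.2) relative deviations give 0.3
  off <- tibble::tibble(t_av = 68 * 1.1, auc_n3 = 11 * 1.2, ap_n3 = 2 * 1.2)
  expect_equal(distance_value(off, ref, 3), 0.3)

  # even-sized cohort median equals the sort-and-average oracle
  hc4 <- dplyr::bind_rows(hc, hc[2, ] + 10)
  ref4 <- compute_reference(hc4)
  vals <- sort(hc4$t_av)
  expect_equal(ref4$t_av_ref, (vals[2] + vals[3]) / 2)

  expect_error(compute_reference(hc[1:2, ]), "At least 3",
               class = "tlb_validation_error")
})

test_that("the 14-feature vector matches an independent oracle and is scale-free", {
  withr::with_seed(99, {
    heights <- runif(6, 0.2, 1.2)
  })
  dec <- mock_deconvolution(heights = heights)
  tg <- make_test_trace(dec$peaks, noise_sd = 0.004, seed = 5)

  hc_stub <- tibble::tibble(
    t_av = c(64, 65, 66),
    auc_n2 = c(300, 310, 320), auc_n3 = c(200, 210, 220),
    auc_n4 = c(350, 360, 370), auc_n5 = c(400, 410, 420),
    ap_n2 = c(2, 2.2, 2.4), ap_n3 = c(0.8, 0.9, 1.0),
    ap_n4 = c(2.0, 2.2, 2.4), ap_n5 = c(3.0, 3.2, 3.4)
  )
  ref <- compute_reference(hc_stub)

  fv <- compute_features(tg, dec, ref)
  expect_equal(ncol(fv), 14)
  expect_named(fv, c("t_av", "g1", paste0("auc_n", 2:5),
                     paste0("ap_n", 2:5), paste0("dv_", 2:5)))

  oracle <- oracle_features(tg$temperature, tg$cp, heights, ref)
  for (nm in names(fv)) {
    expect_equal(fv[[nm]], oracle[[nm]], tolerance = 1e-10, label = nm)
  }
  expect_true(all(fv[paste0("dv_", 2:5)] >= 0))

  # global rescaling of the trace (and hence the fitted heights) changes
  # nothing: relative change < 1e-9 under k = 0.1 and k = 10
  for (k in c(0.1, 10)) {
    tg_k <- tibble::tibble(temperature = tg$temperature, cp = k * tg$cp)
    dec_k <- mock_deconvolution(heights = k * heights)
    fv_k <- compute_features(tg_k, dec_k, ref)
    expect_equal(as.numeric(fv_k[1, 1:10]), as.numeric(fv[1, 1:10]),
                 tolerance = 1e-9)
  }
})

test_that("featurize_cohort assembles features, reference and distances", {
  sub <- cohort_features(delta = 0.5)
  f <- sub$features
  expect_true(all(model_parameters(3) %in% names(f)))
  expect_equal(nrow(f), 199)
  # HC medians match the reference anchoring the distances
  hc <- f[f$group == "HC", ]
  expect_equal(median(hc$t_av), sub$reference$t_av_ref)
  # distance features are consistent with direct recomputation
  redo <- add_distance_features(f, sub$reference)
  expect_equal(redo$dv_3, f$dv_3)
})

test_that("group medians shift in the expected directions", {
  f <- cohort_features(delta = 0.5)$features
  med <- function(p, g) median(f[[p]][f$group == g])
  expect_gt(med("t_av", "LCP"), med("t_av", "HC"))
  expect_gt(med("g1", "LCP"), med("g1", "HC"))
  expect_gt(med("auc_n3", "LCP"), med("auc_n3", "HC"))
  expect_gt(med("ap_n3", "LCP"), med("ap_n3", "HC"))
  expect_lt(med("auc_n4", "LCP"), med("auc_n4", "HC"))
  expect_lt(med("ap_n4", "LCP"), med("ap_n4", "HC"))
  expect_gt(med("dv_5", "LCP"), med("dv_5", "HC"))
})
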