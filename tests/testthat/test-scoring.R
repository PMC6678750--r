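# Small non-separable feature table for model mechanics.
toy_features <- function(n = 40, seed = 7) {
  withr::with_seed(seed, {
    healthy <- rep(c(TRUE, FALSE), length.out = n)
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n)),
      group = ifelse(healthy, "HC", "LCP"),
      dv_2 = rnorm(n, ifelse(healthy, 1.0, 1.15), 0.3),
      dv_3 = rnorm(n, ifelse(healthy, 1.0, 1.25), 0.3),
      dv_4 = rnorm(n, ifelse(healthy, 1.1, 1.15), 0.3),
      dv_5 = rnorm(n, ifelse(healthy, 1.0, 1.3), 0.3)
    )
  })
}

test_that("an intercept-only situation yields the class frequency as PS", {
  # four subjects, no informative features: coefficients shrink to zero and
  # the intercept reproduces the healthy fraction
  f <- tibble::tibble(
    group = c("HC", "HC", "HC", "LCP"),
    dv_2 = c(1, 1, 1, 1), dv_3 = c(2, 2, 2, 2),
    dv_4 = c(1, 1, 1, 1), dv_5 = c(3, 3, 3, 3)
  )
  # far too few subjects for the coefficient count
  expect_error(fit_score_model(f, variant = 2), "more subjects",
               class = "tlb_validation_error")

  # duplicated columns make the design singular
  dup <- toy_features(30)
  dup$dv_4 <- dup$dv_3
  expect_error(fit_score_model(dup, variant = 2), "Singular",
               class = "tlb_validation_error")

  # same situation expressed through glm directly on a legal design:
  # jittered but label-independent features, large n
  withr::with_seed(2, {
    f2 <- tibble::tibble(
      group = rep(c("HC", "HC", "HC", "LCP"), 50),
      dv_2 = rnorm(200, 1, 0.05), dv_3 = rnorm(200, 1, 0.05),
      dv_4 = rnorm(200, 1, 0.05), dv_5 = rnorm(200, 1, 0.05)
    )
  })
  m <- fit_score_model(f2, variant = 2)
  ps <- predict_ps(m, f2)
  expect_equal(mean(ps), 0.75, tolerance = 1e-6)
})

test_that("predict_ps is the logistic of the linear predictor", {
  m <- fit_score_model(toy_features(), variant = 2)
  # mu = 0 -> 0.5 and mu = ln 3 -> 0.75, checked by direct construction
  fake <- m
  fake$coefficients$estimate <- c(0, 0, 0, 0, 0)
  expect_equal(predict_ps(fake, toy_features()[1, ]), 0.5)
  fake$coefficients$estimate <- c(log(3), 0, 0, 0, 0)
  expect_equal(predict_ps(fake, toy_features()[1, ]), 0.75)
  # large mu saturates toward the healthy end
  fake$coefficients$estimate <- c(50, 0, 0, 0, 0)
  expect_gt(predict_ps(fake, toy_features()[1, ]), 0.999999)
  expect_error(predict_ps(m, toy_features()[, -4]),
               class = "tlb_validation_error")
})

test_that("score equation holds: mean training PS equals the healthy fraction", {
  f <- toy_features(60, seed = 12)
  m <- fit_score_model(f, variant = 2)
  ps <- predict_ps(m, f)
  expect_equal(mean(ps), mean(f$group == "HC"), tolerance = 1e-8)
})

test_that("IRLS deviance equals -2 log-likelihood recomputed from the scores", {
  f <- toy_features(80, seed = 3)
  m <- fit_score_model(f, variant = 2)
  ps <- predict_ps(m, f)
  expect_equal(m$deviance, oracle_neg2ll(ps, as.integer(f$group == "HC")),
               tolerance = 1e-8)
  expect_equal(m$aic, m$deviance + 2 * 5)
  expect_equal(m$bic, m$deviance + 5 * log(80))
  # agrees with the z-value definition
  expect_equal(m$coefficients$z_value,
               m$coefficients$estimate / m$coefficients$std_error)
})

test_that("affine feature rescaling leaves every PS unchanged", {
  f <- toy_features(60, seed = 5)
  m1 <- fit_score_model(f, variant = 2)
  f2 <- f
  f2$dv_3 <- 100 * f2$dv_3 - 7
  m2 <- fit_score_model(f2, variant = 2)
  expect_equal(predict_ps(m2, f2), predict_ps(m1, f), tolerance = 1e-8)
  expect_equal(m2$coefficients$estimate[3] * 100,
               m1$coefficients$estimate[3], tolerance = 1e-6)
})

test_that("classification uses the strict-threshold rule with ties positive", {
  expect_equal(classify_ps(c(0.88, 0.05, 0.5, 0.500001)),
               c("negative", "positive", "positive", "negative"))
  expect_error(classify_ps(1.2), class = "tlb_validation_error")
})

test_that("confusion metrics match a hand-counting oracle", {
  withr::with_seed(9, {
    truth <- sample(c("HC", "LCP"), 30, replace = TRUE)
    pred <- sample(c("positive", "negative"), 30, replace = TRUE)
  })
  cm <- confusion_metrics(truth, pred)
  tp <- sum(truth == "LCP" & pred == "positive")
  fp <- sum(truth == "HC" & pred == "positive")
  tn <- sum(truth == "HC" & pred == "negative")
  fn <- sum(truth == "LCP" & pred == "negative")
  expect_equal(unlist(cm$counts[1, 1:4]), c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(cm$success_rate, 100 * (tp + tn) / 30)
  expect_equal(cm$sensitivity, 100 * tp / (tp + fn))
  expect_equal(cm$specificity, 100 * tn / (tn + fp))
  # margins
  expect_equal(cm$counts$tp + cm$counts$fn, sum(truth == "LCP"))
  expect_equal(cm$counts$tn + cm$counts$fp, sum(truth == "HC"))
  # DOR from unrounded rates equals the count DOR
  if (fn > 0 && fp > 0) {
    expect_equal(dor_from_rates(cm$sensitivity, cm$specificity), cm$dor)
  }
})

test_that("perfect classification flags the corrected DOR", {
  cm <- confusion_from_counts(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_true(cm$dor_corrected)
  expect_equal(cm$success_rate, 100)
  expect_gt(cm$dor, 100)
})

test_that("leave-one-out equals a literal per-fold loop", {
  f <- toy_features(12, seed = 31)
  got <- suppressWarnings(loo_cv(f, variant = 2, reference_policy = "fixed"))
  manual <- vapply(1:12, function(i) {
    m <- suppressWarnings(fit_score_model(f[-i, ], variant = 2))
    predict_ps(m, f[i, ])
  }, numeric(1))
  expect_equal(got$ps$ps, manual, tolerance = 1e-12)
  # bit-identical on repeated runs
  again <- suppressWarnings(loo_cv(f, variant = 2, reference_policy = "fixed"))
  expect_identical(got$ps$ps, again$ps$ps)
})

test_that("per-fold reference recomputation changes held-out distances", {
  sub <- cohort_features(delta = 0.5)
  f <- dplyr::bind_rows(sub$features[sub$features$group == "HC", ][1:20, ],
                        sub$features[sub$features$group == "LCP", ][1:20, ])
  a <- suppressWarnings(loo_cv(f, variant = 2, reference_policy = "per_fold"))
  b <- suppressWarnings(loo_cv(f, variant = 2, reference_policy = "fixed"))
  expect_false(identical(a$ps$ps, b$ps$ps))
  expect_s3_class(glance(a), "tbl_df")
})

test_that("model comparison reports nested-likelihood-ratio identities", {
  f <- cohort_features(delta = 0.5)$features
  models <- suppressWarnings(lapply(1:3, function(v) fit_score_model(f, v)))
  cmp <- compare_models(models)
  expect_equal(cmp$df, c(11, 5, 15))
  expect_equal(cmp$df_residual, 199 - cmp$df)
  expect_equal(cmp$aic, cmp$deviance + 2 * cmp$df)
  expect_equal(cmp$bic, cmp$deviance + cmp$df * log(199))
  expect_true(is.na(cmp$p_vs_full[3]))
  expect_equal(
    cmp$p_vs_full[1],
    pchisq(cmp$deviance[1] - cmp$deviance[3], 4, lower.tail = FALSE)
  )
  # reduced models cannot out-fit the full model
  expect_gte(cmp$deviance[1], cmp$deviance[3])
  expect_gte(cmp$deviance[2], cmp$deviance[3])
})

test_that("score models persist through the flat text format", {
  f <- toy_features(40)
  m <- fit_score_model(f, variant = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_model(m, path)
  back <- read_score_model(path)
  expect_equal(back$coefficients$estimate, m$coefficients$estimate)
  expect_equal(back$variant, m$variant)
  expect_equal(predict_ps(back, f), predict_ps(m, f))
})
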