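#' Fit a probability-score model
#'
#' Binomial generalized linear model with logit link fitted by iteratively
#' reweighted least squares (relative deviance tolerance 1e-10, at most 100
#' iterations). The response is coded healthy = 1, so the fitted probability
#' score PS is the probability of an unaltered (healthy-like) thermogram:
#' \deqn{PS = e^{\mu}/(1+e^{\mu}), \qquad \mu = a_0 + \sum_k a_k p_k.}
#' Three variants differ only in which TLB parameters enter the linear
#' predictor: variant 1 the ten direct parameters, variant 2 the four
#' distances, variant 3 all 14 (see [model_parameters()]).
#'
#' Features enter raw (unstandardized). Quasi-separation (fitted
#' probabilities numerically 0 or 1) is detected and flagged in
#' `separation`; an optional ridge penalty (`lambda > 0`, via glmnet) is
#' available because the distance features are nonlinear functions of the
#' direct ones and can destabilize the full model.
#'
#' @param features Feature tibble including the model's parameter columns
#'   and a group column.
#' @param variant 1, 2 or 3.
#' @param group_col Name of the group column (default `"group"`).
#' @param healthy_label Group value coded as 1 (default `"HC"`).
#' @param lambda Ridge penalty; 0 (default) for plain maximum likelihood.
#' @return Object of class `tlb_score_model`: coefficients with Wald
#'   standard errors, z-values (estimate / SE) and p-values, residual
#'   deviance, residual df, AIC = deviance + 2(k+1), BIC = deviance +
#'   (k+1) log n, convergence and separation flags.
#' @export
fit_score_model <- function(features, variant = 3, group_col = "group",
                            healthy_label = "HC", lambda = 0) {
  params <- model_parameters(variant)
  missing_cols <- setdiff(c(params, group_col), names(features))
  if (length(missing_cols)) {
    tlb_stop(sprintf("Missing columns: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  dat <- as_tibble(features)[, c(params, group_col)]
  if (anyNA(dat)) tlb_stop("Missing values in model features.")
  y <- as.integer(dat[[group_col]] == healthy_label)
  if (all(y == 1) || all(y == 0)) {
    tlb_stop("Both classes must be present to fit the model.")
  }
  n <- length(y)
  k1 <- length(params) + 1L
  if (n <= k1) {
    tlb_stop(sprintf(
      "Need more subjects (%d) than coefficients (%d) to fit variant %s.",
      n, k1, variant
    ))
  }

  if (lambda > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      tlb_stop("Ridge fitting requires the glmnet package.")
    }
    x <- as.matrix(dat[, params])
    gf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = lambda, standardize = FALSE)
    est <- as.numeric(coef(gf))
    mu <- est[1] + drop(x %*% est[-1])
    ps <- stats::plogis(mu)
    dev <- -2 * sum(y * log(ps) + (1 - y) * log1p(-ps))
    coefs <- tibble(term = c("(Intercept)", params), estimate = est,
                    std_error = NA_real_, z_value = NA_real_,
                    p_value = NA_real_)
    fit <- NULL
    converged <- TRUE
    n_iter <- NA_integer_
    separation <- FALSE
  } else {
    dat$.healthy <- y
    fml <- stats::as.formula(
      paste(".healthy ~", paste(params, collapse = " + "))
    )
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      glm(fml, family = binomial(), data = dat,
          control = glm.control(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (qr(stats::model.matrix(fit))$rank < k1) {
      tlb_stop("Singular design matrix.")
    }
    sm <- summary(fit)$coefficients
    coefs <- tibble(
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]),
      z_value = unname(sm[, "z value"]),
      p_value = unname(sm[, "Pr(>|z|)"])
    )
    dev <- fit$deviance
    converged <- fit$converged
    n_iter <- fit$iter
    separation <- sep_warn
    if (separation) {
      warn(sprintf(
        "Quasi-separation detected in variant-%s fit; coefficients may be unstable (consider lambda > 0).",
        variant
      ))
    }
  }

  structure(
    list(
      variant = variant,
      parameter_names = params,
      coefficients = coefs,
      deviance = dev,
      df_residual = n - k1,
      aic = dev + 2 * k1,
      bic = dev + k1 * log(n),
      converged = converged,
      n_iter = n_iter,
      separation = separation,
      lambda = lambda,
      n = n,
      healthy_label = healthy_label,
      glm_fit = fit
    ),
    class = "tlb_score_model"
  )
}

#' @export
print.tlb_score_model <- function(x, ...) {
  cat(sprintf(
    "TLB score model (variant %s): %d parameters, n = %d\n",
    x$variant, length(x$parameter_names), x$n
  ))
  cat(sprintf("  deviance %.2f on %d df;  AIC %.1f;  BIC %.1f\n",
              x$deviance, x$df_residual, x$aic, x$bic))
  if (x$separation) cat("  NOTE: quasi-separation detected\n")
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_score_model Coefficient table (`term`, `estimate`,
#'   `std_error`, `z_value`, `p_value`).
#' @param x,object A `tlb_score_model`.
#' @param ... Unused.
#' @export
tidy.tlb_score_model <- function(x, ...) {
  x$coefficients
}

#' @describeIn fit_score_model One-row fit summary (`variant`, `deviance`,
#'   `df_residual`, `aic`, `bic`, `converged`, `n_iter`, `separation`, `n`).
#' @export
glance.tlb_score_model <- function(x, ...) {
  tibble(variant = x$variant, deviance = x$deviance,
         df_residual = x$df_residual, aic = x$aic, bic = x$bic,
         converged = x$converged, n_iter = x$n_iter,
         separation = x$separation, n = x$n)
}

#' Predict the probability score
#'
#' Applies a fitted score model: PS = plogis(a0 + sum a_k p_k), strictly in
#' (0, 1) and increasing in the linear predictor. PS near 1 indicates an
#' unaltered (healthy-like) thermogram; near 0, an altered one.
#'
#' @param model A `tlb_score_model`.
#' @param features Tibble (or one-row list) providing every parameter the
#'   model uses.
#' @return Numeric vector of probability scores.
#' @export
predict_ps <- function(model, features) {
  stopifnot(inherits(model, "tlb_score_model"))
  features <- as_tibble(features)
  missing_cols <- setdiff(model$parameter_names, names(features))
  if (length(missing_cols)) {
    tlb_stop(sprintf("Features missing model parameters: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  est <- model$coefficients$estimate
  x <- as.matrix(features[, model$parameter_names])
  if (anyNA(x)) tlb_stop("Missing values in model features.")
  mu <- est[1] + drop(x %*% est[-1])
  stats::plogis(mu)
}

#' Classify a probability score
#'
#' PS above the threshold is a negative result (unaltered, healthy-like
#' thermogram); PS below is positive (altered). A score exactly at the
#' threshold is classified positive -- the conservative choice toward
#' clinical follow-up.
#'
#' @param ps Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Character vector, `"negative"` or `"positive"`.
#' @export
classify_ps <- function(ps, threshold = 0.5) {
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) {
    tlb_stop("Probability scores must lie in [0, 1].")
  }
  ifelse(ps > threshold, "negative", "positive")
}

dor_woolf_ci <- function(tp, fp, tn, fn, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  if (min(tp, fp, tn, fn) == 0) {
    tp <- tp + 0.5; fp <- fp + 0.5; tn <- tn + 0.5; fn <- fn + 0.5
  }
  ldor <- log((tp * tn) / (fn * fp))
  se <- sqrt(1 / tp + 1 / fp + 1 / tn + 1 / fn)
  exp(c(ldor - z * se, ldor + z * se))
}

prop_ci <- function(x, n, level = 0.95) {
  # Clopper-Pearson exact interval, in percent
  100 * as.numeric(binom.test(x, n, conf.level = level)$conf.int)
}

new_cohort_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  correct <- tp + tn
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  zero_cell <- (fn == 0 || fp == 0)
  dor <- if (zero_cell) {
    ((tp + 0.5) * (tn + 0.5)) / ((fn + 0.5) * (fp + 0.5))
  } else {
    (tp * tn) / (fn * fp)
  }
  structure(
    list(
      counts = tibble(tp = tp, fp = fp, tn = tn, fn = fn, n = n),
      success_rate = 100 * correct / n,
      sensitivity = sens,
      specificity = spec,
      fpr = 100 - spec,
      fnr = 100 - sens,
      dor = dor,
      dor_corrected = zero_cell,
      ci95 = list(
        success_rate = prop_ci(correct, n),
        sensitivity = prop_ci(tp, tp + fn),
        specificity = prop_ci(tn, tn + fp),
        dor = dor_woolf_ci(tp, fp, tn, fn)
      )
    ),
    class = "tlb_cohort_metrics"
  )
}

#' Confusion-matrix metrics for thermogram classification
#'
#' Positive = diseased/altered. True positives are diseased subjects
#' classified positive; false negatives are diseased subjects whose PS
#' exceeded the threshold; false positives are healthy subjects below it.
#' Reports accuracy (success rate), sensitivity, specificity, false
#' positive/negative rates (percent), and the diagnostic odds ratio
#' DOR = (tp * tn) / (fn * fp), with a Haldane-Anscombe +0.5 correction
#' (flagged via `dor_corrected`) only when a zero cell occurs. 95 percent
#' confidence intervals: Clopper-Pearson exact for the three rates, Woolf
#' log-normal for the DOR.
#'
#' @param truth Group labels (or logical healthy vector).
#' @param predicted Classifications from [classify_ps()] (`"positive"` /
#'   `"negative"`), or a logical "positive" vector.
#' @param healthy_label Group value marking healthy subjects.
#' @return Object of class `tlb_cohort_metrics`.
#' @export
confusion_metrics <- function(truth, predicted, healthy_label = "HC") {
  if (length(truth) != length(predicted)) {
    tlb_stop("`truth` and `predicted` must have equal length.")
  }
  healthy <- if (is.logical(truth)) truth else truth == healthy_label
  positive <- if (is.logical(predicted)) predicted else predicted == "positive"
  if (!any(healthy) || all(healthy)) {
    tlb_stop("Both classes must be present in `truth`.")
  }
  new_cohort_metrics(
    tp = sum(!healthy & positive),
    fp = sum(healthy & positive),
    tn = sum(healthy & !positive),
    fn = sum(!healthy & !positive)
  )
}

#' @describeIn confusion_metrics Build metrics directly from the four
#'   confusion counts.
#' @param tp,fp,tn,fn Confusion counts (positive = diseased).
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    tlb_stop("Counts must be non-negative integers.")
  }
  if (tp + fn == 0 || tn + fp == 0) {
    tlb_stop("Both classes must be present.")
  }
  new_cohort_metrics(tp, fp, tn, fn)
}

#' Diagnostic odds ratio from percentage rates
#'
#' DOR expressed through the rates alone:
#' (sens / (100 - sens)) * (spec / (100 - spec)). Equals the count-based
#' DOR when computed from unrounded rates.
#'
#' @param sensitivity,specificity Rates in percent.
#' @return The diagnostic odds ratio.
#' @export
dor_from_rates <- function(sensitivity, specificity) {
  if (sensitivity <= 0 || sensitivity >= 100 ||
      specificity <= 0 || specificity >= 100) {
    tlb_stop("Rates must lie strictly between 0 and 100 percent.")
  }
  (sensitivity / (100 - sensitivity)) * (specificity / (100 - specificity))
}

#' @export
print.tlb_cohort_metrics <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "Confusion counts: tp %d  fp %d  tn %d  fn %d  (n = %d)\n",
    tp, fp, tn, fn, n
  )))
  cat(sprintf(
    "  success %d%% (CI95 %d-%d)  sensitivity %d%% (CI95 %d-%d)  specificity %d%% (CI95 %d-%d)\n",
    round(x$success_rate), round(x$ci95$success_rate[1]),
    round(x$ci95$success_rate[2]),
    round(x$sensitivity), round(x$ci95$sensitivity[1]),
    round(x$ci95$sensitivity[2]),
    round(x$specificity), round(x$ci95$specificity[1]),
    round(x$ci95$specificity[2])
  ))
  cat(sprintf("  DOR %.0f (CI95 %.0f-%.0f)%s\n", x$dor, x$ci95$dor[1],
              x$ci95$dor[2],
              if (x$dor_corrected) " [zero-cell corrected]" else ""))
  invisible(x)
}

#' @describeIn confusion_metrics One-row tibble of counts and rates.
#' @param x A `tlb_cohort_metrics` object.
#' @param ... Unused.
#' @export
tidy.tlb_cohort_metrics <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble(
      success_rate = x$success_rate, sensitivity = x$sensitivity,
      specificity = x$specificity, fpr = x$fpr, fnr = x$fnr, dor = x$dor,
      dor_corrected = x$dor_corrected,
      success_lo = x$ci95$success_rate[1], success_hi = x$ci95$success_rate[2],
      sens_lo = x$ci95$sensitivity[1], sens_hi = x$ci95$sensitivity[2],
      spec_lo = x$ci95$specificity[1], spec_hi = x$ci95$specificity[2],
      dor_lo = x$ci95$dor[1], dor_hi = x$ci95$dor[2]
    )
  )
}

#' Leave-one-out cross-validation of a score model
#'
#' Refits the model n times, each time excluding one subject, and predicts
#' that subject's PS from the refit. By default
#' (`reference_policy = "per_fold"`) the healthy reference medians behind
#' the distance features are recomputed from the HC members of each training
#' fold, so no information from the held-out subject leaks into its own
#' features; `"fixed"` keeps the distance features as supplied.
#'
#' @inheritParams fit_score_model
#' @param reference_policy `"per_fold"` (default) or `"fixed"`.
#' @param threshold Classification threshold (default 0.5).
#' @return Object of class `tlb_loo`: `ps` (tibble with `subject_id`,
#'   `group`, `ps`, `class`), `metrics` (`tlb_cohort_metrics`), plus the
#'   settings. Deterministic.
#' @export
loo_cv <- function(features, variant = 3,
                   reference_policy = c("per_fold", "fixed"),
                   threshold = 0.5, group_col = "group",
                   healthy_label = "HC", lambda = 0) {
  reference_policy <- match.arg(reference_policy)
  features <- as_tibble(features)
  n <- nrow(features)
  if (n < 10) tlb_stop("Leave-one-out needs at least 10 subjects.")
  if (!"subject_id" %in% names(features)) {
    features$subject_id <- as.character(seq_len(n))
  }
  uses_dv <- variant %in% c(2, 3)
  ps <- vapply(seq_len(n), function(i) {
    train <- features[-i, ]
    test <- features[i, ]
    if (uses_dv && reference_policy == "per_fold") {
      ref <- compute_reference(
        train[train[[group_col]] == healthy_label, ]
      )
      train <- add_distance_features(train, ref)
      test <- add_distance_features(test, ref)
    }
    m <- fit_score_model(train, variant = variant, group_col = group_col,
                         healthy_label = healthy_label, lambda = lambda)
    predict_ps(m, test)
  }, numeric(1))
  out <- tibble(
    subject_id = features$subject_id,
    group = features[[group_col]],
    ps = ps,
    class = classify_ps(ps, threshold)
  )
  structure(
    list(
      ps = out,
      metrics = confusion_metrics(out$group, out$class, healthy_label),
      variant = variant,
      reference_policy = reference_policy,
      threshold = threshold
    ),
    class = "tlb_loo"
  )
}

#' @export
print.tlb_loo <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out cross-validation (variant %s, %s reference)\n",
    x$variant, x$reference_policy
  ))
  print(x$metrics)
  invisible(x)
}

#' @describeIn loo_cv Held-out per-subject scores as a tibble.
#' @param x A `tlb_loo` object.
#' @param ... Unused.
#' @export
tidy.tlb_loo <- function(x, ...) {
  x$ps
}

#' @describeIn loo_cv One-row summary of held-out performance.
#' @export
glance.tlb_loo <- function(x, ...) {
  dplyr::bind_cols(
    tibble(variant = x$variant, reference_policy = x$reference_policy),
    tidy(x$metrics)
  )
}

#' Compare nested score models
#'
#' Likelihood-ratio and information-criterion comparison of the three model
#' variants fit on the same subjects. The reduced variants (1 and 2) are
#' nested in the full variant 3 by construction, so the deviance difference
#' is referred to a chi-square with the difference in parameter count as
#' degrees of freedom.
#'
#' @param models List of `tlb_score_model` objects fit on identical data
#'   (the one with the most parameters is taken as the full model).
#' @return A tibble with one row per model: `variant`, `df` (coefficients),
#'   `df_residual`, `deviance`, `delta_df` (vs full), `p_vs_full`, `aic`,
#'   `bic`.
#' @export
compare_models <- function(models) {
  if (!all(vapply(models, inherits, logical(1), "tlb_score_model"))) {
    tlb_stop("`models` must be a list of tlb_score_model objects.")
  }
  ns <- vapply(models, function(m) m$n, numeric(1))
  if (length(unique(ns)) != 1) {
    tlb_stop("Models must be fit on the same subjects.")
  }
  k <- vapply(models, function(m) length(m$parameter_names) + 1, numeric(1))
  full <- models[[which.max(k)]]
  purrr::map_dfr(models, function(m) {
    is_full <- identical(m, full)
    nested <- all(m$parameter_names %in% full$parameter_names)
    if (!is_full && !nested) {
      tlb_stop("Likelihood-ratio comparison requires nested models.")
    }
    delta_df <- (length(full$parameter_names) - length(m$parameter_names))
    tibble(
      variant = m$variant,
      df = length(m$parameter_names) + 1,
      df_residual = m$df_residual,
      deviance = m$deviance,
      delta_df = if (is_full) NA_integer_ else delta_df,
      p_vs_full = if (is_full) NA_real_ else
        pchisq(m$deviance - full$deviance, delta_df, lower.tail = FALSE),
      aic = m$aic,
      bic = m$bic
    )
  })
}

#' Information-criterion identities for a binomial logit fit
#'
#' For a Bernoulli response the saturated log-likelihood is zero, so the
#' residual deviance equals -2 log L and the criteria reduce to
#' AIC = deviance + 2 k and BIC = deviance + k log n, with k the number of
#' fitted coefficients (intercept included).
#'
#' @param deviance Residual deviance.
#' @param n_coef Number of fitted coefficients, intercept included.
#' @param n Number of subjects.
#' @return One-row tibble with `aic`, `bic`, `df_residual`.
#' @export
information_criteria <- function(deviance, n_coef, n) {
  if (deviance < 0 || n_coef < 1 || n <= n_coef) {
    tlb_stop("Need deviance >= 0 and n > n_coef >= 1.")
  }
  tibble(aic = deviance + 2 * n_coef,
         bic = deviance + n_coef * log(n),
         df_residual = n - n_coef)
}

#' Persist a score model as a flat text record
#'
#' @param model A `tlb_score_model`.
#' @param path Output path (CSV; one row per coefficient plus a header
#'   block of fit statistics encoded as comment lines).
#' @return `path`, invisibly.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "tlb_score_model"))
  hdr <- sprintf(
    "# tlb_score_model variant=%s n=%d deviance=%.15g aic=%.15g bic=%.15g df_residual=%d lambda=%g healthy_label=%s",
    model$variant, model$n, model$deviance, model$aic, model$bic,
    model$df_residual, model$lambda, model$healthy_label
  )
  writeLines(hdr, path)
  suppressWarnings(readr::write_csv(model$coefficients, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' Load a score model written by [write_score_model()]
#'
#' @param path Path to the model file.
#' @return A `tlb_score_model` (without the underlying glm object).
#' @export
read_score_model <- function(path) {
  if (!file.exists(path)) tlb_stop(sprintf("File not found: %s", path))
  hdr <- readLines(path, n = 1)
  if (!grepl("^# tlb_score_model", hdr)) {
    tlb_stop("Not a tlb_score_model file.")
  }
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  coefs <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  structure(
    list(
      variant = as.integer(vals[["variant"]]),
      parameter_names = coefs$term[-1],
      coefficients = coefs,
      deviance = as.numeric(vals[["deviance"]]),
      df_residual = as.integer(vals[["df_residual"]]),
      aic = as.numeric(vals[["aic"]]),
      bic = as.numeric(vals[["bic"]]),
      converged = TRUE,
      n_iter = NA_integer_,
      separation = FALSE,
      lambda = as.numeric(vals[["lambda"]]),
      n = as.integer(vals[["n"]]),
      healthy_label = vals[["healthy_label"]],
      glm_fit = NULL
    ),
    class = "tlb_score_model"
  )
}
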