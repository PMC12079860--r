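#' Clip serum biomarkers to assay detection limits
#'
#' Clamps AFP to \[0.5, 2000\] ng/mL and PIVKA-II to \[5, 75000\] mAU/mL,
#' the reporting limits of the clinical assays; values outside the range are
#' set to the nearest limit, in-range values are unchanged.
#'
#' @param data Tibble with `afp` and `pivka` columns.
#' @param afp_limits,pivka_limits Two-element numeric limits.
#' @return `data` with clipped `afp` and `pivka`.
#' @export
clip_to_detection_limits <- function(data,
                                     afp_limits = c(0.5, 2000),
                                     pivka_limits = c(5, 75000)) {
  assert_columns(data, c("afp", "pivka"), "data")
  data |>
    mutate(
      afp = pmin(pmax(.data$afp, afp_limits[1]), afp_limits[2]),
      pivka = pmin(pmax(.data$pivka, pivka_limits[1]), pivka_limits[2])
    )
}

#' ASAP risk score
#'
#' The published logistic risk score combining Age, Sex, AFP and PIVKA-II:
#' `Z = -6.836 + 0.042 * age + 0.989 * sex + 1.841 * log10(AFP) +
#' 0.949 * log10(PIVKA-II)`, with sex coded 1 for male and 0 for female and
#' base-10 logarithms. Non-positive biomarker values are raised to the assay
#' detection floor before the logarithm; full detection-limit clipping of a
#' cohort is the job of [clip_to_detection_limits()].
#'
#' @param age Age in years.
#' @param sex 1 = male, 0 = female.
#' @param afp AFP in ng/mL.
#' @param pivka PIVKA-II in mAU/mL.
#' @return Numeric score vector.
#' @examples
#' asap_score(65, 1, 10, 100)   # 0.622
#' @export
asap_score <- function(age, sex, afp, pivka) {
  if (!all(sex %in% c(0, 1))) stop_medseqr("`sex` must be coded 1 = male, 0 = female.")
  afp <- ifelse(afp <= 0, 0.5, afp)
  pivka <- ifelse(pivka <= 0, 5, pivka)
  -6.836 + 0.042 * age + 0.989 * sex + 1.841 * log10(afp) + 0.949 * log10(pivka)
}

#' Add the ASAP score to a cohort table
#'
#' @param data Cohort tibble with age, sex, afp, pivka columns.
#' @return `data` with an `asap` column.
#' @export
add_asap_score <- function(data) {
  assert_columns(data, c("age", "sex", "afp", "pivka"), "data")
  mutate(data, asap = asap_score(.data$age, .data$sex, .data$afp, .data$pivka))
}

#' Fit a combined logistic classifier
#'
#' Binary logistic regression over the named feature columns. With
#' `method = "enter"` all features are retained; with `method = "backward"`
#' the feature with the largest Wald p-value is removed iteratively until
#' every remaining feature has p <= `p_remove` (intercept always kept;
#' elimination may empty the feature set). Perfect separation is detected
#' from the glm convergence warning and flagged on the result rather than
#' erroring; coefficients from a separated fit are at the boundary and
#' should be interpreted through the flag.
#'
#' @param data Tibble containing the response and feature columns, no
#'   missing values.
#' @param response Name of the response column; coerced to 0/1 with `case`
#'   as 1.
#' @param features Character vector of feature column names.
#' @param case Response level treated as the positive class.
#' @param method "enter" or "backward".
#' @param p_remove Wald-p removal threshold for backward elimination.
#' @return Object of class `combined_fit` with [tidy()], [glance()] and
#'   [predict()] methods.
#' @export
fit_combined <- function(data, response, features, case,
                         method = c("enter", "backward"), p_remove = 0.05) {
  method <- match.arg(method)
  assert_columns(data, c(response, features), "data")
  if (anyNA(data[, c(response, features)])) {
    stop_medseqr("missing values in response or features.")
  }
  y <- as.integer(data[[response]] == case)
  if (min(sum(y), sum(1 - y)) < 10) {
    warn("fewer than 10 samples in a class; coefficient estimates will be unstable.")
  }
  df <- data[, features, drop = FALSE]
  df$.y <- y

  separation <- FALSE
  fit_once <- function(feats) {
    fml <- stats::as.formula(paste(".y ~", if (length(feats) == 0L) "1" else
      paste(sprintf("`%s`", feats), collapse = " + ")))
    withCallingHandlers(
      glm(fml, data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
  }

  feats <- features
  fit <- fit_once(feats)
  if (method == "backward") {
    repeat {
      if (length(feats) == 0L) break
      p <- summary(fit)$coefficients[, "Pr(>|z|)"]
      p <- p[names(p) != "(Intercept)"]
      names(p) <- gsub("`", "", names(p))
      worst <- names(p)[which.max(p)]
      if (max(p) <= p_remove) break
      feats <- setdiff(feats, worst)
      fit <- fit_once(feats)
    }
  }

  structure(
    list(fit = fit, features = feats, features_entered = features,
         method = method, response = response, case = case,
         separation = separation, n_case = sum(y), n_control = sum(1 - y)),
    class = "combined_fit"
  )
}

#' @export
print.combined_fit <- function(x, ...) {
  cat(sprintf("<combined_fit> logistic (%s): %s ~ %s\n", x$method, x$response,
              if (length(x$features)) paste(x$features, collapse = " + ") else "1"))
  if (x$separation) cat("  note: perfect separation detected\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_combined
#' @param object,x A `combined_fit`.
#' @param newdata Tibble with the model's feature columns.
#' @param ... Unused.
#' @export
predict.combined_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0L) {
    stop_medseqr(sprintf("feature(s) missing from newdata: %s.",
                         paste(miss, collapse = ", ")))
  }
  unname(predict(object$fit, newdata = newdata, type = "response"))
}

#' @rdname fit_combined
#' @method tidy combined_fit
#' @export
tidy.combined_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = gsub("`", "", rownames(cf)),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "z value"],
    p_value = cf[, "Pr(>|z|)"]
  )
}

#' @rdname fit_combined
#' @method glance combined_fit
#' @export
glance.combined_fit <- function(x, ...) {
  ll <- as.numeric(logLik(x$fit))
  k <- length(coef(x$fit))
  scores <- predict(x$fit, type = "response")
  tibble(
    n = x$n_case + x$n_control,
    n_case = x$n_case,
    n_control = x$n_control,
    log_lik = ll,
    aic = 2 * k - 2 * ll,
    auc = rank_auc(scores, x$fit$y, 1),
    separation = x$separation
  )
}

#' Evaluate classifier scores at a fixed specificity
#'
#' Computes the AUC (rank/Mann-Whitney formulation; higher scores indicate
#' the case class) and an operating point: the smallest threshold whose
#' specificity on the controls is at least `fixed_specificity` (predicted
#' positive = score strictly above the threshold). Sensitivity and achieved
#' specificity are reported at that threshold. Passing a `threshold` from a
#' training evaluation carries the operating point over unchanged, the
#' validation-cohort convention: achieved specificity may then drift from
#' the nominal value.
#'
#' @param scores Numeric score vector.
#' @param labels Group labels, same length.
#' @param case,control Labels of the two classes.
#' @param fixed_specificity Target specificity in \[0,1\].
#' @param threshold Optional fixed threshold (overrides the operating-point
#'   search).
#' @return Object of class `classifier_eval` with [glance()] (one-row
#'   metrics), [tidy()] (ROC coordinates) and [autoplot()] methods.
#' @examples
#' ev <- evaluate_classifier(c(.9, .8, .4, .7, .3, .2),
#'                           rep(c("HCC", "cirrhosis"), each = 3),
#'                           "HCC", "cirrhosis", fixed_specificity = 2 / 3)
#' glance(ev)
#' @export
evaluate_classifier <- function(scores, labels, case, control,
                                fixed_specificity = 0.813, threshold = NULL) {
  assert_scalar_number(fixed_specificity, "fixed_specificity", lower = 0, upper = 1)
  keep <- labels %in% c(case, control)
  scores <- scores[keep]
  labels <- labels[keep]
  n_case <- sum(labels == case)
  n_control <- sum(labels == control)
  if (n_case == 0L || n_control == 0L) {
    stop_medseqr("both classes must be present to evaluate a classifier.")
  }
  auc <- rank_auc(scores, labels, case)

  ctrl <- scores[labels == control]
  if (is.null(threshold)) {
    cand <- sort(unique(scores))
    spec_at <- vapply(cand, function(t) mean(ctrl <= t), numeric(1))
    ok <- which(spec_at >= fixed_specificity)
    threshold <- if (length(ok) == 0L) max(cand) else cand[min(ok)]
  }
  sensitivity <- mean(scores[labels == case] > threshold)
  specificity <- mean(ctrl <= threshold)

  structure(
    list(
      auc = auc, threshold = threshold,
      sensitivity = sensitivity, specificity = specificity,
      fixed_specificity = fixed_specificity,
      n_case = n_case, n_control = n_control,
      scores = scores, labels = labels, case = case, control = control
    ),
    class = "classifier_eval"
  )
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf(
    "<classifier_eval> AUC %.3f | sens %.1f%% at spec %.1f%% (target %.1f%%) | n = %d + %d\n",
    x$auc, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$fixed_specificity, x$n_case, x$n_control
  ))
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x,object A `classifier_eval`.
#' @param ... Unused.
#' @method glance classifier_eval
#' @export
glance.classifier_eval <- function(x, ...) {
  tibble(
    auc = x$auc, threshold = x$threshold,
    sensitivity = x$sensitivity, specificity = x$specificity,
    fixed_specificity = x$fixed_specificity,
    n_case = x$n_case, n_control = x$n_control
  )
}

#' @rdname evaluate_classifier
#' @method tidy classifier_eval
#' @export
tidy.classifier_eval <- function(x, ...) {
  cand <- c(-Inf, sort(unique(x$scores)))
  purrr::map_dfr(cand, function(t) {
    tibble(
      threshold = t,
      sensitivity = mean(x$scores[x$labels == x$case] > t),
      specificity = mean(x$scores[x$labels == x$control] <= t)
    )
  })
}

#' Paired DeLong test for an AUC difference
#'
#' Compares the AUCs of two score vectors computed on the same samples with
#' the paired DeLong test. Identical rankings (e.g. a model against its own
#' monotone transform) give a zero AUC difference and p = 1.
#'
#' @param scores_a,scores_b Paired score vectors on identical samples.
#' @param labels Class labels.
#' @param case,control The two class labels.
#' @return Tibble (auc_a, auc_b, delta, p_value).
#' @export
compare_auc <- function(scores_a, scores_b, labels, case, control) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop_medseqr("scores and labels must have identical length (paired design).")
  }
  keep <- labels %in% c(case, control)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]; labels <- labels[keep]
  auc_a <- rank_auc(scores_a, labels, case)
  auc_b <- rank_auc(scores_b, labels, case)
  if (identical(rank(scores_a), rank(scores_b))) {
    return(tibble(auc_a = auc_a, auc_b = auc_b, delta = 0, p_value = 1))
  }
  roc_a <- pROC::roc(response = labels, predictor = scores_a,
                     levels = c(control, case), direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(response = labels, predictor = scores_b,
                     levels = c(control, case), direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  p <- as.numeric(tst$p.value)
  if (is.na(p)) p <- 1  # zero-variance difference
  tibble(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b, p_value = p)
}
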