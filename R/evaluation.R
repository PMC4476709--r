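new_classification_result <- function(accuracy, sensitivity, specificity, se,
                                      n, p_value, test, threshold = NA_real_,
                                      correct = NULL, counts = NULL) {
  structure(
    list(
      accuracy = accuracy, sensitivity = sensitivity,
      specificity = specificity, se = se, n = n, p_value = p_value,
      test = test, threshold = threshold, correct = correct, counts = counts
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %s: accuracy %.1f%% (SE %.1f%%), n = %d, p = %.3g\n",
    x$test, 100 * x$accuracy, 100 * x$se, x$n, x$p_value
  ))
  if (!is.na(x$threshold)) {
    cat(sprintf(
      "  threshold %.4g; sensitivity %.1f%%, specificity %.1f%%\n",
      x$threshold, 100 * x$sensitivity, 100 * x$specificity
    ))
  }
  invisible(x)
}

#' Forced-choice classification between two within-subject conditions
#'
#' Each subject contributes a pair of pattern responses, one per condition;
#' the higher-intensity condition is predicted to have the larger response.
#' Accuracy is the fraction of subjects for which the designated
#' higher-intensity condition wins (ties credited 1/2). Because the
#' comparison is relative and threshold-free, sensitivity, specificity and
#' positive predictive value all equal the accuracy, and the statistic is
#' invariant to any strictly increasing transform of the responses.
#' Significance versus chance is an exact two-tailed binomial test on strict
#' wins among non-tied pairs.
#'
#' @param high responses in the designated higher-intensity condition, one
#'   per subject.
#' @param low responses in the lower-intensity condition, aligned with
#'   `high`. Pairs with a missing member are excluded.
#' @return A `classification_result`.
#' @export
forced_choice <- function(high, low) {
  ok <- is.finite(high) & is.finite(low)
  high <- high[ok]
  low <- low[ok]
  n <- length(high)
  if (n < 1L) stop("no complete pairs", call. = FALSE)
  wins <- sum(high > low)
  ties <- sum(high == low)
  acc <- (wins + 0.5 * ties) / n
  n_eff <- n - ties
  p <- if (n_eff > 0) {
    stats::binom.test(wins, n_eff, p = 0.5)$p.value
  } else {
    1
  }
  new_classification_result(
    accuracy = acc, sensitivity = acc, specificity = acc,
    se = sqrt(acc * (1 - acc) / n), n = n, p_value = p,
    test = "forced-choice (exact binomial)",
    correct = ifelse(high == low, NA, high > low)
  )
}

clamp_rate <- function(r, n) {
  pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Single-interval classification with a bias-minimizing threshold
#'
#' Labels each observation by comparing its response to a fixed threshold.
#' The threshold is chosen by brute-force scan over the midpoints between
#' adjacent sorted responses (plus one candidate below the minimum and one
#' above the maximum) to minimize the absolute signal-detection response
#' bias `c = -(qnorm(TPR) + qnorm(FPR)) / 2`, with rates clamped at
#' `1/(2n)` per class before the probit transform; ties in |c| are broken
#' toward higher balanced accuracy, then lower threshold. The reported
#' accuracy is the balanced accuracy `b = (TPR + TNR) / 2`, robust to class
#' imbalance. Significance versus chance (50%) is an exact two-tailed
#' binomial test on total correct classifications.
#'
#' @param responses numeric responses.
#' @param labels logical (or 0/1): `TRUE` marks the positive (high
#'   intensity) class.
#' @return A `classification_result` with the chosen `threshold`.
#' @export
single_interval <- function(responses, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(responses) & !is.na(labels)
  responses <- responses[ok]
  labels <- labels[ok]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- sort(unique(responses))
  cand <- if (length(s) > 1L) {
    c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  } else {
    c(s - 1, s + 1)
  }
  best <- NULL
  for (t in cand) {
    pred <- responses > t
    tp <- sum(pred & labels)
    tn <- sum(!pred & !labels)
    tpr <- tp / n_pos
    fpr <- (n_neg - tn) / n_neg
    bias <- -(stats::qnorm(clamp_rate(tpr, n_pos)) +
      stats::qnorm(clamp_rate(fpr, n_neg))) / 2
    b <- (tpr + (tn / n_neg)) / 2
    key <- c(abs(bias), -b, t)
    if (is.null(best) ||
      key[1] < best$key[1] - 1e-12 ||
      (abs(key[1] - best$key[1]) <= 1e-12 && key[2] < best$key[2] - 1e-12) ||
      (abs(key[1] - best$key[1]) <= 1e-12 &&
        abs(key[2] - best$key[2]) <= 1e-12 && key[3] < best$key[3])) {
      best <- list(key = key, t = t, tp = tp, tn = tn, b = b, tpr = tpr,
        tnr = tn / n_neg, pred = pred)
    }
  }
  n <- n_pos + n_neg
  correct <- best$pred == labels
  p <- stats::binom.test(sum(correct), n, p = 0.5)$p.value
  se <- sqrt(best$tpr * (1 - best$tpr) / (4 * n_pos) +
    best$tnr * (1 - best$tnr) / (4 * n_neg))
  new_classification_result(
    accuracy = best$b, sensitivity = best$tpr, specificity = best$tnr,
    se = se, n = n, p_value = p,
    test = "single-interval (balanced accuracy, bias-minimizing threshold)",
    threshold = best$t, correct = correct,
    counts = c(tp = best$tp, fn = n_pos - best$tp, tn = best$tn,
      fp = n_neg - best$tn)
  )
}

#' Prediction error and correlation metrics
#'
#' RMSE and Pearson correlation between predicted and actual outcomes,
#' optionally within grouping units (subjects) and averaged across units
#' with standard errors. Groups with fewer than two pairs or constant
#' vectors get `r = NA` and are flagged.
#'
#' @param predicted,actual paired numeric vectors.
#' @param group optional grouping vector (e.g. subject ids).
#' @return A list with `pooled_r`, `pooled_rmse` and, when grouped,
#'   `by_group` (tibble: group, n, r, rmse, r_defined), `mean_r`, `se_r`,
#'   `mean_rmse`, `se_rmse`.
#' @export
prediction_metrics <- function(predicted, actual, group = NULL) {
  stopifnot(length(predicted) == length(actual))
  rmse <- sqrt(mean((predicted - actual)^2))
  pooled_r <- if (stats::sd(predicted) > 0 && stats::sd(actual) > 0) {
    stats::cor(predicted, actual)
  } else {
    NA_real_
  }
  out <- list(pooled_r = pooled_r, pooled_rmse = rmse)
  if (!is.null(group)) {
    df <- tibble::tibble(predicted = predicted, actual = actual, group = group)
    by <- dplyr::summarise(
      dplyr::group_by(df, .data$group),
      n = dplyr::n(),
      r = if (dplyr::n() >= 2 && stats::sd(.data$predicted) > 0 &&
        stats::sd(.data$actual) > 0) {
        stats::cor(.data$predicted, .data$actual)
      } else {
        NA_real_
      },
      rmse = sqrt(mean((.data$predicted - .data$actual)^2)),
      .groups = "drop"
    )
    by$r_defined <- !is.na(by$r)
    rs <- by$r[by$r_defined]
    out$by_group <- by
    out$mean_r <- mean(rs)
    out$se_r <- stats::sd(rs) / sqrt(length(rs))
    out$mean_rmse <- mean(by$rmse)
    out$se_rmse <- stats::sd(by$rmse) / sqrt(nrow(by))
  }
  out
}

#' Compare two classification accuracies
#'
#' Dependent designs (the same units classified by two patterns) use
#' McNemar's test on discordant pairs, `chi2 = (b - c)^2 / (b + c)`;
#' independent designs use a two-sample two-tailed z-test for proportions.
#'
#' @param res_a,res_b `classification_result`s. For the dependent design
#'   both must carry aligned per-unit `correct` vectors.
#' @param design `"dependent"` or `"independent"`.
#' @return Tibble with `statistic`, `p_value`, `method`, and discordant
#'   counts for McNemar.
#' @export
compare_accuracies <- function(res_a, res_b,
                               design = c("dependent", "independent")) {
  design <- match.arg(design)
  if (design == "dependent") {
    ca <- res_a$correct
    cb <- res_b$correct
    ok <- !is.na(ca) & !is.na(cb)
    ca <- ca[ok]
    cb <- cb[ok]
    if (length(ca) != length(cb) || !length(ca)) {
      stop("dependent comparison needs aligned per-unit outcomes", call. = FALSE)
    }
    b <- sum(ca & !cb)
    cc <- sum(!ca & cb)
    if (b + cc == 0L) {
      return(tibble::tibble(
        statistic = 0, p_value = 1, method = "McNemar chi-squared",
        b = b, c = cc, note = "no discordant pairs"
      ))
    }
    chi2 <- (b - cc)^2 / (b + cc)
    tibble::tibble(
      statistic = chi2,
      p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
      method = "McNemar chi-squared", b = b, c = cc, note = NA_character_
    )
  } else {
    p1 <- res_a$accuracy
    p2 <- res_b$accuracy
    n1 <- res_a$n
    n2 <- res_b$n
    pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
    denom <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    z <- if (denom > 0) (p1 - p2) / denom else 0
    tibble::tibble(
      statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
      method = "two-proportion z", b = NA_integer_, c = NA_integer_,
      note = NA_character_
    )
  }
}

#' Linear and quadratic trend tests across ordinal levels
#'
#' Applies orthogonal polynomial contrasts to each subject's level means
#' and tests the contrast estimates against zero across subjects with
#' one-sample t-tests. Subjects missing a level are dropped from the
#' contrast (orthogonality requires the full level set).
#'
#' @param data data frame with columns `subject_id`, `level` (ordinal), and
#'   `response`.
#' @return Tibble with one row per contrast (`linear`, `quadratic`):
#'   `estimate` (mean contrast), `se`, `statistic`, `df`, `p_value`,
#'   `n_subjects`.
#' @export
trend_test <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("subject_id", "level", "response") %in% names(data)))
  levels_all <- sort(unique(data$level))
  k <- length(levels_all)
  if (k < 3L) stop("need at least 3 levels for trend tests", call. = FALSE)
  contr <- stats::contr.poly(k)
  by_subj <- dplyr::summarise(
    dplyr::group_by(data, .data$subject_id, .data$level),
    response = mean(.data$response), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(by_subj,
    names_from = "level", values_from = "response"
  )
  mat <- as.matrix(wide[, as.character(levels_all)])
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  if (!nrow(mat)) stop("no subject has all levels", call. = FALSE)
  purrr::map_dfr(c(linear = 1L, quadratic = 2L), function(j) {
    est <- as.numeric(mat %*% contr[, j])
    n <- length(est)
    se <- stats::sd(est) / sqrt(n)
    if (se == 0) {
      # contrast identical across subjects: no sampling variability
      stat <- if (mean(est) == 0) 0 else sign(mean(est)) * Inf
      p <- if (mean(est) == 0) 1 else 0
    } else {
      stat <- mean(est) / se
      p <- 2 * stats::pt(-abs(stat), df = n - 1)
    }
    tibble::tibble(
      estimate = mean(est), se = se, statistic = stat, df = n - 1,
      p_value = p, n_subjects = n
    )
  }, .id = "term")
}
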