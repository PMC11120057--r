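# Evaluation of per-patient scores against tumor aggressiveness: linear
# fit to ISUP grade (Pearson R, p), CsPCa labels, ROC/AUC, and the
# 1000-fold resampled 70/30 logistic AUC confidence interval.

#' Linear fit of scores to ISUP grade
#'
#' Ordinary least squares of grade on score, with the Pearson correlation
#' and the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param scores per-patient scalars.
#' @param isup per-patient grades.
#' @return list with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
linear_fit <- function(scores, isup) {
  n <- length(scores)
  stopifnot(n == length(isup), n >= 3L)
  if (stats::var(scores) == 0 || stats::var(isup) == 0)
    stop("zero variance: undefined fit")
  r <- stats::cor(scores, isup)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(t), df = n - 2), .Machine$double.xmin)
  }
  fit <- stats::lm.fit(cbind(1, scores), isup)
  list(r = r, p_value = p, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = n)
}

#' Clinically significant cancer labels
#'
#' CsPCa is assigned to ISUP grade >= 2; grades below 2 are clinically
#' insignificant (CiPCa).
#'
#' @param isup integer grades in 0..5.
#' @return logical vector.
#' @export
cspca_labels <- function(isup) {
  if (any(is.na(isup)) || any(isup < 0 | isup > 5 | isup != round(isup)))
    stop("ISUP grades must be integers in 0..5")
  isup >= 2
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (score >= threshold is called
#' positive); the AUC is the trapezoidal area, equal to the Mann-Whitney
#' statistic with ties counted 1/2.
#'
#' @param scores per-patient scalars (larger = more positive).
#' @param labels logical (or 0/1) class labels; both classes must be
#'   present.
#' @return list with `fpr`, `tpr` (curve points, thresholds descending) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("ROC undefined: only one class present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nneg, numeric(1))
  rk <- rank(scores)   # ties get average ranks -> ties counted 1/2
  auc <- (sum(rk[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

# univariate logistic probability fit + test-set AUC for one split
logistic_split_auc <- function(scores, labels, train, test) {
  df <- data.frame(y = as.numeric(labels), x = scores)
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(), data = df[train, ],
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  prob <- suppressWarnings(
    stats::predict(fit, newdata = df[test, ], type = "response"))
  roc_auc(prob, labels[test])$auc
}

#' Resampled logistic AUC with percentile confidence interval
#'
#' Repeats `n_splits` times: randomly assign patients to a 70%/30%
#' train/test split, fit a univariate logistic probability model on the
#' training set, score the held-out test set and record its ROC AUC. Splits
#' whose test set lacks a class are redrawn (up to 100 times each). The 95%
#' confidence interval is the empirical 2.5/97.5 percentile of the AUC
#' distribution.
#'
#' @param scores per-patient scalars.
#' @param labels logical CsPCa labels; at least 4 patients per class.
#' @param n_splits number of random splits (default 1000).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with `auc_point` (all-data AUC), `auc_distribution`,
#'   `auc_mean`, `auc_median`, `ci_low`, `ci_high`, `n_splits`, `seed`,
#'   `n_redraws`.
#' @export
logistic_auc_ci <- function(scores, labels, n_splits = 1000L,
                            train_frac = 0.7, seed = 1L) {
  labels <- as.logical(labels)
  n <- length(scores)
  stopifnot(n == length(labels))
  if (sum(labels) < 4L || sum(!labels) < 4L)
    stop("need at least 4 patients per class")
  n_train <- round(train_frac * n)
  aucs <- numeric(n_splits)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_splits)) {
      for (try in seq_len(100L)) {
        train <- sample.int(n, n_train)
        test <- setdiff(seq_len(n), train)
        if (length(unique(labels[test])) == 2L) break
        redraws <- redraws + 1L
        if (try == 100L)
          stop("could not draw a two-class test set in 100 attempts")
      }
      aucs[b] <- logistic_split_auc(scores, labels, train, test)
    }
  })
  ci <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE, type = 7)
  list(auc_point = roc_auc(scores, labels)$auc, auc_distribution = aucs,
       auc_mean = mean(aucs), auc_median = stats::median(aucs),
       ci_low = ci[1], ci_high = ci[2], n_splits = n_splits, seed = seed,
       n_redraws = redraws)
}

#' Evaluate a per-patient score table
#'
#' For every (covariance method x signature mode) combination present in
#' `score_table`, fits scores to ISUP (Pearson R, p) and to CsPCa (resampled
#' logistic AUC with 95% CI).
#'
#' @param score_table data.frame with columns `patient_id`, `method`,
#'   `signature_mode`, `score`, `isup` (see [score_cohort()]).
#' @param n_splits,train_frac,seed passed to [logistic_auc_ci()].
#' @return data.frame with one row per method x mode: `r`, `p_value`,
#'   `auc`, `auc_median`, `ci_low`, `ci_high`, `n`. Combinations whose
#'   labels are single-class get `NA` AUC columns and a `flag`.
#' @export
evaluate_scores <- function(score_table, n_splits = 1000L, train_frac = 0.7,
                            seed = 1L) {
  combos <- unique(score_table[, c("method", "signature_mode")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- score_table[score_table$method == combos$method[i] &
                       score_table$signature_mode == combos$signature_mode[i], ]
    labels <- cspca_labels(sub$isup)
    fit <- linear_fit(sub$score, sub$isup)
    row <- data.frame(method = combos$method[i],
                      signature_mode = combos$signature_mode[i],
                      r = fit$r, p_value = fit$p_value, n = fit$n,
                      auc = NA_real_, auc_median = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      flag = "")
    if (length(unique(labels)) == 2L && sum(labels) >= 4L &&
        sum(!labels) >= 4L) {
      ci <- logistic_auc_ci(sub$score, labels, n_splits, train_frac, seed)
      row$auc <- ci$auc_point
      row$auc_median <- ci$auc_median
      row$ci_low <- ci$ci_low
      row$ci_high <- ci$ci_high
    } else {
      row$flag <- "single-class or too few per class"
    }
    row
  })
  do.call(rbind, rows)
}
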