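# Placement values (structural components) for a scored binary set:
# V10[i] = fraction of negatives scored below positive i (ties count 1/2),
# V01[j] = fraction of positives scored above negative j likewise.
.placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    stop("both classes must be present to compute ROC quantities")
  r_all <- rank(c(pos, neg), ties.method = "average")
  V10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(V10 = V10, V01 = V01, m = m, n = n, auc = mean(V10))
}

#' Mann-Whitney AUC with DeLong variance
#'
#' The area under the ROC curve as the Mann-Whitney two-sample statistic
#' (ties counted one half), with its DeLong structural-component variance
#' `var(V10)/m + var(V01)/n` and a normal-approximation confidence
#' interval clipped to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @param conf Confidence level.
#' @return An object of class `auc_estimate`: `auc`, `variance`, `ci`
#'   (length 2), `m` positives, `n` negatives.
#' @export
auc_estimate <- function(scores, labels, conf = 0.95) {
  stopifnot(length(scores) == length(labels))
  pl <- .placements(scores, labels)
  v10 <- if (pl$m > 1) stats::var(pl$V10) else 0
  v01 <- if (pl$n > 1) stats::var(pl$V01) else 0
  variance <- v10 / pl$m + v01 / pl$n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(variance)))
  structure(list(auc = pl$auc, variance = variance, ci = ci,
                 m = pl$m, n = pl$n, conf = conf),
            class = "auc_estimate")
}

#' @exportS3Method base::print
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, 100 * x$conf, x$ci[1], x$ci[2], x$m, x$n))
  invisible(x)
}

.delong_result <- function(delta, variance, mode, aucs) {
  if (variance < 1e-14) {
    warning("degenerate DeLong variance (identical rankings); p set to 1")
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(delta_auc = delta, z = z, p_value = p, mode = mode,
                 auc_a = aucs[1], auc_b = aucs[2], variance = variance),
            class = "delong_comparison")
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two score vectors over the same cases using the covariance of
#' their structural components; two-sided p-value from the normal
#' approximation.
#'
#' @param scores_a,scores_b Scores from the two models on identical cases.
#' @param labels Shared binary labels.
#' @return An object of class `delong_comparison`: `delta_auc`
#'   (A minus B), `z`, `p_value`, `mode = "paired"`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  v10 <- if (pa$m > 1) stats::var(pa$V10 - pb$V10) else 0
  v01 <- if (pa$n > 1) stats::var(pa$V01 - pb$V01) else 0
  .delong_result(pa$auc - pb$auc, v10 / pa$m + v01 / pa$n, "paired",
                 c(pa$auc, pb$auc))
}

#' Unpaired DeLong test for two independent AUCs
#'
#' @param scores_a,labels_a First scored set.
#' @param scores_b,labels_b Second, independent scored set.
#' @return An object of class `delong_comparison` with `mode = "unpaired"`;
#'   the variance of the difference is the sum of the two single-set
#'   DeLong variances.
#' @export
delong_unpaired <- function(scores_a, labels_a, scores_b, labels_b) {
  ea <- auc_estimate(scores_a, labels_a)
  eb <- auc_estimate(scores_b, labels_b)
  .delong_result(ea$auc - eb$auc, ea$variance + eb$variance, "unpaired",
                 c(ea$auc, eb$auc))
}

#' @exportS3Method base::print
print.delong_comparison <- function(x, ...) {
  cat(sprintf("%s DeLong: AUC %.3f vs %.3f, delta %+0.3f, z = %.2f, p = %.4g\n",
              x$mode, x$auc_a, x$auc_b, x$delta_auc, x$z, x$p_value))
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval from beta-distribution quantiles; the lower bound is
#' 0 when there are no successes and the upper bound 1 when all trials
#' succeed.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf Confidence level.
#' @return Named numeric `c(estimate, lower, upper)`.
#' @export
clopper_pearson <- function(successes, n, conf = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("invalid counts for clopper_pearson")
  a <- (1 - conf) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  c(estimate = successes / n, lower = lower, upper = upper)
}

#' Chi-square test for equality of proportions
#'
#' Pearson chi-square on a 2 x m table of successes and failures, without
#' continuity correction (the large-sample convention; set
#' `correct = TRUE` for Yates correction on 2 x 2 tables).
#'
#' @param counts 2 x m matrix: row 1 successes, row 2 failures per group.
#' @param correct Continuity correction flag.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_proportions <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must be a 2 x m table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Screening operating point at a target sensitivity
#'
#' Sets the classification threshold to the largest score cutoff whose
#' sensitivity meets the target -- the `ceiling(target * n_pos)`-th largest
#' positive score, with cases at the threshold classified positive -- and
#' reports all binary metrics with exact Clopper-Pearson intervals.
#'
#' @param scores,labels Scored binary set; at least one positive required.
#' @param target Target sensitivity (default 0.95).
#' @param conf Confidence level for the intervals.
#' @return An object of class `operating_point`: `threshold`, `target`,
#'   and `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`, each a
#'   named `c(estimate, lower, upper)` triple.
#' @export
operating_point_at_sensitivity <- function(scores, labels, target = 0.95,
                                           conf = 0.95) {
  stopifnot(length(scores) == length(labels), target > 0, target <= 1)
  labels <- as.integer(labels)
  m <- sum(labels == 1)
  if (m == 0L) stop("no positive cases; operating point undefined")
  k <- ceiling(target * m)
  threshold <- sort(scores[labels == 1], decreasing = TRUE)[k]
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- m - tp
  fp <- sum(pred == 1 & labels == 0); tn <- sum(labels == 0) - fp
  cp_or_na <- function(x, n) if (n == 0)
    c(estimate = NA_real_, lower = NA_real_, upper = NA_real_) else
    clopper_pearson(x, n, conf)
  structure(list(threshold = threshold, target = target,
                 n = length(labels),
                 sensitivity = clopper_pearson(tp, m, conf),
                 specificity = cp_or_na(tn, tn + fp),
                 accuracy = clopper_pearson(tp + tn, length(labels), conf),
                 ppv = cp_or_na(tp, tp + fp),
                 npv = cp_or_na(tn, tn + fn)),
            class = "operating_point")
}

#' @exportS3Method base::print
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> threshold %.4g targeting sensitivity >= %.2f (n = %d)\n",
              x$threshold, x$target, x$n))
  for (mname in c("sensitivity", "specificity", "accuracy", "ppv", "npv"))
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n", mname, x[[mname]]["estimate"],
                x[[mname]]["lower"], x[[mname]]["upper"]))
  invisible(x)
}

#' Prevalence-only trivial ranker
#'
#' Scores every case with its site's training-data pneumonia prevalence and
#' nothing else: the baseline showing how far hospital system alone can
#' rank disease in a pooled test set.
#'
#' @param sites Character vector, site of each case.
#' @param train_prevalence Named numeric vector of training prevalences per
#'   site; every case's site must appear.
#' @return Numeric score vector, constant within site.
#' @export
trivial_prevalence_ranker <- function(sites, train_prevalence) {
  unknown <- setdiff(unique(sites), names(train_prevalence))
  if (length(unknown))
    stop("no training prevalence for site(s): ", paste(unknown, collapse = ", "))
  unname(train_prevalence[sites])
}

#' Calibration summary: logistic recalibration slope and binned curve
#'
#' Refits the outcome on the logit of the predicted probability
#' (`glm(y ~ qlogis(p), binomial)`): slope 1 and intercept 0 indicate
#' perfect calibration spread; slopes below 1 indicate overconfident
#' predictions. Also returns equal-width bin points for a calibration plot.
#'
#' @param probabilities Predicted probabilities; values outside
#'   `[1e-6, 1 - 1e-6]` are clamped with a warning.
#' @param labels Binary outcomes, both classes present.
#' @param n_bins Number of equal-width bins over `[0, 1]`.
#' @return An object of class `calibration_summary`: `slope`, `intercept`,
#'   `degenerate` (TRUE when all probabilities are identical, slope
#'   undefined), and `bins` (mean predicted, observed rate, n).
#' @export
calibration_summary <- function(probabilities, labels, n_bins = 10L) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; calibration undefined")
  eps <- 1e-6
  if (any(probabilities < eps | probabilities > 1 - eps)) {
    warning("probabilities clamped to [1e-6, 1 - 1e-6]")
    probabilities <- pmin(1 - eps, pmax(eps, probabilities))
  }
  cuts <- cut(probabilities, breaks = seq(0, 1, length.out = n_bins + 1),
              include.lowest = TRUE)
  bins <- data.frame(
    mean_predicted = as.vector(tapply(probabilities, cuts, mean)),
    observed_rate = as.vector(tapply(labels, cuts, mean)),
    n = as.vector(table(cuts)))
  bins <- bins[bins$n > 0 & !is.na(bins$mean_predicted), ]
  degenerate <- stats::var(probabilities) < 1e-16
  if (degenerate) {
    slope <- NA_real_; intercept <- NA_real_
  } else {
    fit <- stats::glm(labels ~ stats::qlogis(probabilities),
                      family = stats::binomial())
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  structure(list(slope = slope, intercept = intercept,
                 degenerate = degenerate, bins = bins),
            class = "calibration_summary")
}

#' Percentage as printed in summary tables
#'
#' @param x,n Numerator and denominator.
#' @param digits Decimal places.
#' @return `round(100 * x / n, digits)`.
#' @export
percent <- function(x, n, digits = 1) round(100 * x / n, digits)
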