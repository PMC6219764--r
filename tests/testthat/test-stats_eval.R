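test_that("Mann-Whitney AUC equals brute-force pair enumeration", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- if (rep %% 3 == 0) sample(0:3, n, replace = TRUE) else rnorm(n)
    est <- auc_estimate(scores, labels)
    expect_equal(est$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC handles separation, ties and cross-checks against pROC", {
  perfect <- auc_estimate(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$variance, 0)
  expect_equal(perfect$ci, c(1, 1))

  set.seed(7)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  est <- auc_estimate(scores, labels)
  skip_if_not_installed("pROC")
  ro <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(est$auc, as.numeric(pROC::auc(ro)), tolerance = 1e-12)
  expect_equal(sqrt(est$variance), sqrt(pROC::var(ro)), tolerance = 1e-10)
  expect_error(auc_estimate(scores, rep(1, 80)), "both classes")
})

test_that("two-valued trivial-ranker AUC matches its closed form", {
  sites <- rep(c("hi", "lo"), times = c(700, 1300))
  prev <- c(hi = 0.342, lo = 0.012)
  labels <- c(rbinom(700, 1, 0), rbinom(1300, 1, 0))
  # plant exact positive counts: 240 at hi, 16 at lo
  labels[1:240] <- 1
  labels[701:716] <- 1
  scores <- trivial_prevalence_ranker(sites, prev)
  expect_true(all(scores[sites == "hi"] == 0.342))
  est <- auc_estimate(scores, labels)
  expect_equal(est$auc, two_value_auc(pos_hi = 240, pos_lo = 16,
                                      neg_hi = 460, neg_lo = 1284),
               tolerance = 1e-12)
  expect_equal(est$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
  expect_error(trivial_prevalence_ranker(c("hi", "zz"), prev), "zz")
  # single site: all scores tie, AUC exactly 1/2
  expect_equal(auc_estimate(trivial_prevalence_ranker(rep("hi", 10), prev),
                            c(1, 1, rep(0, 8)))$auc, 0.5)
})

test_that("paired DeLong matches jackknife variance, pROC, and is antisymmetric", {
  # hand-built n = 8 instances (3 positives, 5 negatives)
  lab <- c(1, 1, 1, 0, 0, 0, 0, 0)
  hand <- list(
    list(a = c(0.9, 0.88, 0.82, 0.69, 0.55, -0.06, -0.31, -0.38),
         b = c(0.21, 0.67, -0.45, 2.86, 1.76, -1.18, -0.71, -0.85)),
    list(a = c(-0.3, -0.85, -0.4, -1.22, 1.69, -0.02, 1.07, -2.6),
         b = c(-0.75, -1.53, -1.62, 0.33, 0.27, 0.3, 1.92, -2.42)),
    list(a = c(0.51, 0.21, -0.19, -0.12, 1.01, -0.2, -2.04, -0.2),
         b = c(1.05, 0.83, 0.43, -1.81, 1.38, 0.77, -0.76, -0.42)))
  for (h in hand) {
    cmp <- delong_paired(h$a, h$b, lab)
    jk <- jackknife_delta_var(h$a, h$b, lab)
    expect_lt(abs(cmp$variance - jk) / jk, 0.10)
    rev <- delong_paired(h$b, h$a, lab)
    expect_equal(rev$z, -cmp$z, tolerance = 1e-12)
    expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  set.seed(12)
  lab <- rbinom(60, 1, 0.5); a <- rnorm(60); b <- a + rnorm(60)
  ours <- delong_paired(a, b, lab)
  ref <- pROC::roc.test(pROC::roc(lab, a, quiet = TRUE, direction = "<"),
                        pROC::roc(lab, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("identical rankings give the degenerate p = 1 convention", {
  labels <- c(1, 0, 1, 0)
  s <- c(0.9, 0.1, 0.8, 0.2)
  expect_warning(cmp <- delong_paired(s, s, labels), "degenerate")
  expect_equal(cmp$delta_auc, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("paired DeLong p is invariant to monotone transforms", {
  set.seed(13)
  lab <- rbinom(40, 1, 0.5); a <- rnorm(40); b <- rnorm(40)
  base <- delong_paired(a, b, lab)
  tr <- delong_paired(qlogis(plogis(a * 2 + 1)) , b, lab)   # strictly monotone in a
  expect_equal(delong_paired(exp(a), exp(b), lab)$p_value, base$p_value,
               tolerance = 1e-12)
})

test_that("unpaired DeLong: variance additivity, power, null uniformity", {
  set.seed(21)
  la <- rbinom(100, 1, 0.5); sa <- rnorm(100)
  lb <- rbinom(120, 1, 0.5); sb <- rnorm(120)
  cmp <- delong_unpaired(sa, la, sb, lb)
  expect_equal(cmp$variance,
               auc_estimate(sa, la)$variance + auc_estimate(sb, lb)$variance,
               tolerance = 1e-12)

  # perfect vs chance at n = 200 per set
  lp <- rep(c(1, 0), 100)
  strong <- delong_unpaired(lp + 0.01 * rnorm(200), lp,
                            rnorm(200), rbinom(200, 1, 0.5))
  expect_lt(strong$p_value, 0.001)

  # null p-values approximately uniform over 200 simulations
  set.seed(22)
  pvals <- replicate(200, {
    l1 <- c(rep(1, 25), rep(0, 35)); l2 <- c(rep(1, 30), rep(0, 30))
    delong_unpaired(rnorm(60), l1, rnorm(60), l2)$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Clopper-Pearson is exact (matches binom.test) and hits boundaries", {
  expect_equal(unname(clopper_pearson(0, 10)["lower"]), 0)
  expect_equal(unname(clopper_pearson(10, 10)["upper"]), 1)
  for (xn in list(c(3, 10), c(50, 60), c(1, 2), c(449, 449))) {
    ours <- clopper_pearson(xn[1], xn[2])
    ref <- stats::binom.test(xn[1], xn[2])$conf.int
    expect_equal(unname(ours[c("lower", "upper")]), as.numeric(ref),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(5, 4), "invalid")
  expect_error(clopper_pearson(-1, 4), "invalid")
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(31)
  for (p in c(0.01, 0.5, 0.999)) {
    x <- rbinom(2000, 100, p)
    cover <- vapply(x, function(xi) {
      ci <- clopper_pearson(xi, 100)
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, TRUE)
    expect_gte(mean(cover), 0.95 - 0.012)
  }
})

test_that("chi-square on proportions matches the 2x2 closed form", {
  tab <- matrix(c(12, 30, 40, 18), 2)
  out <- chi_square_proportions(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  hand <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(out$statistic, hand, tolerance = 1e-12)
  eq <- chi_square_proportions(matrix(c(10, 90, 10, 90), 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(chi_square_proportions(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("operating point guarantees the sensitivity target", {
  set.seed(41)
  labels <- c(rep(1, 39), rep(0, 400))
  scores <- c(rnorm(39, 1.2), rnorm(400))
  op <- operating_point_at_sensitivity(scores, labels, 0.95)
  expect_equal(unname(op$sensitivity["estimate"]), 38 / 39, tolerance = 1e-12)
  expect_gte(op$sensitivity["estimate"], 0.95)
  # target 1: every positive admitted
  op1 <- operating_point_at_sensitivity(scores, labels, 1)
  expect_equal(unname(op1$sensitivity["estimate"]), 1)
  expect_lte(op1$threshold, min(scores[labels == 1]))
  # increasing the target weakly lowers the threshold
  ts <- vapply(c(0.5, 0.7, 0.9, 0.95, 1),
               function(t) operating_point_at_sensitivity(scores, labels, t)$threshold,
               0)
  expect_true(all(diff(ts) <= 1e-12))
  expect_error(operating_point_at_sensitivity(scores, rep(0, 439)), "no positive")
})

test_that("calibration summary recovers slope structure", {
  set.seed(51)
  n <- 4000
  lp <- rnorm(n, sd = 1.5)
  y <- rbinom(n, 1, plogis(lp))
  cal <- calibration_summary(plogis(lp), y)
  expect_false(cal$degenerate)
  expect_lt(abs(cal$slope - 1), 0.1)
  # doubling the logits halves the recalibration slope
  over <- calibration_summary(plogis(2 * lp), y)
  expect_lt(abs(over$slope - 0.5), 0.1)
  # constant probabilities are flagged degenerate
  deg <- calibration_summary(rep(0.3, 50), rbinom(50, 1, 0.3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$slope))
  expect_warning(calibration_summary(c(0, 0.4, 1), c(0, 1, 1)), "clamped")
  expect_error(calibration_summary(rep(0.5, 5), rep(1, 5)), "single class")
})
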