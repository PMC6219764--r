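test_that("n-gram featurization counts unigrams and bigrams", {
  v <- featurize("No pneumonia")
  expect_equal(sort(colnames(v)), sort(c("no", "pneumonia", "no pneumonia")))
  expect_true(all(as.matrix(v) == 1))

  empty <- featurize("", vocabulary = c("no", "pneumonia"))
  expect_equal(sum(empty), 0)

  rep2 <- featurize("pneumonia pneumonia")
  m <- as.matrix(rep2)
  expect_equal(unname(m[1, "pneumonia"]), 2)
  expect_equal(unname(m[1, "pneumonia pneumonia"]), 1)

  # out-of-vocabulary n-grams are dropped at predict time
  proj <- featurize("new words pneumonia", vocabulary = c("pneumonia"))
  expect_equal(as.numeric(proj), 1)
})

test_that("the Lasso labeler recovers a perfectly separating token", {
  set.seed(2)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  texts <- ifelse(y == 1,
                  paste("chest film shows consolidation at the base",
                        sample(c("today", "again"), n, TRUE)),
                  paste("clear lungs with no acute findings",
                        sample(c("today", "again"), n, TRUE)))
  idx <- sample(n, 70)
  model <- fit_label_model(texts[idx], y[idx], seed = 1)
  expect_gt(model$n_nonzero, 0)
  pred <- predict(model, texts[-idx], type = "class")
  expect_equal(mean(pred == y[-idx]), 1)
})

test_that("permuted labels give chance-level held-out AUC", {
  set.seed(3)
  n <- 200
  texts <- paste("report", sample(c("alpha", "beta", "gamma", "delta"), n, TRUE),
                 sample(c("one", "two", "three"), n, TRUE))
  y <- rbinom(n, 1, 0.5)
  idx <- 1:140
  model <- fit_label_model(texts[idx], y[idx], seed = 2)
  ev <- evaluate_label_model(model, texts[-idx], y[-idx])
  expect_lt(abs(ev$auc$auc - 0.5), 0.15)
})

test_that("identical documents yield a zero-slope model and single-class errors", {
  texts <- rep("routine chest radiograph no findings", 40)
  y <- rep(c(0, 1), 20)
  model <- fit_label_model(texts, y, seed = 1)
  expect_equal(model$n_nonzero, 0)
  p <- predict(model, texts)
  expect_equal(var(p), 0)
  expect_error(fit_label_model(texts, rep(1, 40)), "single class")
})

test_that("stronger L1 penalties never add nonzero coefficients", {
  # single-word documents make the design columns orthogonal, so the Lasso
  # reduces to per-feature soft thresholding and sparsity is monotone in
  # the penalty
  set.seed(1)
  words <- rep(c("alpha", "beta", "gamma", "delta"), each = 30)
  p_word <- c(alpha = 0.95, beta = 0.8, gamma = 0.35, delta = 0.1)
  y <- rbinom(120, 1, p_word[words])
  X <- featurize(words)
  grid <- c(0.4, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = grid)
  nz <- fit$df[order(fit$lambda, decreasing = TRUE)]
  expect_true(all(diff(nz) >= 0))
})

test_that("hernia keyword rule matches whole tokens case-insensitively", {
  expect_equal(apply_hernia_rule("small hiatal hernia noted"), 1L)
  expect_equal(apply_hernia_rule("Hernia is redemonstrated"), 1L)
  expect_equal(apply_hernia_rule(""), 0L)
  expect_equal(apply_hernia_rule("no herniation of disc material"), 0L)
  expect_equal(apply_hernia_rule(c("a hernia.", "clear")), c(1L, 0L))
})

test_that("label models survive a JSON round trip", {
  set.seed(5)
  y <- rep(c(1, 0), 30)
  texts <- ifelse(y == 1, "dense consolidation present", "no acute process")
  model <- fit_label_model(texts, y, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_label_model(model, path)
  back <- read_label_model(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(predict(back, texts), predict(model, texts), tolerance = 1e-12)
})

test_that("reports assert positives, negate absent findings, and stay recoverable", {
  set.seed(6)
  labs <- setNames(rep(0, length(FINDINGS)), FINDINGS)
  none <- generate_report(labs)
  # negation cue precedes any finding mention in an all-negative report
  expect_false(grepl("there is|is seen|consistent with|interval development",
                     none))
  labs["hernia"] <- 1
  for (i in 1:20) expect_match(generate_report(labs), "hernia")
  labs2 <- setNames(rep(0, length(FINDINGS)), FINDINGS)
  labs2["pneumonia"] <- 1
  rep_pos <- generate_report(labs2)
  expect_match(rep_pos, "pneumonia")
})

test_that("end to end: labels inferred from synthetic reports match truth", {
  set <- generate_study_set(tiny_config(n_patients = 130, seed = 8),
                            list(site_profile("r", prevalence = 0.5,
                                              token = NULL)))
  reports <- generate_reports(set, seed = 8)
  y <- set$meta$pneumonia
  n <- nrow(reports)
  expect_gte(n, 380)
  idx_train <- 1:283
  idx_test <- 284:min(n, 405)
  model <- fit_label_model(reports$text[idx_train], y[idx_train], seed = 3)
  ev <- evaluate_label_model(model, reports$text[idx_test], y[idx_test])
  expect_gt(ev$auc$auc, 0.9)
  # hernia rule agrees with generator truth on hernia-positive studies
  hr <- apply_hernia_rule(reports$text)
  expect_true(all(hr[set$meta$hernia == 1] == 1))
})
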