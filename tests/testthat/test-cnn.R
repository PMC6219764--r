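test_that("plateau scheduler decays and stops as specified", {
  # reference sequence: improvements at epochs 1-2, then three stagnant
  # epochs trigger decays after epochs 3, 4, 5 and stop training
  out <- plateau_schedule(c(1.0, 0.9, 0.95, 0.94, 0.93), initial_lr = 0.01)
  expect_equal(nrow(out), 5)
  expect_equal(out$improved, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$lr_next, c(0.01, 0.01, 0.001, 1e-4, 1e-5))
  expect_true(attr(out, "stopped"))
  expect_equal(attr(out, "best_epoch"), 2)
})

test_that("scheduler agrees with an independent step-through on random sequences", {
  reference <- function(losses, lr0, factor, patience) {
    lr <- lr0; best <- Inf; bad <- 0; lrs <- numeric(0)
    for (l in losses) {
      lrs <- c(lrs, lr)
      if (l < best) { best <- l; bad <- 0 } else { bad <- bad + 1; lr <- lr / factor }
      if (bad >= patience) break
    }
    lrs
  }
  set.seed(17)
  for (i in 1:50) {
    losses <- round(runif(12, 0.2, 1), 2)
    out <- plateau_schedule(losses, initial_lr = 0.1, factor = 5,
                            patience_stop = 3)
    expect_equal(out$lr, reference(losses, 0.1, 5, 3))
  }
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  for (task in c("multiclass", "multilabel")) {
    spec <- classifier_spec(task, 3, input_size = 16, channels = c(2, 3),
                            class_names = if (task == "multiclass")
                              c("a", "b", "c") else NULL)
    layers <- radshift:::.build_network(spec)
    X <- matrix(runif(16 * 16 * 4), 16 * 16, 4)
    Y <- if (task == "multiclass")
      radshift:::.targets_to_matrix(sample(c("a", "b", "c"), 4, TRUE), spec)
    else matrix(rbinom(12, 1, 0.5), 3, 4)
    fw <- radshift:::.net_forward(layers, X, keep_acts = TRUE)
    lg <- radshift:::.loss_grad(task, fw$out, Y)
    gr <- radshift:::.net_backward(layers, fw$acts, lg$dZ)
    loss_at <- function(L)
      radshift:::.loss_grad(task, radshift:::.net_forward(L, X)$out, Y)$loss
    eps <- 1e-6
    for (li in seq_along(layers)) {
      if (is.null(gr[[li]])) next
      for (rep in 1:4) {
        i <- sample(length(layers[[li]]$W), 1)
        l2 <- layers
        l2[[li]]$W[i] <- l2[[li]]$W[i] + eps
        num <- (loss_at(l2) - loss_at(layers)) / eps
        expect_lt(abs(num - gr[[li]]$dW[i]) / (abs(num) + 1e-4), 1e-3)
      }
    }
  }
})

test_that("training runs the schedule, is seeded, and flags bad input", {
  set <- generate_study_set(tiny_config(n_patients = 40, seed = 21,
                                        lateral_fraction = 0),
                            default_site_profiles()[1:2])
  split <- split_by_patient(set, seed = 2)
  sp <- unname(split[set$meta$patient_id])
  tr <- which(sp == "train"); tu <- which(sp == "tune")
  spec <- classifier_spec("multiclass", 2, input_size = 32,
                          channels = c(2, 4))
  sched <- train_schedule(seed = 3, max_epochs = 6)
  m1 <- train_classifier(set$images[, , tr], set$meta$site[tr],
                         set$images[, , tu], set$meta$site[tu], spec, sched)
  m2 <- train_classifier(set$images[, , tr], set$meta$site[tr],
                         set$images[, , tu], set$meta$site[tu], spec, sched)
  expect_identical(m1$log, m2$log)
  # the trainer's realized lr sequence obeys the reference scheduler
  ref <- plateau_schedule(m1$log$tune_loss, initial_lr = sched$initial_lr,
                          factor = sched$lr_decay_factor,
                          patience_stop = sched$patience_stop)
  expect_equal(m1$log$lr_next, ref$lr_next)
  expect_equal(m1$log$improved, ref$improved)
  # retained parameters reproduce the best logged tune loss
  Xtu <- radshift:::.images_to_matrix(set$images[, , tu], 32)
  Ytu <- radshift:::.targets_to_matrix(set$meta$site[tu], m1$spec)
  expect_equal(radshift:::.eval_loss("multiclass", m1$layers, Xtu, Ytu),
               min(m1$log$tune_loss), tolerance = 1e-10)

  expect_error(train_classifier(set$images[, , integer(0)],
                                character(0),
                                set$images[, , tu], set$meta$site[tu],
                                spec, sched), "empty train")
  expect_error(predict_proba(m1, array(0, c(16, 16, 2))), "16 x 16")
})

test_that("probabilities are bounded, normalized, and batch-consistent", {
  set <- generate_study_set(tiny_config(n_patients = 20, seed = 22,
                                        lateral_fraction = 0),
                            default_site_profiles()[1:2])
  ia <- which(set$meta$site == "site_a"); ib <- which(set$meta$site == "site_b")
  tr <- c(ia[1:20], ib[1:20]); tu <- c(ia[21:26], ib[21:26])
  spec <- classifier_spec("multiclass", 2, input_size = 32,
                          channels = c(2, 4))
  m <- train_classifier(set$images[, , tr], set$meta$site[tr],
                        set$images[, , tu], set$meta$site[tu],
                        spec, train_schedule(seed = 4, max_epochs = 2))
  p <- predict_proba(m, set$images[, , 1:20])
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  # batch vs single-image evaluation agree
  single <- predict_proba(m, set$images[, , 7])
  expect_equal(as.numeric(single), as.numeric(p[7, ]), tolerance = 1e-6)
  # identical images give identical outputs
  twice <- array(set$images[, , c(3, 3)], c(32, 32, 2))
  pt <- predict_proba(m, twice)
  expect_equal(pt[1, ], pt[2, ])
})

test_that("multilabel heads stay sigmoid-bounded without row normalization", {
  set <- generate_study_set(tiny_config(n_patients = 20, seed = 23,
                                        lateral_fraction = 0),
                            default_site_profiles()[1])
  y <- as.matrix(set$meta[, FINDINGS])
  spec <- classifier_spec("multilabel", 9, input_size = 32,
                          channels = c(2, 4), class_names = FINDINGS)
  m <- train_classifier(set$images[, , 1:40], y[1:40, ],
                        set$images[, , 41:50], y[41:50, ], spec,
                        train_schedule(seed = 5, max_epochs = 2))
  p <- predict_proba(m, set$images[, , 1:10])
  expect_equal(dim(p), c(10, 9))
  expect_true(all(p > 0 & p < 1))
  expect_equal(colnames(p), FINDINGS)
})

test_that("final features satisfy the pooling identity and grid contract", {
  set <- generate_study_set(tiny_config(n_patients = 15, seed = 24,
                                        lateral_fraction = 0),
                            default_site_profiles()[1:2])
  ia <- which(set$meta$site == "site_a"); ib <- which(set$meta$site == "site_b")
  spec <- classifier_spec("multiclass", 2, input_size = 32,
                          channels = c(3, 5))
  m <- train_classifier(set$images[, , c(ia[1:15], ib[1:15])],
                        set$meta$site[c(ia[1:15], ib[1:15])],
                        set$images[, , c(ia[16:20], ib[16:20])],
                        set$meta$site[c(ia[16:20], ib[16:20])],
                        spec, train_schedule(seed = 6, max_epochs = 3))
  img <- set$images[, , 5]
  ft <- extract_final_features(m, img)
  expect_equal(dim(ft$X), c(5, 8, 8))
  expect_equal(dim(ft$B), c(2, 5))
  # grid-average of the subregion scores equals the model logits
  Y <- subregion_scores(ft)
  gap <- apply(ft$X, 1, mean)
  logits <- as.vector(ft$B %*% gap + ft$B0)
  expect_equal(as.vector(apply(Y, 1, mean)), logits, tolerance = 1e-5)
  # ... and those logits reproduce predict_proba through the softmax
  expect_equal(as.numeric(exp(logits) / sum(exp(logits))),
               as.numeric(predict_proba(m, img)), tolerance = 1e-6)

  # a constant mid-gray image is zero after centering, and the untrained
  # stack has zero biases, so every final activation is exactly zero
  fresh <- radshift:::.build_network(spec)
  X0 <- radshift:::.images_to_matrix(matrix(0.5, 32, 32), 32)
  for (i in 1:6) X0 <- radshift:::.layer_forward(fresh[[i]], X0)
  expect_true(all(X0 == 0))
})

test_that("classifier checkpoints round-trip through JSON", {
  set <- generate_study_set(tiny_config(n_patients = 12, seed = 27,
                                        lateral_fraction = 0),
                            default_site_profiles()[1:2])
  ia <- which(set$meta$site == "site_a"); ib <- which(set$meta$site == "site_b")
  spec <- classifier_spec("multiclass", 2, input_size = 32,
                          channels = c(2, 4))
  m <- train_classifier(set$images[, , c(ia[1:8], ib[1:8])],
                        set$meta$site[c(ia[1:8], ib[1:8])],
                        set$images[, , c(ia[9:11], ib[9:11])],
                        set$meta$site[c(ia[9:11], ib[9:11])],
                        spec, train_schedule(seed = 8, max_epochs = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, path)
  back <- read_classifier(path)
  imgs <- set$images[, , 1:6]
  expect_equal(predict_proba(back, imgs), predict_proba(m, imgs),
               tolerance = 1e-12)
  expect_equal(back$spec$class_names, m$spec$class_names)
})

test_that("view filtering removes laterals and reports its accuracy", {
  set <- generate_study_set(tiny_config(n_patients = 150, seed = 25,
                                        lateral_fraction = 0.5),
                            default_site_profiles()[2])
  vf <- view_filter(set, seed = 3)
  expect_true(all(vf$set$meta$view[!is.na(vf$set$meta$view)] %in%
                    c("frontal", "lateral")))
  # held-out view accuracy on the labeled subset is near-perfect
  expect_gte(vf$accuracy[["estimate"]], 0.98)
  # the filtered output keeps (nearly) only frontal studies
  expect_gt(mean(vf$set$meta$view == "frontal"), 0.95)
  # no laterals at all: nothing to do
  set0 <- generate_study_set(tiny_config(n_patients = 10, seed = 26,
                                         lateral_fraction = 0),
                             default_site_profiles()[2])
  vf0 <- view_filter(set0, seed = 3)
  expect_identical(vf0$set$meta, set0$meta)
  expect_true(is.na(vf0$accuracy[1]))
})
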