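test_that("subregion scores compute the exact linear form", {
  # zero weights: the map is the intercept everywhere
  ft <- list(X = array(rnorm(2 * 3 * 3), c(2, 3, 3)),
             B = matrix(0, 2, 2), B0 = c(1.5, -2))
  Y <- subregion_scores(ft)
  expect_true(all(Y[1, , ] == 1.5))
  expect_true(all(Y[2, , ] == -2))

  # hand instance: K = 2, g = 2, B = (1, -1), B0 = 0
  X <- array(0, c(2, 2, 2))
  X[1, , ] <- matrix(c(1, 0, 0, 1), 2)
  X[2, , ] <- matrix(c(0, 1, 1, 0), 2)
  hand <- list(X = X, B = matrix(c(1, -1), 1), B0 = 0)
  Yh <- subregion_scores(hand)
  expect_equal(Yh[1, , ], matrix(c(1, -1, -1, 1), 2))

  bad <- list(X = X, B = matrix(1, 1, 3), B0 = 0)
  expect_error(subregion_scores(bad), "channel mismatch")
})

test_that("cellwise softmax normalizes, is shift-invariant, needs 2+ classes", {
  Y <- array(0, c(3, 4, 4))
  P <- subregion_probability(Y, 1)
  expect_true(all(abs(P - 1 / 3) < 1e-12))

  Y2 <- array(0, c(3, 2, 2))
  Y2[1, , ] <- 10
  P2 <- subregion_probability(Y2, 1)
  expect_equal(P2[1, 1], exp(10) / (exp(10) + 2), tolerance = 1e-9)
  # full softmax sums to one at every cell
  tot <- subregion_probability(Y2, 1) + subregion_probability(Y2, 2) +
    subregion_probability(Y2, 3)
  expect_equal(as.vector(tot), rep(1, 4), tolerance = 1e-9)
  # adding a constant to every class at a cell changes nothing
  Y3 <- Y2
  Y3[, 1, 1] <- Y3[, 1, 1] + 100
  expect_equal(subregion_probability(Y3, 1), P2, tolerance = 1e-9)

  expect_error(subregion_probability(array(0, c(1, 2, 2)), 1), "two classes")
})

test_that("decisive counting is inclusive at the threshold", {
  expect_equal(count_decisive(matrix(1, 7, 7), 0.95), 49)
  expect_equal(count_decisive(matrix(0.949999, 7, 7), 0.95), 0)
  expect_equal(count_decisive(matrix(0.95, 7, 7), 0.95), 49)
  P <- matrix(c(0.96, 0.2, 0.95, 0.1), 2)
  expect_equal(count_decisive(P, 0.95), 2)
  expect_error(count_decisive(P, 1.2))
})

test_that("influence heatmaps are mean-centered target-minus-rest evidence", {
  # identical class maps cancel exactly
  Y <- array(rep(matrix(rnorm(4), 2), each = 1), c(2, 2, 2))
  Y[2, , ] <- Y[1, , ]
  expect_true(all(abs(influence_heatmap(Y, 1)) < 1e-12))

  # hand instance with two classes
  Y2 <- array(0, c(2, 2, 2))
  Y2[1, , ] <- matrix(c(1, -1, -1, 1), 2)
  Y2[2, , ] <- matrix(c(0, 1, 1, 0), 2)
  D <- influence_heatmap(Y2, 1)
  raw <- matrix(c(1, -2, -2, 1), 2)
  expect_equal(D, raw - mean(raw), tolerance = 1e-12)
  expect_equal(sum(D), 0, tolerance = 1e-9)

  # three classes: target minus the sum of the others
  Y3 <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  D3 <- influence_heatmap(Y3, 2)
  raw3 <- Y3[2, , ] - Y3[1, , ] - Y3[3, , ]
  expect_equal(D3, raw3 - mean(raw3), tolerance = 1e-12)
})

test_that("decisive summaries aggregate counts and fractions correctly", {
  set <- generate_study_set(tiny_config(n_patients = 10, seed = 31,
                                        lateral_fraction = 0),
                            default_site_profiles()[1:2])
  ia <- which(set$meta$site == "site_a"); ib <- which(set$meta$site == "site_b")
  spec <- classifier_spec("multiclass", 2, input_size = 32,
                          channels = c(2, 4))
  m <- train_classifier(set$images[, , c(ia[1:10], ib[1:10])],
                        set$meta$site[c(ia[1:10], ib[1:10])],
                        set$images[, , c(ia[11:13], ib[11:13])],
                        set$meta$site[c(ia[11:13], ib[11:13])],
                        spec, train_schedule(seed = 7, max_epochs = 2))
  one <- summarize_decisive(m, set$images[, , 1], "site_a")
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  expect_equal(one$cells, 64)

  multi <- summarize_decisive(m, set$images[, , 1:6], "site_a")
  shuffled <- summarize_decisive(m, set$images[, , c(4, 2, 6, 1, 3, 5)],
                                 "site_a")
  expect_equal(sort(multi$counts), sort(shuffled$counts))
  expect_equal(multi$mean, shuffled$mean)
  expect_equal(multi$fraction, multi$mean / 64)
  # printed-fraction arithmetic: a mean of 35.7 decisive cells of 49 is 72.9%
  expect_equal(percent(35.7, 49), 72.9)
})

test_that("token grid cells map corners onto the feature grid", {
  p <- site_profile("t", token = token_spec("br", side = 6, margin = 2))
  expect_equal(token_grid_cell(p, 32, 8), c(7, 7))
  # the 6 px block spans pixels 25:30, i.e. grid rows/cols 7 and 8
  cov <- token_grid_cells(p, 32, 8)
  expect_setequal(paste(cov[, "row"], cov[, "col"]),
                  c("7 7", "7 8", "8 7", "8 8"))
  p2 <- site_profile("t", token = token_spec("tl", side = 6, margin = 2))
  expect_equal(token_grid_cell(p2, 32, 8), c(2, 2))
  p3 <- site_profile("t", token = NULL)
  expect_error(token_grid_cell(p3, 32, 8), "no token")
})
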