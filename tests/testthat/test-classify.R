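test_that("balanced class weights follow N / (k * n_c)", {
  w <- make_class_weights(rep(c("resp", "hold", "swal"), c(5272, 950, 611)))
  expect_equal(unname(w[c("resp", "hold", "swal")]),
               c(0.43, 2.40, 3.73), tolerance = 0.01)
  expect_equal(unname(make_class_weights(rep(c("a", "b"), c(10, 10)))),
               c(1, 1))
  expect_equal(unname(make_class_weights(rep("a", 5))), 1)
  expect_error(make_class_weights(factor(c("a", "a"), levels = c("a", "b"))),
               "at least one")
})

test_that("evaluate builds the confusion matrix and per-class metrics", {
  r <- evaluate(c("a", "a", "b", "b", "b"), c("a", "b", "b", "b", "a"))
  expect_equal(unname(r$confusion["a", ]), c(1, 1))
  expect_equal(unname(r$confusion["b", ]), c(1, 2))
  expect_equal(unname(r$precision["a"]), 0.5)
  expect_equal(unname(r$recall["b"]), 2 / 3)
  # perfect predictions
  expect_equal(evaluate(c("x", "y", "z"), c("x", "y", "z"))$macro_f1, 1)
  # a class never predicted gets precision 0, not NaN
  r2 <- evaluate(factor(c("a", "b"), levels = c("a", "b")),
                 factor(c("a", "a"), levels = c("a", "b")))
  expect_equal(unname(r2$precision["b"]), 0)
  expect_equal(unname(r2$f1["b"]), 0)
  expect_error(evaluate(c("a", "b"), c("a")), "equal length")
})

test_that("macro-F1 is the unweighted mean of per-class F1 and permutation-invariant", {
  conf <- matrix(c(50, 5, 3, 8, 30, 2, 1, 4, 20), 3, 3, byrow = TRUE)
  # independent oracle: explicit per-class arithmetic
  oracle <- mean(sapply(1:3, function(k) {
    p <- conf[k, k] / sum(conf[, k]); r <- conf[k, k] / sum(conf[k, ])
    2 * p * r / (p + r)
  }))
  expect_equal(macro_f1(conf), oracle)
  expect_equal(macro_f1(diag(c(7, 1, 12))), 1)
  perm <- c(3, 1, 2)
  expect_equal(macro_f1(conf[perm, perm]), macro_f1(conf))
  expect_error(macro_f1(matrix(0, 2, 2)), "zero")
  expect_error(macro_f1(matrix(1, 2, 3)), "square")
})

test_that("separable blobs reach perfect grouped-CV macro-F1", {
  d <- blob_data()
  for (kind in c("margin-linear", "tree-ensemble")) {
    cfg <- train_config(kind,
                        grid = if (kind == "margin-linear")
                          data.frame(C = 1)
                        else data.frame(trees = 100, depth = 0,
                                        mtry_rule = "sqrt"),
                        seed = 1)
    fit <- tune_and_train(d$x, d$y, d$groups, cfg)
    expect_equal(fit$cv_macro_f1, 1)
    # training data predicted perfectly by the refit model
    expect_equal(evaluate(d$y, predict(fit, d$x))$macro_f1, 1)
  }
})

test_that("the rbf kernel and grid search select a working model", {
  d <- blob_data(n_per_class = 20)
  cfg <- train_config("margin-rbf",
                      grid = expand.grid(C = c(1, 10), gamma_mult = c(0.1, 1)),
                      seed = 1)
  fit <- tune_and_train(d$x, d$y, d$groups, cfg)
  expect_gt(fit$cv_macro_f1, 0.95)
  expect_equal(nrow(fit$cv_scores), 4)
})

test_that("balanced weighting raises minority recall on an overlapping 9:1 set", {
  set.seed(33)
  n_maj <- 450; n_min <- 50
  x <- data.frame(
    f1 = c(rnorm(n_maj, 0), rnorm(n_min, 1.6)),
    f2 = c(rnorm(n_maj, 0), rnorm(n_min, 1.6)))
  y <- factor(rep(c("maj", "min"), c(n_maj, n_min)))
  g <- sample(rep_len(paste0("g", 1:4), n_maj + n_min))
  fit_b <- tune_and_train(x, y, g, train_config("margin-linear",
                                                grid = data.frame(C = 1),
                                                class_weight = "balanced"))
  fit_u <- tune_and_train(x, y, g, train_config("margin-linear",
                                                grid = data.frame(C = 1),
                                                class_weight = "none"))
  expect_gt(fit_b$cv_report$recall[["min"]], fit_u$cv_report$recall[["min"]])
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- blob_data(n_per_class = 10)
  expect_error(tune_and_train(d$x, rep("a", nrow(d$x)), d$groups),
               "two classes")
  expect_error(tune_and_train(d$x, d$y, rep("g1", nrow(d$x))),
               "two groups")
  # a class confined to a single group is absent from that group's
  # training fold only -- but absent from EVERY training fold is an error
  x2 <- data.frame(f1 = rnorm(8), f2 = rnorm(8))
  y2 <- factor(rep(c("a", "b"), each = 4))
  g2 <- rep(c("g1", "g2"), each = 4) # each class lives in one group only
  expect_error(
    tune_and_train(x2, y2, g2, train_config("margin-linear",
                                            grid = data.frame(C = 1))),
    "absent")
})

test_that("the window-size sweep returns one deterministic row per size", {
  rec <- simulate_cohort(3, 2, seed = 44, measure = "truth")
  cfg <- train_config("tree-ensemble",
                      grid = data.frame(trees = 50, depth = 0,
                                        mtry_rule = "sqrt"),
                      seed = 1)
  sw1 <- window_size_sweep(rec, sizes = 4, config = cfg)
  expect_equal(nrow(sw1), 1)
  expect_equal(sw1$window_s, 4)
  sw2 <- window_size_sweep(rec, sizes = c(3, 4), config = cfg)
  expect_equal(sw2$macro_f1[sw2$window_s == 4], sw1$macro_f1)
  expect_identical(window_size_sweep(rec, sizes = c(3, 4), config = cfg), sw2)
})
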