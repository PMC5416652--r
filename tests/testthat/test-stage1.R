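# Binary labels used throughout: deep_red vs red_or_light_red; the helper
# clouds put the deep_red class on the negative side of the first feature.
.cloud_data <- function(n = 20, gap = 2, seed = 51) {
  withr::with_seed(seed, {
    X <- rbind(
      cbind(stats::rnorm(n, 3 + gap / 2, 0.3), stats::rnorm(n, 0, 0.5)),
      cbind(stats::rnorm(n, -3 - gap / 2, 0.3), stats::rnorm(n, 0, 0.5))
    )
  })
  list(X = X, y = rep(c(STAGE1_RED_OR_LIGHT, STAGE1_DEEP_RED), each = n))
}

test_that("linearly separable clouds are fitted perfectly with few support vectors", {
  d <- .cloud_data()
  m <- train_stage1(d$X, d$y, kernel = "linear", C = 1)
  expect_identical(predict_stage1(m, d$X), d$y)
  expect_lt(count_support_vectors(m), nrow(d$X) / 2)
  expect_gte(count_support_vectors(m), 2L)
})

test_that("the XOR pattern defeats a linear kernel", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(STAGE1_DEEP_RED, STAGE1_DEEP_RED,
         STAGE1_RED_OR_LIGHT, STAGE1_RED_OR_LIGHT)
  m <- train_stage1(X, y, kernel = "linear", C = 10)
  acc <- classification_accuracy(predict_stage1(m, X), y)
  expect_lte(acc$accuracy_pct, 75)
})

test_that("the fitted linear hyperplane matches a brute-force max-margin search", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 6
    Xp <- cbind(stats::runif(n, 2, 5), stats::runif(n, -2, 2))
    Xn <- cbind(stats::runif(n, -5, -2), stats::runif(n, -2, 2))
    X <- rbind(Xp, Xn)
    y <- rep(c(1, -1), each = n)
    labels <- ifelse(y == 1, STAGE1_RED_OR_LIGHT, STAGE1_DEEP_RED)
    # large C approximates the hard-margin problem the oracle solves; the
    # model fits standardised features, so the oracle searches that space
    m <- train_stage1(X, labels, kernel = "linear", C = 1e6,
                      tolerance = 1e-8)
    Xs <- scale(X, center = m$center, scale = m$scale)
    oracle <- oracle_max_margin(Xs, y)
    hp <- tonguecolor:::linear_hyperplane(m)
    expect_lt(max(abs(unname(hp$w) - unname(oracle$w))), 1e-4)
    expect_lt(abs(unname(hp$b) - unname(oracle$b)), 1e-4)
  }
})

test_that("training points far from the margin are classified by side", {
  d <- .cloud_data()
  m <- train_stage1(d$X, d$y)
  expect_identical(predict_stage1(m, c(8, 0)), STAGE1_RED_OR_LIGHT)
  expect_identical(predict_stage1(m, c(-8, 0)), STAGE1_DEEP_RED)
})

test_that("a two-point training set has exactly two support vectors", {
  X <- rbind(c(1, 0), c(-1, 0))
  y <- c(STAGE1_RED_OR_LIGHT, STAGE1_DEEP_RED)
  m <- train_stage1(X, y)
  expect_identical(count_support_vectors(m), 2L)
})

test_that("removing a non-support-vector point leaves the decision function unchanged", {
  d <- .cloud_data(n = 15, gap = 3)
  m <- train_stage1(d$X, d$y, kernel = "linear", C = 1, tolerance = 1e-9)
  sv_rows <- m$fit$index
  non_sv <- setdiff(seq_len(nrow(d$X)), sv_rows)[1]
  m2 <- train_stage1(d$X[-non_sv, ], d$y[-non_sv], kernel = "linear", C = 1,
                     tolerance = 1e-9)
  grid <- cbind(stats::runif(50, -6, 6), stats::runif(50, -2, 2))
  f1 <- attr(predict_stage1(m, grid, decision_values = TRUE),
             "decision_values")
  f2 <- attr(predict_stage1(m2, grid, decision_values = TRUE),
             "decision_values")
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("training is deterministic: same data and settings, same model", {
  d <- .cloud_data(n = 25, gap = 1, seed = 77)
  m1 <- train_stage1(d$X, d$y, kernel = "rbf", C = 2, seed = 5)
  m2 <- train_stage1(d$X, d$y, kernel = "rbf", C = 2, seed = 5)
  expect_identical(count_support_vectors(m1), count_support_vectors(m2))
  probe <- cbind(stats::runif(20, -5, 5), stats::runif(20, -2, 2))
  expect_identical(predict_stage1(m1, probe), predict_stage1(m2, probe))
})

test_that("scaler parameters are learned on training data and frozen", {
  d <- .cloud_data()
  m <- train_stage1(d$X, d$y)
  expect_equal(m$center, colMeans(d$X))
  expect_equal(m$scale, apply(d$X, 2, stats::sd))
  # predictions on wildly shifted probes still use the training scaler
  expect_identical(predict_stage1(m, c(1000, 0)), STAGE1_RED_OR_LIGHT)
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(stats::runif(10), ncol = 2)
  expect_error(train_stage1(X, rep(STAGE1_DEEP_RED, 5)), "both stage-1 classes")
  Xn <- X; Xn[1, 1] <- NaN
  expect_error(train_stage1(Xn, rep(c(STAGE1_DEEP_RED, STAGE1_RED_OR_LIGHT),
                                    length.out = 5)), "finite")
  d <- .cloud_data()
  m <- train_stage1(d$X, d$y)
  expect_error(predict_stage1(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("every kernel name maps to a fittable model", {
  d <- .cloud_data(n = 10)
  for (kern in c("linear", "rbf", "polynomial", "quadratic")) {
    m <- train_stage1(d$X, d$y, kernel = kern)
    expect_s3_class(m, "stage1_svm")
    expect_gte(count_support_vectors(m), 2L)
  }
  expect_error(train_stage1(d$X, d$y, kernel = "sigmoidal"), "unknown kernel")
})

test_that("accuracy rate follows the counting formula", {
  # 90 correct red/light-red + 98 correct deep-red of 200 -> 94%
  truth <- rep(c(STAGE1_RED_OR_LIGHT, STAGE1_DEEP_RED), each = 100)
  pred <- truth
  pred[1:10] <- STAGE1_DEEP_RED        # 10 red/light-red wrong
  pred[101:102] <- STAGE1_RED_OR_LIGHT # 2 deep-red wrong
  res <- classification_accuracy(pred, truth)
  expect_equal(res$accuracy_pct, 94.0)
  expect_identical(unname(res$n_correct[STAGE1_DEEP_RED]), 98L)
  expect_identical(res$N, 200L)
  expect_identical(sum(res$confusion), 200L)

  expect_equal(classification_accuracy(truth, truth)$accuracy_pct, 100)

  set.seed(83)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    a <- sample(TONGUE_CLASSES, n, replace = TRUE)
    b <- sample(TONGUE_CLASSES, n, replace = TRUE)
    expect_equal(classification_accuracy(a, b)$accuracy_pct,
                 oracle_accuracy_pct(a, b))
  }
  expect_error(classification_accuracy(c("red"), c("red", "red")),
               "length mismatch")
  expect_error(classification_accuracy(character(0), character(0)),
               "no observations")
})

test_that("evaluation reports serialise accuracy and confusion counts", {
  res <- classification_accuracy(c("red", "red", "deep_red"),
                                 c("red", "light_red", "deep_red"),
                                 support_vector_count = 7L)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(res, path, meta = list(kernel = "linear", C = 1))
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy_pct, res$accuracy_pct)
  expect_equal(back$support_vector_count, 7)
  expect_true(file.exists(sub("\\.json$", "_confusion.csv", path)))
})
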