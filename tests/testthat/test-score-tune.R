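# minimal model constructs used to probe the score
lm_fitter <- function(X, y) {
  structure(list(coef = stats::coef(stats::lm(y ~ X))), class = "toy_lm")
}
predict.toy_lm <- function(object, newdata, ...) {
  as.vector(cbind(1, as.matrix(newdata)) %*% object$coef)
}
registerS3method("predict", "toy_lm", predict.toy_lm)

memorizer <- function(X, y) structure(list(X = X, y = y), class = "toy_memo")
predict.toy_memo <- function(object, newdata, ...) {
  # 1-nearest-neighbour lookup: zero train error, poor interpolation
  apply(as.matrix(newdata), 1, function(r) {
    object$y[which.min(colSums((t(object$X) - r)^2))]
  })
}
registerS3method("predict", "toy_memo", predict.toy_memo)

test_that("dataset splitting reproduces the documented sizes and is deterministic", {
  expect_equal(split_sizes(581), c(train = 406L, test = 88L, validation = 87L))
  expect_equal(split_sizes(10, c(0.8, 0.1, 0.1)),
               c(train = 8L, test = 1L, validation = 1L))
  rec <- tibble::tibble(record_id = sprintf("r%03d", 1:100), v = rnorm(100))
  s1 <- split_dataset(rec, seed = 11)
  s2 <- split_dataset(rec, seed = 11)
  expect_identical(s1, s2)
  ids <- c(s1$train$record_id, s1$test$record_id, s1$validation$record_id)
  expect_setequal(ids, rec$record_id)
  expect_equal(length(ids), length(unique(ids)))
  expect_error(split_dataset(rec[1:2, ]), "at least 3")
})

test_that("a perfect model on noiseless linear data scores near zero", {
  withr::with_seed(2, X <- matrix(runif(200, -1, 1), 100, 2))
  y <- X %*% c(2, -1) + 1
  sc <- custom_score(lm_fitter, X, as.vector(y))
  expect_lt(sc$base_error, 1e-8)
  expect_lt(sc$lca_penalty, 1e-8)
  expect_lt(sc$total, 1e-8)
})

test_that("lambda = 0 switches the learning-curve penalty off", {
  withr::with_seed(3, {
    X <- matrix(rnorm(120), 60, 2)
    y <- X[, 1] + rnorm(60, 0, 0.3)
  })
  sc0 <- custom_score(lm_fitter, X, y, lambda = 0)
  sc1 <- custom_score(lm_fitter, X, y, lambda = 1)
  expect_equal(sc0$total, sc0$base_error)
  expect_equal(sc1$total, sc1$base_error + sc1$lca_penalty)
  expect_gt(sc1$total, sc0$total)
})

test_that("an overfitting memoriser scores worse than an honest linear model", {
  withr::with_seed(4, {
    X <- matrix(rnorm(80), 40, 2)
    y <- X[, 1] + rnorm(40, 0, 0.5)
  })
  sc_memo <- custom_score(memorizer, X, y, seed = 1)
  sc_lm <- custom_score(lm_fitter, X, y, seed = 1)
  # the memoriser has zero training error at full size ...
  lca <- attr(sc_memo, "lca_curve")
  expect_lt(lca$train_mae[which.max(lca$n_train)], 1e-12)
  # ... but a strictly worse penalised score
  expect_gt(sc_memo$total, sc_lm$total)
})

test_that("the learning curve spans 50-100% of the training part with k points", {
  withr::with_seed(5, {
    X <- matrix(rnorm(120), 60, 2)
    y <- X[, 1]
  })
  lc <- learning_curve(lm_fitter, X, y, k = 20)
  expect_equal(nrow(lc), 20L)
  expect_equal(range(lc$size_frac), c(0.5, 1))
  expect_true(all(diff(lc$n_train) >= 0))
})

test_that("TPE finds the minimiser of a quadratic surface within 10%", {
  res <- tpe_minimize(list(x = p_uniform(-5, 5)),
                      function(p) (p$x - 2)^2, n_trials = 200, seed = 3)
  expect_lt(abs(res$best_params$x - 2) / 2, 0.10)
  # reference: a fine grid search oracle over the same interval
  grid <- seq(-5, 5, length.out = 2001)
  oracle <- grid[which.min((grid - 2)^2)]
  expect_lt(abs(res$best_params$x - oracle), 0.2)
})

test_that("the TPE trial sequence is deterministic and a single trial returns its params", {
  r1 <- tpe_minimize(list(x = p_uniform(0, 1)), function(p) p$x,
                     n_trials = 50, seed = 8)
  r2 <- tpe_minimize(list(x = p_uniform(0, 1)), function(p) p$x,
                     n_trials = 50, seed = 8)
  expect_identical(r1$trials, r2$trials)
  one <- tpe_minimize(list(x = p_uniform(0, 1)), function(p) p$x,
                      n_trials = 1, seed = 1)
  expect_equal(one$best_params$x, one$trials$x[1])
  expect_equal(one$best_value, one$trials$x[1])
})

test_that("failing trials are tolerated but an all-failing objective errors", {
  res <- tpe_minimize(list(x = p_uniform(0, 1)),
                      function(p) if (p$x > 0.5) stop("boom") else p$x,
                      n_trials = 30, seed = 2)
  expect_true(any(!is.finite(res$trials$value)))
  expect_lte(res$best_value, 0.5)
  expect_error(
    tpe_minimize(list(x = p_uniform(0, 1)), function(p) stop("dead"),
                 n_trials = 5, seed = 2),
    "all tuning trials failed.*dead")
})

test_that("integer and categorical dimensions are sampled within their domains", {
  res <- tpe_minimize(
    list(k = p_int(1, 5), m = p_categorical(c("a", "b")),
         s = p_loguniform(1e-3, 1e3)),
    function(p) abs(p$k - 3) + (p$m == "a") + abs(log10(p$s)),
    n_trials = 80, seed = 4)
  expect_true(all(res$trials$k %in% 1:5))
  expect_true(all(res$trials$m %in% c("a", "b")))
  expect_true(all(res$trials$s >= 1e-3 & res$trials$s <= 1e3))
  expect_equal(res$best_params$k, 3L)
  expect_equal(res$best_params$m, "b")
})

test_that("tune_models returns ranked per-family candidates with history", {
  withr::with_seed(6, {
    X <- matrix(rnorm(240), 80, 3)
    y <- X %*% c(1, -2, 0.5) + rnorm(80, 0, 0.1)
  })
  tuned <- tune_models(X, as.vector(y), n_trials = 15, seed = 2)
  expect_s3_class(tuned, "tune_result")
  expect_equal(nrow(tuned$trials), 15L)
  scores <- vapply(tuned$candidates, `[[`, 0, "score")
  expect_true(!is.unsorted(scores))
  # ridge should beat the forest on a linear map
  expect_lt(tuned$candidates[[1]]$score, tuned$candidates[["rf"]]$score)
  tuned2 <- tune_models(X, as.vector(y), n_trials = 15, seed = 2)
  expect_identical(tuned$trials, tuned2$trials)
})
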