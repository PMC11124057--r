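mae <- function(obs, pred) mean(abs(obs - pred))
rmsd <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Split records into training, test and validation subsets
#'
#' Seeded shuffle followed by sequential held-out splits: the test count is
#' `ceiling(n * f_test)`, the validation count `ceiling` of the validation
#' share of the remainder, and training takes the rest. With fractions
#' (0.70, 0.15, 0.15) this maps 581 records to sizes (406, 88, 87).
#'
#' @param records A tibble of records (any columns).
#' @param fractions Numeric length-3 `(train, test, validation)` fractions,
#'   positive, summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return A named list of three disjoint, exhaustive tibbles: `train`,
#'   `test`, `validation`.
#' @export
#' @examples
#' split_sizes(581)
split_dataset <- function(records, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records to split", call. = FALSE)
  sizes <- split_sizes(n, fractions)
  idx <- withr::with_seed(seed, sample.int(n))
  test_idx <- idx[seq_len(sizes[["test"]])]
  val_idx <- idx[sizes[["test"]] + seq_len(sizes[["validation"]])]
  train_idx <- idx[-seq_len(sizes[["test"]] + sizes[["validation"]])]
  list(train = records[sort(train_idx), , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE],
       validation = records[sort(val_idx), , drop = FALSE])
}

#' @rdname split_dataset
#' @param n Number of records.
#' @return `split_sizes()`: named integer vector `(train, test, validation)`.
#' @export
split_sizes <- function(n, fractions = c(0.70, 0.15, 0.15)) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  n_test <- as.integer(ceiling(n * fractions[2]))
  n_val <- as.integer(ceiling((n - n_test) * fractions[3] /
                                (fractions[1] + fractions[3])))
  c(train = n - n_test - n_val, test = n_test, validation = n_val)
}

#' Learning curve of a model family
#'
#' Trains on nested subsets of the training part (fractions of the data from
#' 50% to 100%) and records train and validation MAE at each size — the basis
#' of the generalisability penalty in [custom_score()]. Two points are used
#' during tuning; 20 for the final audit of a chosen model.
#'
#' @param fit_fun Function `(features, targets) -> model` where the model has
#'   a `predict(model, features)` method.
#' @param features Numeric feature matrix (or data frame).
#' @param targets Numeric response.
#' @param k Number of learning-curve points spanning 50--100% of the
#'   training part.
#' @param val_frac Fraction held out as the fixed validation set.
#' @param seed Integer seed for the hold-out shuffle.
#' @return A tibble: `size_frac`, `n_train`, `train_mae`, `val_mae`.
#' @export
learning_curve <- function(fit_fun, features, targets, k = 2,
                           val_frac = 0.25, seed = 1) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  n <- nrow(X)
  stopifnot(k >= 1, n >= 8)
  idx <- withr::with_seed(seed, sample.int(n))
  n_val <- max(2L, floor(n * val_frac))
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  fracs <- if (k == 1) 1 else seq(0.5, 1, length.out = k)
  purrr::map_dfr(fracs, function(f) {
    sub <- tr[seq_len(max(2L, floor(length(tr) * f)))]
    m <- fit_fun(X[sub, , drop = FALSE], y[sub])
    tibble::tibble(
      size_frac = f, n_train = length(sub),
      train_mae = mae(y[sub], predict(m, X[sub, , drop = FALSE])),
      val_mae = mae(y[val], predict(m, X[val, , drop = FALSE])))
  })
}

#' Learning-curve-penalised model score
#'
#' The tuning objective: cross-validated MAE plus `lambda` times a
#' learning-curve-analysis (LCA) penalty. The penalty is the mean validation
#' MAE at the largest learning-curve training size plus the train/validation
#' MAE gap there, so models that fit the training data but generalise poorly
#' score strictly worse than equally accurate regularised ones.
#'
#' @inheritParams learning_curve
#' @param k_lca Learning-curve points: 2 during tuning, 20 for the final
#'   audit.
#' @param lambda Penalty weight (`lambda = 0` reduces the score to the
#'   cross-validated MAE).
#' @param n_folds Cross-validation folds for the base error.
#' @return A one-row tibble (`score_breakdown`): `base_error`, `lca_penalty`,
#'   `total`, with the learning curve in attribute `lca_curve`.
#' @export
custom_score <- function(fit_fun, features, targets, k_lca = 2, lambda = 1,
                         n_folds = 3, val_frac = 0.25, seed = 1) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  n <- nrow(X)
  if (n < n_folds * 2L) stop("too few records to score", call. = FALSE)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  cv_mae <- vapply(seq_len(n_folds), function(f) {
    m <- fit_fun(X[folds != f, , drop = FALSE], y[folds != f])
    mae(y[folds == f], predict(m, X[folds == f, , drop = FALSE]))
  }, numeric(1))
  base_error <- mean(cv_mae)

  curve <- learning_curve(fit_fun, X, y, k = k_lca, val_frac = val_frac,
                          seed = seed)
  last <- curve[which.max(curve$n_train), ]
  lca_penalty <- last$val_mae + max(0, last$val_mae - last$train_mae)

  out <- tibble::tibble(base_error = base_error, lca_penalty = lca_penalty,
                        total = base_error + lambda * lca_penalty)
  attr(out, "lca_curve") <- curve
  out
}
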