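fit_ridge <- function(X, y, lambda) {
  structure(list(fit = glmnet::glmnet(X, y, alpha = 0, lambda = lambda),
                 lambda = lambda),
            class = "desolv_ridge")
}

#' @export
predict.desolv_ridge <- function(object, newdata, ...) {
  as.vector(stats::predict(object$fit, newx = as.matrix(newdata),
                           s = object$lambda))
}

fit_rf <- function(X, y, mtry_frac, min_node, num_trees = 100L, seed = 7L) {
  d <- as.data.frame(X)
  names(d) <- paste0("f", seq_len(ncol(d)))
  d$.y <- y
  structure(list(fit = ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = num_trees, mtry = max(1L, floor(mtry_frac * ncol(X))),
    min.node.size = min_node, seed = seed, num.threads = 1L)),
    class = "desolv_rf")
}

#' @export
predict.desolv_rf <- function(object, newdata, ...) {
  d <- as.data.frame(as.matrix(newdata))
  names(d) <- paste0("f", seq_len(ncol(d)))
  stats::predict(object$fit, data = d, num.threads = 1L)$predictions
}

#' Model families available to the tuner
#'
#' A representative subset of the regressor zoo: the multi-layer perceptron
#' (the architecture family the final model belongs to), ridge regression,
#' and a random forest. Each family carries its hyperparameter space and a
#' builder turning a sampled parameter list into a `fit(X, y)` function.
#'
#' @param tune_max_iter L-BFGS iteration cap for MLP fits during tuning
#'   (final refits use the [network_spec()] default).
#' @param fit_seed Seed used for stochastic fitters inside trials, so trials
#'   are comparable and reruns identical.
#' @return Named list of families, each `list(space, build)`.
#' @export
model_library <- function(tune_max_iter = 150L, fit_seed = 7L) {
  list(
    mlp = list(
      space = list(hidden1 = p_int(8, 32), hidden2 = p_int(0, 16),
                   alpha = p_loguniform(1e-5, 1e-1)),
      build = function(params) {
        hidden <- c(params$hidden1,
                    if (params$hidden2 > 0) params$hidden2)
        function(X, y) train_network(
          network_spec(hidden, alpha = params$alpha,
                       max_iter = tune_max_iter),
          X, y, seed = fit_seed)
      }
    ),
    ridge = list(
      space = list(lambda = p_loguniform(1e-4, 10)),
      build = function(params) function(X, y) fit_ridge(X, y, params$lambda)
    ),
    rf = list(
      space = list(mtry_frac = p_uniform(0.3, 1), min_node = p_int(2, 10)),
      build = function(params) function(X, y)
        fit_rf(X, y, params$mtry_frac, params$min_node, seed = fit_seed)
    )
  )
}

#' Tune model families with the TPE sampler and the custom score
#'
#' Runs [tpe_minimize()] over a joint space (family choice plus the chosen
#' family's hyperparameters), scoring each trial with [custom_score()] on the
#' training data, and returns the best candidate per family ranked by score.
#'
#' @param features,targets Training feature matrix and response.
#' @param families Model families from [model_library()].
#' @param n_trials Number of trials (desk-scale default 100; the full-scale
#'   protocol uses 5000).
#' @param seed Integer seed controlling the whole trial sequence.
#' @param k_lca,lambda,n_folds Passed to [custom_score()].
#' @return A `tune_result`: list with `trials` (per-trial history tibble),
#'   and `candidates` — per family, the best parameter list with its score
#'   breakdown, ranked by total score.
#' @export
tune_models <- function(features, targets, families = model_library(),
                        n_trials = 100, seed = 1, k_lca = 2, lambda = 1,
                        n_folds = 3) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  space <- list(family = p_categorical(names(families)))
  for (fam in names(families)) {
    for (pn in names(families[[fam]]$space)) {
      space[[paste(fam, pn, sep = ".")]] <- families[[fam]]$space[[pn]]
    }
  }
  objective <- function(params) {
    fam <- params$family
    sub <- params[startsWith(names(params), paste0(fam, "."))]
    names(sub) <- sub(paste0("^", fam, "\\."), "", names(sub))
    fit_fun <- families[[fam]]$build(sub)
    custom_score(fit_fun, X, y, k_lca = k_lca, lambda = lambda,
                 n_folds = n_folds, seed = seed)$total
  }
  res <- tpe_minimize(space, objective, n_trials = n_trials, seed = seed)

  candidates <- purrr::map(names(families), function(fam) {
    tr <- res$trials[res$trials$family == fam & is.finite(res$trials$value), ]
    if (nrow(tr) == 0L) return(NULL)
    best <- res$trials$trial[res$trials$family == fam &
                               res$trials$value == min(tr$value)][1]
    raw <- res$trials[res$trials$trial == best, ]
    sub <- as.list(raw[, paste(fam, names(families[[fam]]$space), sep = "."),
                       drop = FALSE])
    names(sub) <- names(families[[fam]]$space)
    # restore integer types lost in the history tibble
    for (pn in names(sub)) {
      if (families[[fam]]$space[[pn]]$type == "int") {
        sub[[pn]] <- as.integer(sub[[pn]])
      }
    }
    list(family = fam, params = sub, score = raw$value)
  })
  candidates <- purrr::compact(candidates)
  candidates <- candidates[order(vapply(candidates, `[[`, 0, "score"))]
  names(candidates) <- vapply(candidates, `[[`, "", "family")
  structure(list(trials = res$trials, candidates = candidates,
                 best_value = res$best_value, seed = seed),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat("<tune_result>", nrow(x$trials), "trials,",
      length(x$candidates), "candidate families\n")
  for (cand in x$candidates) {
    cat(sprintf("  %-6s score %.4f\n", cand$family, cand$score))
  }
  invisible(x)
}
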