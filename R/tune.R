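#' Hyperparameter space primitives
#'
#' Parameter definitions for [tpe_minimize()] / [tune_models()]: continuous
#' uniform, log-uniform, integer and categorical dimensions.
#'
#' @param low,high Bounds (inclusive).
#' @param choices Vector of categorical choices.
#' @return A parameter-definition list.
#' @export
p_uniform <- function(low, high) {
  stopifnot(high > low)
  list(type = "uniform", low = low, high = high)
}

#' @rdname p_uniform
#' @export
p_loguniform <- function(low, high) {
  stopifnot(low > 0, high > low)
  list(type = "loguniform", low = low, high = high)
}

#' @rdname p_uniform
#' @export
p_int <- function(low, high) {
  stopifnot(high >= low)
  list(type = "int", low = as.integer(low), high = as.integer(high))
}

#' @rdname p_uniform
#' @export
p_categorical <- function(choices) {
  stopifnot(length(choices) >= 1)
  list(type = "categorical", choices = choices)
}

sample_param <- function(def) {
  switch(def$type,
    uniform = stats::runif(1, def$low, def$high),
    loguniform = exp(stats::runif(1, log(def$low), log(def$high))),
    int = sample(seq(def$low, def$high), 1L),
    categorical = def$choices[[sample.int(length(def$choices), 1L)]]
  )
}

param_transform <- function(x, def) if (def$type == "loguniform") log(x) else x
param_back <- function(t, def) {
  x <- if (def$type == "loguniform") exp(t) else t
  if (def$type == "int") x <- as.integer(round(x))
  lo <- def$low; hi <- def$high
  min(max(x, lo), hi)
}

kde_logdens <- function(x, centers, bw) {
  log(rowMeans(outer(x, centers, function(a, b) stats::dnorm(a, b, bw))) + 1e-300)
}

# Propose one parameter value by the Parzen-estimator density ratio:
# draw candidates from a Gaussian mixture over the good trials and keep the
# candidate maximising l(x)/g(x).
tpe_suggest_param <- function(def, good, bad, n_candidates = 24L) {
  if (length(good) < 2L || length(bad) < 2L) return(sample_param(def))
  if (def$type == "categorical") {
    lv <- def$choices
    pg <- (tabulate(match(good, lv), length(lv)) + 1)
    pb <- (tabulate(match(bad, lv), length(lv)) + 1)
    cand <- sample(seq_along(lv), n_candidates, replace = TRUE, prob = pg / sum(pg))
    ratio <- (pg / sum(pg)) / (pb / sum(pb))
    return(lv[[cand[which.max(ratio[cand])]]])
  }
  gt <- param_transform(as.numeric(good), def)
  bt <- param_transform(as.numeric(bad), def)
  span <- param_transform(def$high, def) - param_transform(def$low, def)
  bw_g <- max(1.06 * stats::sd(gt) * length(gt)^-0.2, span / 25)
  bw_b <- max(1.06 * stats::sd(bt) * length(bt)^-0.2, span / 25)
  cand <- sample(gt, n_candidates, replace = TRUE) +
    stats::rnorm(n_candidates, 0, bw_g)
  cand <- pmin(pmax(cand, param_transform(def$low, def)),
               param_transform(def$high, def))
  score <- kde_logdens(cand, gt, bw_g) - kde_logdens(cand, bt, bw_b)
  param_back(cand[which.max(score)], def)
}

split_good_bad <- function(values, gamma = 0.25) {
  ok <- is.finite(values)
  thr <- stats::quantile(values[ok], gamma, names = FALSE, type = 7)
  list(good = which(ok & values <= thr), bad = which(!ok | values > thr))
}

#' Minimise an objective with a tree-structured Parzen estimator
#'
#' Sequential model-based search: the first `n_startup` trials sample the
#' space uniformly; later trials split the history at the `gamma` score
#' quantile and propose, per dimension, the candidate maximising the
#' good/bad Parzen density ratio. Identical seeds give identical trial
#' sequences.
#'
#' @param space Named list of parameter definitions ([p_uniform()] and
#'   friends).
#' @param objective Function taking a named parameter list, returning a
#'   finite numeric score to minimise (errors count as failed trials).
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed.
#' @param n_startup Uniform warm-up trials.
#' @param gamma Good/bad split quantile.
#' @param n_candidates Candidates scored per dimension and trial.
#' @return A list: `best_params`, `best_value`, and the full `trials` tibble.
#' @export
#' @examples
#' res <- tpe_minimize(list(x = p_uniform(-5, 5)),
#'                     function(p) (p$x - 2)^2, n_trials = 60, seed = 1)
#' res$best_params$x
tpe_minimize <- function(space, objective, n_trials = 100, seed = 1,
                         n_startup = 10L, gamma = 0.25, n_candidates = 24L) {
  stopifnot(n_trials >= 1)
  withr::with_seed(seed, {
    hist_params <- vector("list", n_trials)
    values <- rep(NA_real_, n_trials)
    errors <- character(n_trials)
    for (i in seq_len(n_trials)) {
      params <- if (i <= n_startup) {
        lapply(space, sample_param)
      } else {
        sb <- split_good_bad(values[seq_len(i - 1L)], gamma)
        lapply(stats::setNames(names(space), names(space)), function(nm) {
          gv <- lapply(hist_params[sb$good], `[[`, nm)
          bv <- lapply(hist_params[sb$bad], `[[`, nm)
          tpe_suggest_param(space[[nm]], unlist(gv), unlist(bv), n_candidates)
        })
      }
      hist_params[[i]] <- params
      res <- tryCatch(objective(params), error = function(e) e)
      if (inherits(res, "error")) {
        values[i] <- Inf
        errors[i] <- conditionMessage(res)
      } else {
        values[i] <- as.numeric(res)
      }
    }
    if (all(!is.finite(values))) {
      stop("all tuning trials failed; first error: ",
           errors[which(nzchar(errors))[1]], call. = FALSE)
    }
    best <- which.min(values)
    trials <- dplyr::bind_cols(
      tibble::tibble(trial = seq_len(n_trials), value = values),
      dplyr::bind_rows(lapply(hist_params, function(p)
        tibble::as_tibble(lapply(p, function(v)
          if (is.numeric(v)) v else as.character(v)))))
    )
    list(best_params = hist_params[[best]], best_value = values[best],
         trials = trials)
  })
}
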