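#' Feed-forward network specification
#'
#' Architecture and training hyperparameters of the multi-layer perceptron
#' regressor. The default is the tuned architecture used for the COX-inhibitor
#' solubility model: hidden layers of 64, 17, 45, 54, 18, 14, 45 and 61
#' neurons, ReLU activation, L2 regularisation `alpha = 0.045`, an adaptive
#' learning-rate mode (relevant only to gradient-descent solvers; the default
#' solver is L-BFGS) and a capped iteration count. `max_iter` defaults to a
#' desk-scale 10000; the full-scale 928539 is accepted.
#'
#' @param hidden_layer_sizes Integer vector of hidden-layer widths (all >= 1).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param alpha L2 regularisation coefficient (>= 0).
#' @param learning_rate_mode Learning-rate schedule name (metadata for
#'   gradient solvers).
#' @param solver `"lbfgs"` (the only implemented solver).
#' @param max_iter Maximum optimiser iterations.
#' @return A `network_spec` list.
#' @export
#' @examples
#' network_spec()$hidden_layer_sizes
network_spec <- function(hidden_layer_sizes = c(64, 17, 45, 54, 18, 14, 45, 61),
                         activation = c("relu", "tanh"),
                         alpha = 0.045,
                         learning_rate_mode = "adaptive",
                         solver = "lbfgs",
                         max_iter = 10000L) {
  activation <- match.arg(activation)
  hidden_layer_sizes <- as.integer(hidden_layer_sizes)
  stopifnot(length(hidden_layer_sizes) >= 1, all(hidden_layer_sizes >= 1),
            alpha >= 0, max_iter >= 1, identical(solver, "lbfgs"))
  structure(list(hidden_layer_sizes = hidden_layer_sizes,
                 activation = activation, alpha = alpha,
                 learning_rate_mode = learning_rate_mode,
                 solver = solver, max_iter = as.integer(max_iter)),
            class = "network_spec")
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}
act_grad <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - tanh(z)^2
}

mlp_layout <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  n_layer <- length(sizes) - 1L
  offs <- vector("list", n_layer)
  pos <- 0L
  for (l in seq_len(n_layer)) {
    nw <- sizes[l] * sizes[l + 1L]
    offs[[l]] <- list(w = pos + seq_len(nw), b = pos + nw + seq_len(sizes[l + 1L]))
    pos <- pos + nw + sizes[l + 1L]
  }
  list(sizes = sizes, offsets = offs, n_par = pos)
}

unpack_params <- function(theta, layout) {
  lapply(seq_along(layout$offsets), function(l) {
    o <- layout$offsets[[l]]
    list(W = matrix(theta[o$w], layout$sizes[l], layout$sizes[l + 1L]),
         b = theta[o$b])
  })
}

mlp_forward <- function(X, params, activation) {
  n_layer <- length(params)
  A <- vector("list", n_layer + 1L)
  Z <- vector("list", n_layer)
  A[[1]] <- X
  for (l in seq_len(n_layer)) {
    Z[[l]] <- sweep(A[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`)
    A[[l + 1L]] <- if (l < n_layer) act_fun(Z[[l]], activation) else Z[[l]]
  }
  list(A = A, Z = Z, pred = as.vector(A[[n_layer + 1L]]))
}

#' Train a multi-layer perceptron regressor
#'
#' Fits the network of `spec` to a numeric feature matrix and a numeric
#' target (log10 mole-fraction solubility in the pipeline) by minimising
#' \eqn{\tfrac12\,\mathrm{MSE} + \tfrac{\alpha}{2n}\sum_l \lVert W_l\rVert^2}
#' (biases unpenalised) with L-BFGS and analytic backpropagation gradients.
#'
#' @param spec A [network_spec()].
#' @param features Numeric matrix or data frame of finite predictor values.
#' @param targets Numeric response vector.
#' @param seed Optional integer seed for the weight initialisation (Glorot
#'   uniform).
#' @return An `mlp_regressor` object with a [predict()][predict.mlp_regressor]
#'   method.
#' @export
#' @examples
#' x <- matrix(seq(-1, 1, length.out = 50))
#' fit <- train_network(network_spec(8, alpha = 1e-6), x, 2 * x[, 1] + 1, seed = 1)
#' cor(predict(fit, x), 2 * x[, 1] + 1)^2
train_network <- function(spec, features, targets, seed = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(targets)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("features and targets must be finite", call. = FALSE)
  }
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L)
  n <- nrow(X)
  layout <- mlp_layout(ncol(X), spec$hidden_layer_sizes)
  n_layer <- length(layout$sizes) - 1L

  if (!is.null(seed)) {
    theta0 <- withr::with_seed(seed, glorot_init(layout))
  } else {
    theta0 <- glorot_init(layout)
  }

  obj <- function(theta) {
    params <- unpack_params(theta, layout)
    fw <- mlp_forward(X, params, spec$activation)
    resid <- fw$pred - y
    0.5 * mean(resid^2) +
      spec$alpha / (2 * n) * sum(vapply(params, function(p) sum(p$W^2), 0))
  }
  grad <- function(theta) {
    params <- unpack_params(theta, layout)
    fw <- mlp_forward(X, params, spec$activation)
    g <- numeric(layout$n_par)
    delta <- matrix((fw$pred - y) / n, ncol = 1)
    for (l in rev(seq_len(n_layer))) {
      o <- layout$offsets[[l]]
      gW <- crossprod(fw$A[[l]], delta) + spec$alpha / n * params[[l]]$W
      g[o$w] <- gW
      g[o$b] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(params[[l]]$W)) *
          act_grad(fw$Z[[l - 1L]], spec$activation)
      }
    }
    g
  }

  fit <- stats::optim(theta0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = spec$max_iter, factr = 1e6))
  structure(list(spec = spec, theta = fit$par, layout = layout,
                 loss = fit$value, convergence = fit$convergence,
                 feature_names = colnames(X)),
            class = "mlp_regressor")
}

glorot_init <- function(layout) {
  theta <- numeric(layout$n_par)
  for (l in seq_along(layout$offsets)) {
    o <- layout$offsets[[l]]
    lim <- sqrt(6 / (layout$sizes[l] + layout$sizes[l + 1L]))
    theta[o$w] <- stats::runif(length(o$w), -lim, lim)
    theta[o$b] <- 0
  }
  theta
}

#' @export
predict.mlp_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  params <- unpack_params(object$theta, object$layout)
  mlp_forward(X, params, object$spec$activation)$pred
}

#' @export
print.mlp_regressor <- function(x, ...) {
  cat("<mlp_regressor>", paste(x$spec$hidden_layer_sizes, collapse = "-"),
      "hidden units,", x$spec$activation, "activation\n")
  cat("  ", x$layout$n_par, "parameters, final loss",
      format(x$loss, digits = 4), "\n")
  invisible(x)
}

#' @export
glance.mlp_regressor <- function(x, ...) {
  tibble::tibble(n_parameters = x$layout$n_par,
                 n_hidden_layers = length(x$spec$hidden_layer_sizes),
                 alpha = x$spec$alpha, loss = x$loss,
                 converged = x$convergence == 0)
}
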