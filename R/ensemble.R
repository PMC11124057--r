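softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

optimise_simplex_weights <- function(P, y) {
  m <- ncol(P)
  if (m == 1L) return(1)
  obj <- function(z) rmsd(y, as.vector(P %*% softmax(z)))
  member_rmsd <- apply(P, 2, function(p) rmsd(y, p))
  starts <- list(rep(0, m), 8 * (seq_len(m) == which.min(member_rmsd)))
  best <- NULL
  for (z0 in starts) {
    fit <- stats::optim(z0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  softmax(best$par)
}

#' Build a validation-RMSD-optimal pruned ensemble
#'
#' Optimises non-negative member weights (summing to 1) by minimising the
#' root-mean-square deviation of the weighted prediction on the validation
#' subset, removes members contributing less than `min_weight` (1%),
#' renormalises, and re-optimises over the survivors. Members with identical
#' validation predictions are degenerate; their weight is shared equally.
#' When one model dominates, the procedure naturally collapses to selecting
#' that single model.
#'
#' @param models Named list of fitted models (each with a `predict` method).
#' @param features Validation feature matrix.
#' @param targets Validation response.
#' @param min_weight Pruning threshold on a member's weight.
#' @return A `des_ensemble`: members, weights (all >= `min_weight`, summing
#'   to 1), per-member and ensemble validation RMSD.
#' @export
build_ensemble <- function(models, features, targets, min_weight = 0.01) {
  if (length(models) == 0L) stop("no candidate models supplied", call. = FALSE)
  if (is.null(names(models))) names(models) <- paste0("m", seq_along(models))
  X <- as.matrix(features)
  y <- as.numeric(targets)
  P <- vapply(models, function(m) as.numeric(predict(m, X)), numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X), dimnames = list(NULL, names(models)))

  keep <- seq_along(models)
  repeat {
    w <- optimise_simplex_weights(P[, keep, drop = FALSE], y)
    # equal weights within groups of members with identical predictions
    groups <- ties_groups(P[, keep, drop = FALSE])
    for (g in groups) w[g] <- mean(w[g])
    drop_idx <- which(w < min_weight)
    if (length(drop_idx) == 0L || length(keep) == 1L) break
    keep <- keep[-drop_idx[which.min(w[drop_idx])]]
  }
  w <- w / sum(w)

  ens_pred <- as.vector(P[, keep, drop = FALSE] %*% w)
  structure(
    list(members = models[keep], weights = stats::setNames(w, names(models)[keep]),
         val_rmsd = rmsd(y, ens_pred),
         member_rmsd = apply(P, 2, function(p) rmsd(y, p)),
         min_weight = min_weight),
    class = "des_ensemble")
}

ties_groups <- function(P, tol = 1e-10) {
  m <- ncol(P)
  assigned <- integer(m)
  gid <- 0L
  for (j in seq_len(m)) {
    if (assigned[j] > 0L) next
    gid <- gid + 1L
    assigned[j] <- gid
    if (j < m) {
      for (k in seq((j + 1L), m)) {
        if (assigned[k] == 0L && max(abs(P[, j] - P[, k])) < tol) {
          assigned[k] <- gid
        }
      }
    }
  }
  unname(split(seq_len(m), assigned))
}

#' @export
predict.des_ensemble <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  P <- vapply(object$members, function(m) as.numeric(predict(m, X)),
              numeric(nrow(X)))
  as.vector(matrix(P, nrow = nrow(X)) %*% object$weights)
}

#' @export
print.des_ensemble <- function(x, ...) {
  cat("<des_ensemble>", length(x$members), "member(s), validation RMSD",
      format(x$val_rmsd, digits = 4), "\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-8s weight %.3f\n", nm, x$weights[[nm]]))
  }
  invisible(x)
}

#' @export
tidy.des_ensemble <- function(x, ...) {
  tibble::tibble(member = names(x$weights),
                 weight = unname(x$weights),
                 val_rmsd = unname(x$member_rmsd[names(x$weights)]))
}

#' @export
glance.des_ensemble <- function(x, ...) {
  tibble::tibble(n_members = length(x$members),
                 val_rmsd = x$val_rmsd,
                 best_member_rmsd = min(x$member_rmsd),
                 min_weight = x$min_weight)
}
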