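#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_abline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a sigma-potential
#'
#' @param potential A sigma-potential tibble from [sigma_potential()] /
#'   [mixture_potential()] (several may be row-bound; curves are coloured by
#'   `source`).
#' @return A ggplot.
#' @export
plot_sigma_potential <- function(potential) {
  ggplot(potential, aes(x = .data$sigma, y = .data$mu,
                        colour = .data$source)) +
    geom_line() +
    labs(x = expression(sigma ~ "(e/" * ring(A)^2 * ")"),
         y = expression(mu[S](sigma) ~ "(kJ/(mol" ~ ring(A)^2 * "))"),
         colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.sigma_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$report, c("r2_nonDES", "r2_DES"),
                              names_to = "subset", values_to = "r2")
  ggplot(long, aes(x = .data$sigma, y = .data$r2, colour = .data$subset)) +
    geom_line() +
    geom_point(data = long[long$r2 > object$threshold, ], size = 2) +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    labs(x = expression(sigma ~ "(e/" * ring(A)^2 * ")"),
         y = expression(R^2), colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.calibration_curve <- function(object, ...) {
  d <- object$model$model
  names(d) <- c("absorbance", "conc_mg_mL")
  ggplot(d, aes(x = .data$conc_mg_mL, y = .data$absorbance)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept) +
    labs(x = "concentration (mg/mL)", y = "absorbance") +
    theme_minimal()
}

#' @export
autoplot.des_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$member, y = .data$weight)) +
    geom_col() +
    geom_hline(yintercept = object$min_weight, linetype = 2) +
    labs(x = NULL, y = "ensemble weight") +
    theme_minimal()
}

#' Plot a cosolvency curve
#'
#' @param series Tibble with `x_star_des` and `x_exp` columns.
#' @return A ggplot with the neat-DES level marked.
#' @export
plot_cosolvency <- function(series) {
  neat <- series$x_exp[abs(series$x_star_des - 1) < 1e-12]
  ggplot(series, aes(x = .data$x_star_des, y = .data$x_exp)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = neat, linetype = 2) +
    labs(x = expression(x["DES"]^"*"), y = "mole-fraction solubility") +
    theme_minimal()
}
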