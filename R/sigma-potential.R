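#' Interaction constants for the simplified COSMO-RS engine
#'
#' Versioned constants of the segment-interaction model used to turn
#' sigma-profiles into temperature-dependent sigma-potentials: the
#' electrostatic misfit prefactor `alpha_prime`, the hydrogen-bond strength
#' `c_hb` and threshold `sigma_hb`, the effective segment area `a_eff`, and
#' the fixed-point solver controls. The misfit/hydrogen-bond values are the
#' widely used open COSMO-SAC parameterisation converted to kJ.
#'
#' @param alpha_prime Misfit energy constant, kJ A^4 / (mol e^2).
#' @param c_hb Hydrogen-bond energy constant, kJ A^4 / (mol e^2).
#' @param sigma_hb Hydrogen-bond screening-charge threshold, e/A^2.
#' @param a_eff Effective segment surface area, A^2.
#' @param damping Fixed-point damping factor in (0, 1].
#' @param tol Convergence tolerance on the max-abs change of the segment
#'   log-activity, dimensionless.
#' @param max_iter Maximum fixed-point iterations.
#' @return A named list of constants (class `cosmo_constants`).
#' @export
cosmo_constants <- function(alpha_prime = 16466.72 * 4.184,
                            c_hb = 85580 * 4.184,
                            sigma_hb = 0.0084,
                            a_eff = 7.5,
                            damping = 0.5,
                            tol = 1e-10,
                            max_iter = 10000L) {
  stopifnot(alpha_prime > 0, c_hb >= 0, sigma_hb > 0, a_eff > 0,
            damping > 0, damping <= 1, tol > 0, max_iter >= 1)
  structure(
    list(alpha_prime = alpha_prime, c_hb = c_hb, sigma_hb = sigma_hb,
         a_eff = a_eff, damping = damping, tol = tol,
         max_iter = as.integer(max_iter), version = "1.0"),
    class = "cosmo_constants"
  )
}

# Segment-pair exchange energy matrix W[i, j] (kJ/mol) on grid `sig`:
# electrostatic misfit plus hydrogen-bond term (active only when one segment
# is a donor beyond -sigma_hb and the other an acceptor beyond +sigma_hb).
exchange_energy <- function(sig, constants) {
  si <- matrix(sig, length(sig), length(sig))
  sj <- t(si)
  acc <- pmax(si, sj)
  don <- pmin(si, sj)
  constants$alpha_prime / 2 * (si + sj)^2 +
    constants$c_hb * pmax(0, acc - constants$sigma_hb) *
      pmin(0, don + constants$sigma_hb)
}

# Normalised area-weighted sigma composition of a (mixture) liquid:
# p_S(sigma) = sum_i x_i A_i(sigma) / sum_i x_i A_i^total.
mixture_sigma_composition <- function(area_list, mole_fractions) {
  num <- Reduce(`+`, Map(`*`, area_list, mole_fractions))
  num / sum(num)
}

#' Self-consistent sigma-potential of a liquid
#'
#' Solves the simplified COSMO-RS segment self-consistency equation for a pure
#' compound or a mixture of sigma-profiles at temperature `T`, by damped
#' fixed-point iteration of
#' \deqn{\ln\Gamma_S(\sigma) = -\ln \sum_{\sigma'} p_S(\sigma')\,
#'   \Gamma_S(\sigma')\, e^{-W(\sigma,\sigma')/RT}}
#' where the exchange energy `W` combines the electrostatic misfit and
#' hydrogen-bond terms of [cosmo_constants()]. The sigma-potential is the
#' per-area segment chemical potential
#' \eqn{\mu_S(\sigma) = RT \ln\Gamma_S(\sigma) / a_\mathrm{eff}}
#' in kJ/(mol A^2).
#'
#' @param profiles Long sigma-profile tibble (`compound_id`, `sigma`, `area`)
#'   holding the profiles of all mixture components.
#' @param mole_fractions Named or positional numeric vector of component mole
#'   fractions (non-negative, summing to 1); names, when given, are matched
#'   against `compound_id`. Defaults to a single pure component.
#' @param T Temperature in K.
#' @param constants A [cosmo_constants()] list.
#' @return A tibble with columns `sigma`, `mu` (kJ/(mol A^2)), `temperature`
#'   (K) and `source` (`"pure-compound"` or `"mixture"`), carrying the number
#'   of fixed-point iterations in attribute `iterations`.
#' @export
#' @examples
#' pr <- sigma_profile("toy", dnorm(sigma_grid(), 0, 0.004))
#' pot <- sigma_potential(pr, T = 298.15)
#' pot$sigma[which.min(pot$mu)]
sigma_potential <- function(profiles, mole_fractions = NULL, T = 298.15,
                            constants = cosmo_constants()) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0)
  if (nrow(profiles) == 0L) stop("empty sigma-profile table", call. = FALSE)
  ids <- unique(profiles$compound_id)
  if (is.null(mole_fractions)) {
    if (length(ids) != 1L) {
      stop("`mole_fractions` must be given for a multi-component liquid",
           call. = FALSE)
    }
    mole_fractions <- 1
  }
  if (!is.null(names(mole_fractions))) {
    ids <- names(mole_fractions)
  } else if (length(mole_fractions) != length(ids)) {
    stop("one mole fraction per component is required", call. = FALSE)
  }
  if (any(mole_fractions < 0) || abs(sum(mole_fractions) - 1) > 1e-8) {
    stop("mole fractions must be non-negative and sum to 1", call. = FALSE)
  }
  areas <- lapply(ids, function(id) profile_areas(profiles, id))
  p <- mixture_sigma_composition(areas, mole_fractions)
  sig <- sigma_grid()

  RT <- GAS_CONSTANT * T / 1000 # kJ/mol
  K <- exp(-exchange_energy(sig, constants) / RT)

  ln_gamma <- numeric(length(sig))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ln_new <- -log(as.vector(K %*% (p * exp(ln_gamma))))
    delta <- max(abs(ln_new - ln_gamma))
    ln_gamma <- (1 - constants$damping) * ln_gamma + constants$damping * ln_new
    if (delta < constants$tol) break
    if (iter >= constants$max_iter) {
      stop("sigma-potential fixed point did not converge after ",
           constants$max_iter, " iterations (final residual ",
           format(delta, digits = 3), ")", call. = FALSE)
    }
  }

  out <- tibble::tibble(
    sigma = sig,
    mu = RT * ln_gamma / constants$a_eff,
    temperature = T,
    source = if (length(ids) > 1L) "mixture" else "pure-compound"
  )
  attr(out, "iterations") <- iter
  out
}

#' Sigma-potential of a solvent system
#'
#' Combines the pure-component sigma-potentials of a solvent system's
#' components, weighted by their solute-free mole fractions. The default
#' (`method = "potential"`) linearly weights the component
#' \emph{sigma-potentials}; `method = "profile"` instead mixes the
#' sigma-profiles by mole fraction and solves the self-consistency once for
#' the mixed liquid (provided for comparison).
#'
#' @param system A solvent-system component table from [des_system()] or
#'   [solvent_mixture()] (a single `system_id`).
#' @param profiles Long sigma-profile tibble holding every component.
#' @param T Temperature in K.
#' @param constants A [cosmo_constants()] list.
#' @param method `"potential"` (default) or `"profile"`.
#' @return A sigma-potential tibble as from [sigma_potential()], with
#'   `source = "mixture"`.
#' @export
mixture_potential <- function(system, profiles, T = 298.15,
                              constants = cosmo_constants(),
                              method = c("potential", "profile")) {
  method <- match.arg(method)
  stopifnot(length(unique(system$system_id)) == 1L)
  missing <- setdiff(system$component, unique(profiles$compound_id))
  if (length(missing) > 0L) {
    stop("no sigma-profile available for component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- system$fraction / sum(system$fraction)

  if (method == "profile") {
    names(w) <- system$component
    out <- sigma_potential(profiles, mole_fractions = w, T = T,
                           constants = constants)
    out$source <- "mixture"
    return(out)
  }

  pots <- lapply(system$component, function(id) {
    sigma_potential(profiles[profiles$compound_id == id, ], T = T,
                    constants = constants)$mu
  })
  tibble::tibble(
    sigma = sigma_grid(),
    mu = as.vector(Reduce(`+`, Map(`*`, pots, w))),
    temperature = T,
    source = "mixture"
  )
}

#' Relative solute-solvent sigma-potential
#'
#' Pointwise difference between the sigma-potential of a pure solute and that
#' of a solvent (system) at the same temperature — the descriptor family used
#' for solubility modelling.
#'
#' @param solute,solvent Sigma-potential tibbles from [sigma_potential()] /
#'   [mixture_potential()] on the canonical grid at the same temperature.
#' @return A tibble with columns `sigma`, `delta_mu` (kJ/(mol A^2)) and
#'   `temperature`.
#' @export
relative_potential <- function(solute, solvent) {
  check_grid(solute$sigma)
  check_grid(solvent$sigma)
  ts <- unique(solute$temperature)
  tv <- unique(solvent$temperature)
  if (length(ts) != 1L || length(tv) != 1L || abs(ts - tv) > 1e-9) {
    stop("solute and solvent sigma-potentials must share one temperature",
         call. = FALSE)
  }
  tibble::tibble(
    sigma = solute$sigma,
    delta_mu = solute$mu - solvent$mu,
    temperature = ts
  )
}
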