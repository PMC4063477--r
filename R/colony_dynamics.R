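# Hybrid annual colony dynamics: within a year colony densities are frozen
# and patch occupancy is resolved daily at quasi-steady state; the food a
# species clears over the year is converted to new colonies in a discrete
# between-year update, iterated to community equilibrium.

#' Configuration for the annual colony-dynamics map
#'
#' @param L Days per year (default 365).
#' @param mu Relaxation/death rate of the annual map (time^-1). The map's
#'   fixed point `N* = B(N*) / L` does not depend on `mu`; `mu` only sets how
#'   fast colony densities relax towards it, which is why food quality enters
#'   the model only through `eps_prime = eps / mu`. Default `1 / L`, the
#'   fastest relaxation; an internal oscillation guard halves the rate when
#'   the iteration cycles instead of contracting.
#' @param extinction_threshold Relative abundance below which a species is
#'   recorded absent at equilibrium (default 1e-3 of the community total).
#' @param max_years Iteration cap (default 2000); hitting it is reported as
#'   non-convergence, never silently truncated.
#' @param convergence_tol Relative change below which the iteration stops
#'   (default 1e-6).
#' @param n0 Default initial colony density per species (default 0.1).
#' @return A `dynamics_config` list.
#' @export
dynamics_config <- function(L = 365, mu = 1 / L,
                            extinction_threshold = 1e-3,
                            max_years = 2000, convergence_tol = 1e-6,
                            n0 = 0.1) {
  stopifnot(mu > 0, extinction_threshold > 0, extinction_threshold <= 0.01,
            convergence_tol > 0, max_years >= 1, L > 0, n0 > 0)
  structure(list(L = L, mu = mu,
                 extinction_threshold = extinction_threshold,
                 max_years = max_years, convergence_tol = convergence_tol,
                 n0 = n0),
            class = "dynamics_config")
}

# Precompute the daily forcing for a scenario: the S x L matrix of foraging
# efforts and the length-L resource vector, plus the per-species constants
# that turn colony densities into attack rates and patch holdings into
# colony births. Row order of `traits` must be ascending dominance rank
# (asserted), which is what makes the strict-hierarchy solve triangular.
build_forcing <- function(traits, sigma, config = dynamics_config(),
                          lambda_r = 1) {
  stopifnot(is.data.frame(traits), inherits(sigma, "phenology_curve"))
  if (is.unsorted(traits$rank, strictly = TRUE)) {
    stop("trait rows must be ordered by ascending dominance rank")
  }
  days <- seq(0, config$L - 1)
  Fmat <- t(vapply(traits$foraging, pheno_at, numeric(length(days)),
                   day = days))
  list(Fmat = Fmat, sig = pheno_at(sigma, days),
       k_attack = lambda_r * traits$r * traits$a,
       species = traits$name, c_rel = traits$c, w = traits$w, a = traits$a)
}

#' Yearly birth potential from daily patch holdings
#'
#' Sums each species' quasi-steady-state patch holdings over the days of one
#' year (colony densities frozen at their start-of-year values) and converts
#' the cleared food into potential new colonies:
#' `B_i = eps_prime * lambda_c * c_i / (w_i * a_i) * sum_d p_i*(d)`.
#' Division by worker mass `w_i` turns harvested food into workers, and by
#' `a_i` workers into colonies; only food from patches the species itself
#' clears is credited (patches lost to takeover yield nothing).
#'
#' @param N Start-of-year colony densities.
#' @param traits Species trait table (rows in ascending rank order).
#' @param mh A [microhabitat()].
#' @param sigma Resource [phenology_curve()].
#' @param w_mode Win-matrix mode, `"strict"` or `"equal"`.
#' @param config A [dynamics_config()].
#' @return Numeric vector `B` of yearly birth potentials, `>= 0`.
#' @export
annual_yield <- function(N, traits, mh, sigma, w_mode = "strict",
                         config = dynamics_config()) {
  forc <- build_forcing(traits, sigma, config)
  yield_from_forcing(N, forc, mh, w_mode)
}

yield_from_forcing <- function(N, forc, mh, w_mode) {
  P <- qss_year(forc$k_attack * N, forc$Fmat, forc$sig, mh, forc$c_rel,
                w_mode)
  mh$eps_prime * mh$lambda_c * forc$c_rel / (forc$w * forc$a) * rowSums(P)
}

#' One step of the annual colony-density map
#'
#' `N_i(y + 1) = max(N_i(y) + mu * (B_i - L * N_i(y)), 0)`: colony density
#' relaxes towards the yearly birth potential divided by the year length.
#'
#' @param N Current colony densities.
#' @param B Yearly birth potentials from [annual_yield()].
#' @param config A [dynamics_config()].
#' @return Updated colony densities.
#' @export
annual_update <- function(N, B, config = dynamics_config()) {
  out <- N + config$mu * (B - config$L * N)
  if (any(!is.finite(out))) stop("non-finite colony density in annual update",
                                 call. = FALSE)
  pmax(out, 0)
}

#' Iterate the annual map to community equilibrium
#'
#' Repeats daily-QSS years and annual updates until the largest per-species
#' change, relative to the community total, falls below `convergence_tol`,
#' or until `max_years` is reached (reported via `converged = FALSE`).
#' Species whose equilibrium share of the community total is below
#' `extinction_threshold` are flagged absent. Densities below 1e-12 of the
#' community total are set to zero, a numerical floor that shortens the
#' geometric tail of competitive exclusion without affecting presence calls.
#'
#' @param N0 Initial colony densities (default `config$n0` for each species).
#' @inheritParams annual_yield
#' @return A list: `N` (equilibrium densities), `present` (logical flags),
#'   `years` (iterations used), `converged`.
#' @export
iterate_to_equilibrium <- function(traits, mh, sigma, w_mode = "strict",
                                   config = dynamics_config(), N0 = NULL) {
  forc <- build_forcing(traits, sigma, config)
  equilibrium_from_forcing(forc, mh, w_mode, config, N0)
}

equilibrium_from_forcing <- function(forc, mh, w_mode, config, N0 = NULL) {
  S <- length(forc$k_attack)
  N <- if (is.null(N0)) rep(config$n0, S) else as.numeric(N0)
  stopifnot(length(N) == S, all(N >= 0))
  converged <- FALSE
  years <- 0L
  cfg <- config
  prev_delta <- Inf
  for (y in seq_len(config$max_years)) {
    B <- yield_from_forcing(N, forc, mh, w_mode)
    # fixed-point residual |B/L - N|: unlike the per-year change, this
    # stopping rule does not scale with mu, so equilibria agree across
    # relaxation rates
    delta <- max(abs(B / config$L - N))
    scale <- sum(N)
    if (scale == 0 || delta <= config$convergence_tol * scale) {
      converged <- TRUE
      years <- y
      break
    }
    N_new <- annual_update(N, B, cfg)
    tot <- sum(N_new)
    if (tot > 0) N_new[N_new < 1e-12 * tot] <- 0
    years <- y
    N <- N_new
    # oscillation guard: if the per-year change has stopped shrinking, halve
    # the relaxation rate (the fixed point is mu-invariant, so this changes
    # only the path taken to it)
    if (y %% 25L == 0L) {
      if (delta > prev_delta) cfg$mu <- cfg$mu / 2
      prev_delta <- delta
    }
  }
  tot <- sum(N)
  present <- if (tot > 0) N / tot >= config$extinction_threshold
             else rep(FALSE, S)
  list(N = N, present = present, years = years, converged = converged,
       species = forc$species)
}
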