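# Food-patch dynamics. Patches are produced seasonally, discovered by
# foraging ants, taken over along the behavioural dominance hierarchy,
# cleared by the holder, and removed by non-focal species. On the daily
# timescale patch occupancy is assumed to equilibrate at fixed colony
# densities ("quasi-steady state"), reducing the patch ODEs to a linear
# system solved separately for each day.

#' Microhabitat resource parameters
#'
#' One randomly drawn resource-parameter vector defines a "microhabitat":
#' `lambda_s` the seasonal maximum patch production rate
#' (patches time^-1 area^-1), `lambda_c` the inverse patch size (time^-1,
#' large values = small, quickly cleared patches), `eps_prime` the food
#' quality epsilon' = epsilon / mu (conversion of harvested patches into new
#' colonies, per unit worker mass), and `b` the clearance rate by non-focal
#' species (time^-1). The discovery scale factor `lambda_r` is fixed at 1,
#' which defines the model's time and area units.
#'
#' @param lambda_s,lambda_c,eps_prime,b Non-negative scalars.
#' @param lambda_r Discovery scale factor (default 1).
#' @return A `microhabitat` list.
#' @export
microhabitat <- function(lambda_s, lambda_c, eps_prime, b, lambda_r = 1) {
  vals <- c(lambda_s, lambda_c, eps_prime, b, lambda_r)
  if (anyNA(vals) || any(vals < 0)) {
    stop("microhabitat parameters must be non-negative")
  }
  structure(list(lambda_s = lambda_s, lambda_c = lambda_c,
                 eps_prime = eps_prime, b = b, lambda_r = lambda_r),
            class = "microhabitat")
}

#' Patch-takeover (win) matrix
#'
#' `W[i, j]` is the probability that species `i` takes a contested patch from
#' species `j`. Under the strict behavioural hierarchy the more dominant
#' species always wins (`W[i, j] = 1` iff `rank_i > rank_j`); the equalized-
#' dominance scenario gives every pairing a 50% outcome.
#'
#' @param rank Integer vector of dominance ranks (1 = most subordinate), a
#'   permutation of `1:S`.
#' @param mode `"strict"` or `"equal"`.
#' @return An `S x S` matrix with zero diagonal and `W[i,j] + W[j,i] <= 1`.
#' @export
win_matrix <- function(rank, mode = c("strict", "equal")) {
  mode <- match.arg(mode)
  S <- length(rank)
  if (!setequal(rank, seq_len(S))) stop("ranks must be a permutation of 1..S")
  W <- matrix(0, S, S)
  if (mode == "strict") {
    W <- outer(rank, rank, ">") * 1
  } else {
    W <- matrix(0.5, S, S)
    diag(W) <- 0
  }
  W
}

#' Per-species patch attack (discovery) rates
#'
#' `D_i = lambda_r * r_i * a_i * N_i * f_i(day)`: the rate at which the
#' forager force of species `i` discovers unoccupied patches, given its
#' relative discovery rate `r_i`, foragers per colony `a_i`, colony density
#' `N_i` and seasonal foraging effort `f_i`.
#'
#' @param N Colony densities (colonies area^-1), one per species.
#' @param traits Species trait table (see [default_traits()]) with columns
#'   `r`, `a` and list-column `foraging` of [phenology_curve()] objects.
#' @param day Day of year at which to evaluate foraging effort.
#' @param lambda_r Discovery scale factor (default 1).
#' @return Numeric vector `D` of attack rates, `>= 0`.
#' @export
attack_rates <- function(N, traits, day, lambda_r = 1) {
  stopifnot(length(N) == nrow(traits), all(N >= 0))
  f <- vapply(traits$foraging, pheno_at, numeric(1), day = day)
  lambda_r * traits$r * traits$a * N * f
}

#' Quasi-steady-state patch occupancy for one day
#'
#' Solves the daily linear system for unoccupied (`p0`) and per-species
#' occupied (`p`) patch densities at fixed attack rates:
#' `p0 = lambda_s * sigma / (b + sum(D))`, and for each species
#' `(lambda_c c_i + b + sum_{j != i} W[j,i] D_j) p_i -
#'  D_i sum_{j != i} W[i,j] p_j = D_i p0`.
#' A strict hierarchy makes the system triangular in rank order; a general
#' win matrix requires the dense solve used here.
#'
#' @param D Attack rates, one per species.
#' @param mh A [microhabitat()].
#' @param W Win matrix from [win_matrix()].
#' @param c_rel Relative clearance rates `c_i`.
#' @param sigma_day Resource availability fraction `sigma(day)` in `[0, 1]`
#'   (values above 1 are allowed under supplementation).
#' @return A list with elements `p0` and `p`, all `>= 0`.
#' @export
patch_qss <- function(D, mh, W, c_rel, sigma_day) {
  S <- length(D)
  stopifnot(nrow(W) == S, length(c_rel) == S, all(D >= 0))
  denom0 <- mh$b + sum(D)
  if (denom0 <= 0) stop("b + sum(D) must be positive")
  p0 <- mh$lambda_s * sigma_day / denom0
  A <- -W * D                      # A[i, j] = -W[i,j] * D_i for j != i
  diag(A) <- mh$lambda_c * c_rel + mh$b + as.vector(t(W) %*% D)
  if (any(diag(A) <= 0)) stop("singular patch system: need b > 0 or clearance")
  p <- solve(A, D * p0)
  if (any(p < -1e-12)) stop("negative patch density in QSS solve")
  list(p0 = p0, p = pmax(p, 0))
}

#' Right-hand side of the patch ODEs
#'
#' The full (unreduced) patch dynamics:
#' `dp0/dt = lambda_s sigma - p0 sum(D) - b p0` and
#' `dp_i/dt = D_i (p0 + sum_{j != i} W[i,j] p_j)
#'           - p_i sum_{j != i} W[j,i] D_j - (lambda_c c_i + b) p_i`.
#' Discovery moves unoccupied patches to the discoverer; takeover transfers
#' patches up the hierarchy; clearance (`lambda_c c_i p_i`, food credited to
#' the holder) and non-focal removal (`b`) destroy patches. Used as the
#' verification oracle for [patch_qss()].
#'
#' @param p0 Unoccupied patch density.
#' @param p Per-species occupied patch densities.
#' @inheritParams patch_qss
#' @return A list with `dp0` and `dp` (time derivatives).
#' @export
patch_ode_rhs <- function(p0, p, D, mh, W, c_rel, sigma_day) {
  gains <- D * (p0 + as.vector(W %*% p))
  losses <- p * as.vector(t(W) %*% D) + (mh$lambda_c * c_rel + mh$b) * p
  dp0 <- mh$lambda_s * sigma_day - p0 * sum(D) - mh$b * p0
  list(dp0 = dp0, dp = gains - losses)
}

# Vectorized full-year QSS solve used by the equilibrium iteration.
#
# kN:     per-species constant lambda_r * r_i * a_i * N_i (length S, rank
#         order ascending = row order of Fmat)
# Fmat:   S x n_days matrix of daily foraging efforts f_i(d)
# sig:    length n_days vector sigma(d)
# Returns the S x n_days matrix of daily QSS occupied patch densities.
# For the strict hierarchy the triangular structure is solved by forward
# substitution from the most subordinate species upward; for the equalized
# (symmetric 0.5) matrix the closed form via the total occupied density is
# used. Both are validated against the dense per-day solve in the tests.
qss_year <- function(kN, Fmat, sig, mh, c_rel, w_mode = c("strict", "equal")) {
  w_mode <- match.arg(w_mode)
  S <- length(kN)
  n <- ncol(Fmat)
  D <- Fmat * kN                       # recycles kN down columns: D[i, d]
  Dsum <- .colSums(D, S, n)
  p0 <- mh$lambda_s * sig / (mh$b + Dsum)
  P <- matrix(0, S, n)
  if (w_mode == "strict") {
    # loss to all more-dominant species; gain from p0 plus all subordinate
    # holdings, so solve in ascending rank order
    above <- 0                         # sum_{j > i} D[j, ] at step i
    for (i in S:1) {
      P[i, ] <- mh$lambda_c * c_rel[i] + mh$b + above  # stash denominators
      if (i > 1) above <- above + D[i, ]
    }
    cum <- 0
    for (i in seq_len(S)) {
      P[i, ] <- D[i, ] * (p0 + cum) / P[i, ]
      cum <- cum + P[i, ]
    }
  } else {
    base <- mh$b + 0.5 * Dsum
    G <- 0
    for (i in seq_len(S)) {
      P[i, ] <- mh$lambda_c * c_rel[i] + base          # denominators
      G <- G + D[i, ] / P[i, ]
    }
    gain <- p0 + 0.5 * p0 * G / (1 - 0.5 * G)          # p0 + q / 2
    for (i in seq_len(S)) P[i, ] <- D[i, ] * gain / P[i, ]
  }
  P
}
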