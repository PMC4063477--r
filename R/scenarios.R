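# Experiment drivers: uniform microhabitat ensembles, trait equalizations,
# phenological-shift and warming scenarios, single-species (no-competition)
# contrasts, and percent-change comparisons between ensembles run on common
# random microhabitats.

#' Sample random microhabitats
#'
#' Draws `K` independent resource-parameter vectors, each parameter uniform
#' over its range. The same seed always yields the same draw, which is how
#' scenarios are compared on common random microhabitats.
#'
#' @param K Number of microhabitats, `>= 1`.
#' @param ranges Range table as from [default_ranges()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A tibble with columns `k`, `lambda_s`, `lambda_c`, `eps_prime`,
#'   `b`.
#' @export
sample_microhabitats <- function(K, ranges = default_ranges(), seed = NULL) {
  stopifnot(K >= 1)
  if (any(ranges$hi < ranges$lo)) stop("inverted parameter range")
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::map2(ranges$lo, ranges$hi, ~stats::runif(K, .x, .y))
  names(draws) <- ranges$parameter
  dplyr::bind_cols(tibble::tibble(k = seq_len(K)), tibble::as_tibble(draws))
}

#' Equalize one trait across all species
#'
#' Removes interspecific variation in a single trait, leaving all others at
#' their parameterized values: discovery rate, clearance rate, or worker
#' mass are set to one shared value drawn uniformly from the range spanned
#' by the three species (re-drawn per simulated microhabitat in ensemble
#' runs); dominance is equalized by giving every pairing a 50% contest
#' outcome; thermal niches are equalized by letting every species forage at
#' full effort all year (`f_i == 1`).
#'
#' @param traits Species trait table (see [default_traits()]).
#' @param which One of `"discovery"`, `"clearance"`, `"mass"`,
#'   `"dominance"`, `"thermal_niche"`.
#' @param value Optional shared value for the three quantitative traits;
#'   drawn uniformly from the observed range when `NULL`.
#' @return A list with the modified `traits` table and the win-matrix mode
#'   `w_mode` (`"equal"` for the dominance equalization, else `"strict"`).
#' @export
equalize_trait <- function(traits, which = c("discovery", "clearance",
                                             "mass", "dominance",
                                             "thermal_niche"),
                           value = NULL) {
  which <- match.arg(which)
  w_mode <- "strict"
  col <- switch(which, discovery = "r", clearance = "c", mass = "w",
                NA_character_)
  if (!is.na(col)) {
    if (is.null(value)) {
      value <- stats::runif(1, min(traits[[col]]), max(traits[[col]]))
    }
    traits[[col]] <- rep(value, nrow(traits))
  } else if (which == "dominance") {
    w_mode <- "equal"
  } else { # thermal_niche
    traits$foraging <- replicate(nrow(traits), constant_phenology(1),
                                 simplify = FALSE)
  }
  list(traits = traits, w_mode = w_mode)
}

#' Run an ensemble of microhabitat equilibria
#'
#' Iterates the community to equilibrium in each microhabitat and returns
#' one row per microhabitat and species. With `equalize` set to
#' `"discovery"`, `"clearance"` or `"mass"`, the shared trait value is
#' re-drawn independently for every microhabitat; `"dominance"` switches the
#' win matrix to 50/50 contests and `"thermal_niche"` sets every foraging
#' curve to 1 year-round. Per-microhabitat non-convergence is reported in
#' the `converged` column, never raised as a failure.
#'
#' @param microhabitats Tibble from [sample_microhabitats()].
#' @param traits Species trait table with `foraging` list-column, rows in
#'   ascending rank order.
#' @param sigma Resource [phenology_curve()].
#' @param w_mode Win-matrix mode (`"strict"` or `"equal"`); overridden to
#'   `"equal"` by `equalize = "dominance"`.
#' @param config A [dynamics_config()].
#' @param equalize Optional trait-equalization scenario (see above).
#' @param seed Optional seed governing the per-microhabitat equalized-trait
#'   draws (the microhabitat stream itself is fixed by its own sampling
#'   seed).
#' @return A tibble of class `ant_ensemble`: columns `k`, the four
#'   microhabitat parameters, `species`, `N` (equilibrium colony density),
#'   `workers` (`a * N`), `biomass` (`w * a * N`), `present`, `converged`,
#'   `years`.
#' @export
run_ensemble <- function(microhabitats, traits, sigma, w_mode = "strict",
                         config = dynamics_config(), equalize = NULL,
                         seed = NULL) {
  stopifnot(is.data.frame(microhabitats), nrow(microhabitats) >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (identical(equalize, "dominance")) w_mode <- "equal"
  if (identical(equalize, "thermal_niche")) {
    traits <- equalize_trait(traits, "thermal_niche")$traits
  }
  redraw <- !is.null(equalize) &&
    equalize %in% c("discovery", "clearance", "mass")
  forc <- build_forcing(traits, sigma, config)
  S <- nrow(traits)
  rows <- purrr::map(seq_len(nrow(microhabitats)), function(i) {
    row <- microhabitats[i, ]
    mh <- microhabitat(row$lambda_s, row$lambda_c, row$eps_prime, row$b)
    forc_k <- forc
    tr_k <- traits
    if (redraw) {
      tr_k <- equalize_trait(traits, equalize)$traits
      forc_k$k_attack <- tr_k$r * tr_k$a
      forc_k$c_rel <- tr_k$c
      forc_k$w <- tr_k$w
    }
    eq <- equilibrium_from_forcing(forc_k, mh, w_mode, config)
    tibble::tibble(
      k = row$k, lambda_s = row$lambda_s, lambda_c = row$lambda_c,
      eps_prime = row$eps_prime, b = row$b,
      species = traits$name, N = eq$N, workers = tr_k$a * eq$N,
      biomass = tr_k$w * tr_k$a * eq$N,
      present = eq$present, converged = eq$converged, years = eq$years
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "species") <- traits$name
  attr(out, "K") <- nrow(microhabitats)
  class(out) <- c("ant_ensemble", class(out))
  out
}

#' Run an ensemble with a single species present
#'
#' The no-competition contrast: all other species' colony densities are held
#' at zero (equivalently, the focal species is simulated alone), over the
#' same microhabitats as the community run.
#'
#' @param species Name of the focal species (a `traits$name` entry).
#' @inheritParams run_ensemble
#' @return An `ant_ensemble` tibble containing only the focal species.
#' @export
run_single_species <- function(microhabitats, traits, sigma, species,
                               w_mode = "strict",
                               config = dynamics_config(), seed = NULL) {
  if (!species %in% traits$name) stop("unknown species: ", species)
  run_ensemble(microhabitats, traits[traits$name == species, ], sigma,
               w_mode = w_mode, config = config, seed = seed)
}

#' Percent change in ensemble abundance between two scenarios
#'
#' For each species, `100 * (sum_k N'_ik - sum_k N_ik) / sum_k N_ik`, where
#' the sums run over the common microhabitats of the reference and treated
#' ensembles. With `measure = "share"` the same contrast is applied to the
#' mean relative abundance (ratio of ensemble totals) instead of the
#' absolute ensemble total.
#'
#' @param reference,treated `ant_ensemble` tibbles run on the same
#'   microhabitat draw (same `K`); the treated ensemble may contain a subset
#'   of the reference's species (e.g. single-species runs).
#' @param measure `"abundance"` (ensemble total, the default) or `"share"`
#'   (mean relative abundance).
#' @param unit Abundance unit: `"colonies"`, `"workers"` or `"biomass"`.
#' @return A tibble with columns `species`, `reference`, `treated`,
#'   `pct_change` (`NA` with a warning when a reference total is zero).
#' @export
percent_change <- function(reference, treated,
                           measure = c("abundance", "share"),
                           unit = c("colonies", "workers", "biomass")) {
  measure <- match.arg(measure)
  unit <- match.arg(unit)
  if (!identical(attr(reference, "K"), attr(treated, "K"))) {
    stop("ensembles were not run on the same number of microhabitats")
  }
  if (!all(unique(treated$species) %in% unique(reference$species))) {
    stop("treated ensemble contains species absent from the reference")
  }
  col <- switch(unit, colonies = "N", workers = "workers",
                biomass = "biomass")
  tot <- function(ens) {
    ens |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(total = sum(.data[[col]]), .groups = "drop")
  }
  ref <- tot(reference)
  trt <- tot(treated)
  if (measure == "share") {
    ref$total <- ref$total / sum(ref$total)
    trt$total <- trt$total / sum(trt$total)
  }
  out <- dplyr::inner_join(ref, trt, by = "species",
                           suffix = c("_ref", "_trt")) |>
    dplyr::transmute(
      species = .data$species, reference = .data$total_ref,
      treated = .data$total_trt,
      pct_change = 100 * (.data$total_trt - .data$total_ref) /
        .data$total_ref
    )
  if (any(out$reference == 0)) {
    warning("zero reference total: percent change undefined for some species")
    out$pct_change[out$reference == 0] <- NA_real_
  }
  out
}

#' The experiment grid
#'
#' Enumerates the community scenarios analysed by the pipeline: the fully
#' parameterized baseline, the five trait equalizations, phenological shifts
#' of 1-4 weeks, and uniform warming of 1-5 degrees C (15 scenarios). Each
#' can be run with the full community or with any one of the three species
#' alone (4 competition variants).
#'
#' @param expand_competition Cross the 15 scenarios with the 4 competition
#'   variants (default `FALSE`).
#' @return A tibble with columns `scenario`, `family`, `trait`, `weeks`,
#'   `delta_t` (and `competition` when expanded).
#' @export
scenario_grid <- function(expand_competition = FALSE) {
  g <- dplyr::bind_rows(
    tibble::tibble(scenario = "baseline", family = "baseline",
                   trait = NA_character_, weeks = NA_real_,
                   delta_t = NA_real_),
    tibble::tibble(
      scenario = paste0("equalize_", c("discovery", "clearance", "mass",
                                       "dominance", "thermal_niche")),
      family = "equalize",
      trait = c("discovery", "clearance", "mass", "dominance",
                "thermal_niche"),
      weeks = NA_real_, delta_t = NA_real_),
    tibble::tibble(scenario = paste0("shift_", 1:4, "w"), family = "shift",
                   trait = NA_character_, weeks = as.numeric(1:4),
                   delta_t = NA_real_),
    tibble::tibble(scenario = paste0("warm_", 1:5, "C"), family = "warm",
                   trait = NA_character_, weeks = NA_real_,
                   delta_t = as.numeric(1:5))
  )
  if (expand_competition) {
    g <- tidyr::crossing(
      g, competition = c("community", "n_faisonensis", "a_rudis",
                         "p_imparis"))
  }
  g
}

#' Scenario-adjusted phenology inputs
#'
#' Applies a climate scenario to the baseline curves: phenological shifts
#' move both the foraging and the resource curves (spring earlier, fall
#' later, re-normalized); warming rescales foraging curves through the
#' species' thermal responses while holding resource phenology at baseline.
#'
#' @param family `"baseline"`, `"shift"` or `"warm"` (trait equalizations do
#'   not alter curves and are handled by [run_ensemble()]'s `equalize`).
#' @param traits Species trait table with `foraging` list-column.
#' @param resource Baseline resource [phenology_curve()].
#' @param weeks Shift in weeks (for `family = "shift"`).
#' @param delta_t Warming in degrees C (for `family = "warm"`).
#' @param temps Baseline [temperature_series()].
#' @param responses Named list of [thermal_response()]s.
#' @return A list with the adjusted `traits` and `resource`.
#' @export
scenario_inputs <- function(family, traits, resource, weeks = NULL,
                            delta_t = NULL, temps = default_temperatures(),
                            responses = default_thermal_responses()) {
  if (family == "shift") {
    stopifnot(!is.null(weeks))
    traits$foraging <- lapply(traits$foraging, shift_phenology,
                              weeks = weeks)
    resource <- shift_phenology(resource, weeks)
  } else if (family == "warm") {
    stopifnot(!is.null(delta_t))
    traits$foraging <- purrr::map2(
      traits$foraging, responses[traits$name],
      function(curve, resp) {
        apply_warming(curve, resp, temps, delta_t)
      })
  } else if (family != "baseline") {
    stop("unknown curve-altering scenario family: ", family)
  }
  list(traits = traits, resource = resource)
}
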