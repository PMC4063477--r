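# Reporting quantities: community composition fractions, mean relative
# abundances, Pielou's evenness, and one-object summaries of ensemble runs.

#' Composition fractions of an ensemble
#'
#' Classifies each microhabitat by which species are present at equilibrium
#' and reports the fraction of microhabitats showing each of the `2^S`
#' possible presence patterns (including patterns never observed, at 0).
#'
#' @param ensemble An `ant_ensemble` tibble from [run_ensemble()].
#' @return A tibble with columns `pattern` (e.g. `"111"`, ordered by
#'   ascending dominance rank), `n_species`, `fraction`; fractions sum to 1.
#' @export
composition_fractions <- function(ensemble) {
  species <- attr(ensemble, "species")
  if (is.null(species)) species <- unique(ensemble$species)
  S <- length(species)
  pat <- ensemble |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      pattern = paste(as.integer(.data$present[match(species,
                                                     .data$species)]),
                      collapse = ""),
      .groups = "drop")
  all_patterns <- apply(expand.grid(rep(list(0:1), S))[, S:1, drop = FALSE],
                        1, paste, collapse = "")
  counts <- table(factor(pat$pattern, levels = sort(all_patterns)))
  tibble::tibble(
    pattern = names(counts),
    n_species = nchar(gsub("0", "", names(counts))),
    fraction = as.numeric(counts) / nrow(pat)
  )
}

#' Mean relative abundance across microhabitats
#'
#' The default convention is the ratio of ensemble totals,
#' `sum_k N_ik / sum_k sum_j N_jk`, which is consistent with the ensemble
#' totals used by [percent_change()]; `method = "mean_of_ratios"` instead
#' averages each microhabitat's relative-abundance vector (microhabitats
#' where every species is extinct are dropped from that average).
#'
#' @param ensemble An `ant_ensemble` tibble.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @param unit Abundance unit: `"colonies"`, `"workers"` or `"biomass"`.
#' @return A tibble with columns `species`, `mean_rel_abundance` (summing
#'   to 1 whenever any species persists anywhere).
#' @export
mean_relative_abundance <- function(ensemble,
                                    method = c("ratio_of_means",
                                               "mean_of_ratios"),
                                    unit = c("colonies", "workers",
                                             "biomass")) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  col <- switch(unit, colonies = "N", workers = "workers",
                biomass = "biomass")
  species <- attr(ensemble, "species")
  if (is.null(species)) species <- unique(ensemble$species)
  if (method == "ratio_of_means") {
    tot <- ensemble |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(total = sum(.data[[col]]), .groups = "drop")
    grand <- sum(tot$total)
    if (grand == 0) stop("all species extinct in every microhabitat")
    out <- tot |>
      dplyr::mutate(mean_rel_abundance = .data$total / grand) |>
      dplyr::select("species", "mean_rel_abundance")
  } else {
    shares <- ensemble |>
      dplyr::group_by(.data$k) |>
      dplyr::mutate(tot_k = sum(.data[[col]])) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$tot_k > 0) |>
      dplyr::mutate(share = .data[[col]] / .data$tot_k)
    if (nrow(shares) == 0) stop("all species extinct in every microhabitat")
    out <- shares |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(mean_rel_abundance = mean(.data$share),
                       .groups = "drop")
  }
  out[match(species, out$species), ]
}

#' Pielou's evenness index
#'
#' `J = H / ln(S)` with Shannon entropy `H = -sum(q_i ln q_i)` over the
#' positive entries of a relative-abundance distribution; `S` is the full
#' species count including zero entries. A one-species distribution has
#' `H = 0` and hence evenness 0; the uniform distribution has evenness 1.
#'
#' @param q Relative abundances summing to 1, length `S >= 2`.
#' @return Evenness in `[0, 1]`.
#' @export
pielou_evenness <- function(q) {
  if (length(q) < 2) stop("need at least two species categories")
  if (any(q < 0) || abs(sum(q) - 1) > 1e-8) {
    stop("`q` must be non-negative relative abundances summing to 1")
  }
  qq <- q[q > 0]
  H <- -sum(qq * log(qq))
  H / log(length(q))
}

#' Summarise an ensemble run
#'
#' Collects the reporting quantities for one scenario ensemble: composition
#' fractions over the `2^S` presence patterns, mean relative abundances,
#' and Pielou's evenness of that distribution.
#'
#' @param ensemble An `ant_ensemble` tibble.
#' @param scenario Optional scenario label carried into the summary.
#' @inheritParams mean_relative_abundance
#' @return An object of class `ant_ensemble_summary`.
#' @export
summarize_ensemble <- function(ensemble, scenario = NA_character_,
                               method = "ratio_of_means",
                               unit = "colonies") {
  comp <- composition_fractions(ensemble)
  mra <- mean_relative_abundance(ensemble, method = method, unit = unit)
  structure(list(
    scenario = scenario,
    K = attr(ensemble, "K"),
    composition = comp,
    mean_rel_abundance = mra,
    evenness = if (nrow(mra) >= 2) pielou_evenness(mra$mean_rel_abundance)
               else NA_real_,
    frac_coexist = comp$fraction[comp$n_species == length(
      attr(ensemble, "species"))],
    frac_single = sum(comp$fraction[comp$n_species == 1]),
    n_nonconverged = sum(!ensemble$converged) / max(1, length(unique(
      ensemble$species))),
    method = method, unit = unit
  ), class = "ant_ensemble_summary")
}

#' @export
print.ant_ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble summary%s: K = %d, evenness = %.3f, 3-sp = %.3f>\n",
              if (is.na(x$scenario)) "" else paste0(" ", x$scenario),
              x$K, x$evenness, x$frac_coexist))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble summary
#'
#' One row per species with its mean relative abundance, joined with the
#' fraction of microhabitats in which the species is present.
#'
#' @param x An `ant_ensemble_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ant_ensemble_summary <- function(x, ...) {
  species <- x$mean_rel_abundance$species
  pres <- vapply(seq_along(species), function(i) {
    sum(x$composition$fraction[substr(x$composition$pattern, i, i) == "1"])
  }, numeric(1))
  tibble::tibble(scenario = x$scenario,
                 species = species,
                 mean_rel_abundance = x$mean_rel_abundance$mean_rel_abundance,
                 frac_present = pres)
}

#' Glance at an ensemble summary
#'
#' @param x An `ant_ensemble_summary`.
#' @param ... Unused.
#' @return A one-row tibble with `scenario`, `K`, `evenness`,
#'   `frac_coexist`, `frac_single`, `n_nonconverged`.
#' @export
glance.ant_ensemble_summary <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, K = x$K, evenness = x$evenness,
                 frac_coexist = x$frac_coexist, frac_single = x$frac_single,
                 n_nonconverged = x$n_nonconverged)
}

#' @export
autoplot.ant_ensemble_summary <- function(object, ...) {
  df <- object$composition
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Presence pattern (ascending dominance rank)",
                  y = "Fraction of microhabitats",
                  title = object$scenario)
}
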