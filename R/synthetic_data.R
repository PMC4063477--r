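# Packaged inputs and generators: trait tables, phenology fixtures,
# baseline temperatures, thermal responses, and random curves for
# property testing. Everything needed to run the pipeline ships with the
# package as plain text.

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "antcoex")
  if (path == "") stop("missing fixture file: ", file, call. = FALSE)
  path
}

.read_curve_fixture <- function(file) {
  df <- utils::read.delim(.fixture_path(file), comment.char = "#")
  if (!all(c("day", "value") %in% names(df)) || nrow(df) == 0) {
    stop("corrupt fixture file (need day/value columns): ", file,
         call. = FALSE)
  }
  normalize_phenology(phenology_curve(df$day, df$value))
}

#' Default species trait table
#'
#' The three-species guild of ground-foraging ants from the Maryland (SERC)
#' deciduous-forest community, ordered by ascending behavioural dominance:
#' *Nylanderia faisonensis* (rank 1, most subordinate), *Aphaenogaster
#' rudis* (rank 2), *Prenolepis imparis* (rank 3, most dominant). Columns:
#' relative per-capita discovery rate `r` (N. faisonensis = 1 standard),
#' relative patch clearance rate `c`, worker mass `w` (mg), and foragers per
#' colony `a` (taken equal to reported colony sizes; the N. faisonensis
#' value is the midpoint of the reported 125-150 range). Only an upper bound
#' is reported for the P. imparis discovery rate (below the A. rudis value
#' of 2.2); the default `r3 = 1` reflects that P. imparis competes through
#' dominance and fast clearance rather than discovery, and is configurable.
#'
#' @param r3 Relative discovery rate for P. imparis (default 1).
#' @param phenology Optional list of foraging curves, as returned in the
#'   `foraging` element of [load_fixture_phenologies()]; when supplied
#'   (default), the table gains a `foraging` list-column.
#' @return A tibble with one row per species, ascending rank order.
#' @export
default_traits <- function(r3 = 1,
                           phenology = load_fixture_phenologies()$foraging) {
  tr <- tibble::tibble(
    name = c("n_faisonensis", "a_rudis", "p_imparis"),
    rank = 1:3,
    r = c(1, 2.2, r3),
    c = c(1, 6, 17),
    w = c(0.1, 1.3, 0.7),
    a = c(137.5, 300, 1200)
  )
  if (!is.null(phenology)) {
    if (!all(tr$name %in% names(phenology))) {
      stop("`phenology` must name curves for all three species")
    }
    tr$foraging <- unname(phenology[tr$name])
  }
  tr
}

#' Default microhabitat parameter ranges
#'
#' Uniform sampling ranges for the four resource parameters that define a
#' microhabitat: patch production `lambda_s` in `[0, 200]`, inverse patch
#' size `lambda_c` in `[0, 200]`, food quality `eps_prime` in `[0, 2]`, and
#' non-focal clearance `b` in `[0.1, 0.2]`.
#'
#' @return A tibble with columns `parameter`, `lo`, `hi`.
#' @export
default_ranges <- function() {
  tibble::tibble(
    parameter = c("lambda_s", "lambda_c", "eps_prime", "b"),
    lo = c(0, 0, 0, 0.1),
    hi = c(200, 200, 2, 0.2)
  )
}

#' Load the packaged phenology fixtures
#'
#' Reads the packaged seasonal curves: per-species foraging effort at the
#' first day of each month (12 knots) and resource availability at 17
#' approximately evenly spaced sampling days, all max-normalized. The
#' P. imparis curve is bimodal (spring and fall peaks with a mid-summer
#' trough); the A. rudis and N. faisonensis curves are unimodal with
#' mid-summer peaks. The fixture files are editable plain text and document
#' their own provenance.
#'
#' @return A list with `foraging` (named list of [phenology_curve()]s in
#'   ascending rank order) and `resource` (17-knot [phenology_curve()]).
#' @export
load_fixture_phenologies <- function() {
  foraging <- list(
    n_faisonensis = .read_curve_fixture("foraging_n_faisonensis.tsv"),
    a_rudis = .read_curve_fixture("foraging_a_rudis.tsv"),
    p_imparis = .read_curve_fixture("foraging_p_imparis.tsv")
  )
  resource <- .read_curve_fixture("resource_sigma.tsv")
  if (length(resource$day) != 17L) {
    stop("corrupt fixture file: resource_sigma.tsv must have 17 knots")
  }
  list(foraging = foraging, resource = resource)
}

#' Baseline monthly temperature series
#'
#' Loads the packaged synthetic 12-month mean temperature series (degrees C,
#' mid-Atlantic seasonal shape) used as the warming-scenario baseline.
#'
#' @return A [temperature_series()].
#' @export
default_temperatures <- function() {
  df <- utils::read.delim(.fixture_path("temperatures_monthly_synthetic.tsv"),
                          comment.char = "#")
  if (nrow(df) != 12L || !all(c("month", "temp_c") %in% names(df))) {
    stop("corrupt fixture file: temperatures_monthly_synthetic.tsv")
  }
  temperature_series(df$temp_c[order(df$month)])
}

#' Per-species thermal-response fixtures
#'
#' Loads the packaged synthetic Gaussian thermal performance curves used to
#' rescale foraging under uniform warming (see the fixture file for the
#' qualitative behaviour each curve encodes).
#'
#' @return Named list of [thermal_response()] objects, ascending rank order.
#' @export
default_thermal_responses <- function() {
  cfg <- yaml::read_yaml(.fixture_path("thermal_responses.yaml"))
  lapply(cfg$species, function(s) thermal_response(s$t_opt, s$breadth))
}

#' Generate a random phenology curve
#'
#' Builds a smooth annually periodic curve as a sum of circular Gaussian
#' bumps, for property tests and synthetic experiments.
#'
#' @param shape `"unimodal"` or `"bimodal"`.
#' @param peaks Peak day(s) of year: one value for unimodal, two for
#'   bimodal. Defaults: 180 and `c(90, 280)`.
#' @param widths Bump standard deviations in days, `> 0`, recycled.
#' @param baseline Constant floor added before normalization (default 0).
#' @param period Year length (default 365).
#' @return A normalized daily-grid [phenology_curve()].
#' @export
generate_random_phenology <- function(shape = c("unimodal", "bimodal"),
                                      peaks = NULL, widths = 30,
                                      baseline = 0, period = 365) {
  shape <- match.arg(shape)
  if (is.null(peaks)) peaks <- if (shape == "unimodal") 180 else c(90, 280)
  n_peaks <- if (shape == "unimodal") 1L else 2L
  if (length(peaks) != n_peaks) stop("need ", n_peaks, " peak day(s)")
  if (any(widths <= 0)) stop("widths must be positive")
  widths <- rep_len(widths, n_peaks)
  d <- seq(0, period - 1)
  val <- rep(baseline, length(d))
  for (i in seq_len(n_peaks)) {
    delta <- pmin(abs(d - peaks[i] %% period),
                  period - abs(d - peaks[i] %% period))  # circular distance
    val <- val + exp(-delta^2 / (2 * widths[i]^2))
  }
  normalize_phenology(phenology_curve(d, val, period))
}
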