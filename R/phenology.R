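# Annually periodic phenology curves: ant foraging effort f_i(t) and resource
# production sigma(t), both stored as non-negative fractions at day-of-year
# knots and evaluated everywhere else by periodic linear interpolation.

#' Construct an annually periodic phenology curve
#'
#' A phenology curve stores non-negative fractional values (foraging effort or
#' resource production, relative to the seasonal maximum) at day-of-year knots
#' and treats the year as periodic: interpolation wraps from the last knot of
#' one year to the first knot of the next. Days use a 365-day calendar with
#' day 0 = January 1.
#'
#' @param day Numeric vector of day-of-year knots, strictly increasing, all in
#'   `[0, period)`.
#' @param value Numeric vector of non-negative values at those knots.
#' @param period Length of the year in days (default 365).
#' @return An object of class `phenology_curve`.
#' @examples
#' f <- phenology_curve(c(0, 100, 200, 300), c(0.1, 1, 0.4, 0.2))
#' pheno_at(f, 50)
#' @export
phenology_curve <- function(day, value, period = 365) {
  day <- as.numeric(day)
  value <- as.numeric(value)
  if (length(day) == 0L) stop("phenology curve needs at least one knot")
  if (length(day) != length(value)) stop("`day` and `value` lengths differ")
  if (anyNA(day) || anyNA(value)) stop("phenology knots must be finite")
  if (any(value < 0)) stop("phenology values must be non-negative")
  if (any(day < 0) || any(day >= period)) {
    stop("knot days must lie in [0, period)")
  }
  if (is.unsorted(day, strictly = TRUE)) {
    stop("knot days must be strictly increasing within one period")
  }
  structure(list(day = day, value = value, period = period),
            class = "phenology_curve")
}

#' @export
print.phenology_curve <- function(x, ...) {
  cat(sprintf("<phenology_curve: %d knots, period %g d, max %.3g>\n",
              length(x$day), x$period, max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.phenology_curve <- function(x, ...) {
  data.frame(day = x$day, value = x$value)
}

#' Evaluate a phenology curve at arbitrary days
#'
#' Piecewise-linear, periodic interpolation. Queries are reduced modulo the
#' period, so any real day (including negative days) is valid; values stored
#' at knots are returned exactly.
#'
#' @param curve A [phenology_curve()].
#' @param day Numeric vector of days (any real values).
#' @return Numeric vector of interpolated values, all `>= 0`.
#' @export
pheno_at <- function(curve, day) {
  stopifnot(inherits(curve, "phenology_curve"))
  L <- curve$period
  d <- day %% L
  k <- curve$day
  v <- curve$value
  if (length(k) == 1L) return(rep(v, length(d)))
  # extend with the wrap-around knot (first knot one period later) so every
  # query in [k[1], k[1] + L) falls inside a segment
  kx <- c(k, k[1] + L)
  vx <- c(v, v[1])
  d <- ifelse(d < k[1], d + L, d)
  stats::approx(kx, vx, xout = d, method = "linear", ties = "ordered")$y
}

#' Normalize a phenology curve to unit maximum
#'
#' Divides all knot values by the curve maximum so that `max(value) == 1`,
#' the convention under which seasonal foraging effort and food production
#' are expressed as fractions of their seasonal peak.
#'
#' @param curve A [phenology_curve()] with at least one positive value.
#' @return The rescaled curve; idempotent on already-normalized curves.
#' @export
normalize_phenology <- function(curve) {
  stopifnot(inherits(curve, "phenology_curve"))
  m <- max(curve$value)
  if (m <= 0) stop("cannot normalize an all-zero phenology curve")
  phenology_curve(curve$day, curve$value / m, curve$period)
}

#' A constant (flat) phenology curve
#'
#' Used for the equalized-thermal-niche scenario, in which every species
#' forages at full effort all year round.
#'
#' @param value Constant value (default 1).
#' @param period Year length in days.
#' @return A [phenology_curve()] that evaluates to `value` everywhere.
#' @export
constant_phenology <- function(value = 1, period = 365) {
  phenology_curve(c(0, period / 2), c(value, value), period)
}

# cumulative day-of-year at the start of each month, non-leap calendar,
# day 0 = Jan 1
.month_start <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
.month_length <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Shift a phenology curve towards an "extended summer"
#'
#' Moves spring activity earlier and fall activity later, the phenological
#' signature of climate warming. For output day `d` in the spring window
#' (March 1 - July 31) the value is read from the input at `d + 7 * weeks`;
#' for `d` in the fall window (September 1 - January 31) it is read at
#' `d - 7 * weeks`. August and February act as continuity buffers in which
#' the two oppositely shifted branches are blended with linear cross-fade
#' weights, so the output is continuous. The result is evaluated on a daily
#' grid and re-normalized by default.
#'
#' @param curve A [phenology_curve()] with period 365.
#' @param weeks Integer shift in weeks; the scenario set uses 1-4. Values
#'   outside that range (including 0) require `allow_any = TRUE`.
#' @param renormalize Re-normalize the shifted curve to unit maximum
#'   (default `TRUE`).
#' @param allow_any Permit `weeks` outside 1..4 (default `FALSE`).
#' @return A daily-grid [phenology_curve()].
#' @export
shift_phenology <- function(curve, weeks, renormalize = TRUE,
                            allow_any = FALSE) {
  stopifnot(inherits(curve, "phenology_curve"))
  if (!allow_any && (weeks < 1 || weeks > 4)) {
    stop("`weeks` must be in 1..4 (set allow_any = TRUE to override)")
  }
  L <- curve$period
  d <- seq(0, L - 1)
  s <- 7 * weeks
  spring <- pheno_at(curve, d + s)   # activity pulled earlier
  fall <- pheno_at(curve, d - s)     # activity pushed later
  # window membership: spring Mar 1..Jul 31 (59..211), fall Sep 1..Jan 31
  # (243..364 and 0..30); August (212..242) fades spring -> fall, February
  # (31..58) fades fall -> spring
  val <- numeric(length(d))
  in_spring <- d >= 59 & d <= 211
  in_fall <- d >= 243 | d <= 30
  in_aug <- d >= 212 & d <= 242
  in_feb <- d >= 31 & d <= 58
  val[in_spring] <- spring[in_spring]
  val[in_fall] <- fall[in_fall]
  wa <- (d[in_aug] - 211) / (243 - 211)       # 0 at Jul 31 edge -> 1 at Sep 1
  val[in_aug] <- (1 - wa) * spring[in_aug] + wa * fall[in_aug]
  wf <- (d[in_feb] - 30) / (59 - 30)          # 0 at Jan 31 edge -> 1 at Mar 1
  val[in_feb] <- (1 - wf) * fall[in_feb] + wf * spring[in_feb]
  out <- phenology_curve(d, val, L)
  if (renormalize && max(val) > 0) out <- normalize_phenology(out)
  out
}

#' Monthly mean temperature series
#'
#' Twelve monthly mean temperatures (degrees C), interpolated to daily values
#' by placing each monthly mean at the midpoint of its month and applying
#' periodic linear interpolation, which keeps the daily series continuous
#' across the year boundary.
#'
#' @param monthly Numeric vector of 12 monthly means, January first.
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(monthly) {
  monthly <- as.numeric(monthly)
  if (length(monthly) != 12L || anyNA(monthly)) {
    stop("`monthly` must be 12 finite monthly mean temperatures")
  }
  mid <- .month_start + .month_length / 2
  structure(list(monthly = monthly,
                 curve = list(day = mid, value = monthly, period = 365)),
            class = "temperature_series")
}

#' Daily temperature from a monthly series
#'
#' @param temps A [temperature_series()].
#' @param day Numeric vector of days (any real values; reduced mod 365).
#' @return Daily mean temperatures (degrees C).
#' @export
daily_temperature <- function(temps, day) {
  stopifnot(inherits(temps, "temperature_series"))
  cv <- temps$curve
  L <- cv$period
  d <- day %% L
  kx <- c(cv$day, cv$day[1] + L)
  vx <- c(cv$value, cv$value[1])
  d <- ifelse(d < cv$day[1], d + L, d)
  stats::approx(kx, vx, xout = d, method = "linear", ties = "ordered")$y
}

#' Species thermal-response curve
#'
#' Maps temperature (degrees C) to relative foraging propensity (>= 0). The
#' default shape is a Gaussian performance curve with optimum `t_opt` and
#' breadth `breadth` (the standard deviation, in degrees C); an arbitrary
#' non-negative function of temperature may be supplied instead.
#'
#' @param t_opt Thermal optimum (degrees C).
#' @param breadth Gaussian breadth (degrees C), `> 0`.
#' @param fun Optional function of temperature replacing the Gaussian.
#' @return An object of class `thermal_response`.
#' @export
thermal_response <- function(t_opt = 20, breadth = 8, fun = NULL) {
  if (is.null(fun)) {
    stopifnot(breadth > 0)
    fun <- function(temp) exp(-((temp - t_opt)^2) / (2 * breadth^2))
  }
  structure(list(fun = fun, t_opt = t_opt, breadth = breadth),
            class = "thermal_response")
}

#' Evaluate a thermal response
#' @param response A [thermal_response()].
#' @param temp Temperatures (degrees C).
#' @return Relative foraging propensity, `>= 0`.
#' @export
thermal_at <- function(response, temp) {
  stopifnot(inherits(response, "thermal_response"))
  out <- response$fun(temp)
  if (any(out < 0)) stop("thermal response must be non-negative")
  out
}

#' Rescale a foraging curve for a uniform temperature increase
#'
#' Each day's foraging effort is multiplied by the ratio of the species'
#' thermal response at the warmed temperature to its response at the baseline
#' temperature, then clipped to `[0, 1]` (a species cannot exceed its maximal
#' observed effort). Where the baseline response is numerically zero
#' (`< 1e-6`) the warmed response is used directly as an absolute propensity,
#' which keeps behaviour smooth at the edges of the foraging season. The
#' result is deliberately not re-normalized, so warming can redistribute and
#' suppress (or recover) total seasonal effort.
#'
#' @param curve Baseline foraging [phenology_curve()].
#' @param response The species' [thermal_response()].
#' @param temps Baseline [temperature_series()].
#' @param delta_t Uniform warming in degrees C, `>= 0` (scenario set: 1-5).
#' @return A daily-grid [phenology_curve()], not re-normalized.
#' @export
apply_warming <- function(curve, response, temps, delta_t) {
  stopifnot(inherits(curve, "phenology_curve"))
  if (delta_t < 0) stop("`delta_t` must be non-negative")
  L <- curve$period
  d <- seq(0, L - 1)
  base_t <- daily_temperature(temps, d)
  v <- pheno_at(curve, d)
  r0 <- thermal_at(response, base_t)
  r1 <- thermal_at(response, base_t + delta_t)
  scaled <- ifelse(r0 < 1e-6, r1, v * r1 / r0)
  phenology_curve(d, pmin(pmax(scaled, 0), 1), L)
}

#' Add seasonal food supplementation to a resource curve
#'
#' Increments the knot values of a resource phenology curve by the given
#' non-negative supplement, one value per knot. The supplemented curve is an
#' absolute addition to availability and is not re-normalized; linear
#' interpolation between knots applies as usual.
#'
#' @param curve Resource [phenology_curve()] (canonically 17 knots).
#' @param supplement Non-negative numeric vector, one entry per knot.
#' @return The supplemented [phenology_curve()].
#' @export
supplement_resource <- function(curve, supplement) {
  stopifnot(inherits(curve, "phenology_curve"))
  supplement <- as.numeric(supplement)
  if (length(supplement) != length(curve$day)) {
    stop("`supplement` must have one entry per resource knot")
  }
  if (any(supplement < 0) || anyNA(supplement)) {
    stop("supplement entries must be non-negative")
  }
  phenology_curve(curve$day, curve$value + supplement, curve$period)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.phenology_curve <- function(object, ...) {
  d <- seq(0, object$period - 1)
  df <- data.frame(day = d, value = pheno_at(object, d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of year", y = "Fraction of seasonal maximum") +
    ggplot2::ylim(0, NA)
}
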