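test_that("interpolation is exact at knots, linear between, and periodic", {
  f <- phenology_curve(c(0, 100, 200), c(0.3, 1, 0.5))
  expect_identical(pheno_at(f, c(0, 100, 200)), c(0.3, 1, 0.5))
  expect_equal(pheno_at(phenology_curve(c(0, 100), c(0, 1)), 50), 0.5)
  # wrap-around segment: knots (10 -> 0.6, 350 -> 0.2), the segment from day
  # 350 to day 375 (= 10 + 365) runs 0.2 -> 0.6; at day 0 (= 365) the value
  # is 0.2 + 15/25 * 0.4 = 0.44
  g <- phenology_curve(c(10, 350), c(0.6, 0.2))
  expect_equal(pheno_at(g, 0), 0.44)
  expect_equal(pheno_at(g, 365 + 10), 0.6)  # periodic reduction
  expect_equal(pheno_at(g, -355), 0.6)
})

test_that("interpolated values are bounded by the neighbouring knot values", {
  set.seed(5)
  for (i in 1:20) {
    kn <- sort(sample(0:364, 6))
    vals <- runif(6)
    f <- phenology_curve(kn, vals)
    q <- runif(50, 0, 365)
    expect_true(all(pheno_at(f, q) >= min(vals) - 1e-12))
    expect_true(all(pheno_at(f, q) <= max(vals) + 1e-12))
  }
})

test_that("curve construction rejects invalid knots", {
  expect_error(phenology_curve(numeric(0), numeric(0)), "at least one knot")
  expect_error(phenology_curve(c(0, 10), c(-1, 1)), "non-negative")
  expect_error(phenology_curve(c(10, 10), c(1, 1)), "strictly increasing")
  expect_error(phenology_curve(c(0, 400), c(1, 1)), "period")
})

test_that("normalization scales to unit max, is idempotent, rejects zeros", {
  f <- phenology_curve(c(0, 100, 200), c(2, 4, 1))
  expect_equal(normalize_phenology(f)$value, c(0.5, 1, 0.25))
  expect_equal(normalize_phenology(normalize_phenology(f))$value,
               normalize_phenology(f)$value)
  expect_error(normalize_phenology(phenology_curve(c(0, 10), c(0, 0))),
               "all-zero")
  set.seed(9)
  for (i in 1:20) {
    g <- phenology_curve(sort(sample(0:364, 5)), runif(5, 0.01, 10))
    expect_equal(max(normalize_phenology(g)$value), 1)
  }
})

test_that("phenological shifts move spring earlier and fall later", {
  # delta-like spike at April 1 (day 90) lands 14 days earlier at weeks = 2
  spike <- phenology_curve(c(0, 89, 90, 91, 200), c(0, 0, 1, 0, 0))
  sh <- shift_phenology(spike, weeks = 2)
  expect_equal(which.max(pheno_at(sh, 0:364)) - 1, 76)
  # spike at October 15 (day 287) lands 14 days later
  spike_f <- phenology_curve(c(0, 286, 287, 288), c(0, 0, 1, 0))
  sh_f <- shift_phenology(spike_f, weeks = 2)
  expect_equal(which.max(pheno_at(sh_f, 0:364)) - 1, 301)
})

test_that("shift edge cases: identity at weeks = 0, constants unchanged", {
  f <- generate_random_phenology("bimodal", peaks = c(95, 280), widths = 25)
  sh0 <- shift_phenology(f, weeks = 0, allow_any = TRUE)
  expect_equal(pheno_at(sh0, 0:364), pheno_at(f, 0:364), tolerance = 1e-12)
  cst <- constant_phenology(1)
  for (w in c(1, 4)) {
    expect_equal(pheno_at(shift_phenology(cst, w), 0:364), rep(1, 365))
  }
  expect_error(shift_phenology(f, weeks = 5), "1..4")
  expect_error(shift_phenology(f, weeks = 0), "1..4")
})

test_that("shifting changes the annual integral only by the extension", {
  # moving spring activity earlier and fall activity later duplicates up to
  # shift + buffer days of mid-summer values (the "extended summer"), so the
  # annual integral may grow by at most that window at the curve maximum --
  # and for summer-peaked curves (like the resource) it must not shrink
  phen <- load_fixture_phenologies()
  for (curve in c(phen$foraging, list(phen$resource))) {
    base_int <- sum(pheno_at(curve, 0:364))
    deltas <- vapply(1:4, function(w) {
      sh <- shift_phenology(curve, w, renormalize = FALSE)
      sum(pheno_at(sh, 0:364)) - base_int
    }, numeric(1))
    for (w in 1:4) {
      expect_lt(abs(deltas[w]), 2 * (7 * w + 31) * max(curve$value))
    }
    # longer shifts perturb the integral more
    expect_true(all(diff(abs(deltas)) > 0))
  }
  # extended summers increase total food availability
  sig_d <- vapply(1:4, function(w) {
    sum(pheno_at(shift_phenology(phen$resource, w, renormalize = FALSE),
                 0:364))
  }, numeric(1))
  expect_true(all(sig_d > sum(pheno_at(phen$resource, 0:364))))
})

test_that("warming rescaling: identity cases and directional response", {
  temps <- default_temperatures()
  resp <- thermal_response(t_opt = 20, breadth = 8)
  f <- generate_random_phenology("unimodal", peaks = 180, widths = 50)
  w0 <- apply_warming(f, resp, temps, delta_t = 0)
  expect_equal(pheno_at(w0, 0:364), pheno_at(f, 0:364), tolerance = 1e-12)
  flat <- thermal_response(fun = function(temp) rep(0.7, length(temp)))
  wf <- apply_warming(f, flat, temps, delta_t = 3)
  expect_equal(pheno_at(wf, 0:364), pheno_at(f, 0:364), tolerance = 1e-12)
  # summer baseline is already above the 20 C optimum, so warming must
  # depress mid-summer foraging
  w3 <- apply_warming(f, resp, temps, delta_t = 3)
  july <- 181:211
  expect_true(all(pheno_at(w3, july) < pheno_at(f, july)))
  expect_true(all(pheno_at(w3, 0:364) <= 1))
  expect_error(apply_warming(f, resp, temps, delta_t = -1), "non-negative")
})

test_that("resource supplementation adds at knots and is local", {
  phen <- load_fixture_phenologies()
  sig <- phen$resource
  n <- length(sig$day)
  expect_equal(supplement_resource(sig, rep(0, n))$value, sig$value)
  expect_equal(supplement_resource(sig, rep(0.1, n))$value, sig$value + 0.1)
  expect_error(supplement_resource(sig, rep(-0.1, n)), "non-negative")
  expect_error(supplement_resource(sig, rep(0.1, n - 1)), "one entry per")
  # supplementing one knot only changes the two adjacent segments
  supp <- rep(0, n); supp[8] <- 0.5
  s1 <- supplement_resource(sig, supp)
  d <- 0:364
  changed <- abs(pheno_at(s1, d) - pheno_at(sig, d)) > 1e-12
  expect_true(all(d[changed] > sig$day[7] & d[changed] < sig$day[9]))
})

test_that("daily temperature interpolation is periodic and continuous", {
  temps <- temperature_series(c(2, 3, 8, 13, 19, 23, 26, 25, 21, 15, 9, 4))
  d <- seq(0, 365, by = 0.25)
  v <- daily_temperature(temps, d)
  expect_equal(v[1], v[length(v)])              # wraps at the year boundary
  expect_lt(max(abs(diff(v))), 0.2)             # no jumps on a 6-hour grid
  expect_error(temperature_series(1:5), "12")
})
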