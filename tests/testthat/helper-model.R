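# Shared builders and oracles for the test suite.

# three identical species (useful for symmetry checks)
identical_traits <- function(flat = TRUE) {
  curve <- if (flat) constant_phenology(1) else
    generate_random_phenology("unimodal", peaks = 180, widths = 60)
  tibble::tibble(
    name = c("sp1", "sp2", "sp3"), rank = 1:3,
    r = 1, c = 2, w = 0.5, a = 100,
    foraging = replicate(3, curve, simplify = FALSE)
  )
}

random_microhabitat <- function() {
  rg <- default_ranges()
  vals <- stats::runif(4, rg$lo, rg$hi)
  microhabitat(vals[1], vals[2], vals[3], vals[4])
}

# independent oracle: integrate the patch ODEs to (near) steady state
integrate_patch_ode <- function(D, mh, W, c_rel, sigma_day, p0_init = NULL,
                                p_init = NULL, t_end = NULL) {
  testthat::skip_if_not_installed("deSolve")
  S <- length(D)
  if (is.null(p0_init)) p0_init <- 1
  if (is.null(p_init)) p_init <- rep(1, S)
  if (is.null(t_end)) t_end <- 50 / mh$b
  rhs <- function(t, state, parms) {
    out <- patch_ode_rhs(state[1], state[-1], D, mh, W, c_rel, sigma_day)
    list(c(out$dp0, out$dp))
  }
  sol <- deSolve::ode(y = c(p0_init, p_init), times = c(0, t_end),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  st <- sol[nrow(sol), -1]
  list(p0 = unname(st[1]), p = unname(st[-1]))
}

# independent oracle: scalar fixed point of the single-species annual map
single_species_root <- function(traits1, mh, sigma,
                                config = dynamics_config()) {
  g <- function(N) {
    annual_yield(N, traits1, mh, sigma, config = config)[1] / config$L - N
  }
  hi <- 1
  while (g(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (g(1e-12) <= 0) return(0)
  stats::uniroot(g, c(1e-12, hi), tol = 1e-12)$root
}

# heavy shared ensembles for the acceptance-style checks, computed once per
# test run
.ens_cache <- new.env(parent = emptyenv())
cached <- function(name, fn) {
  if (!exists(name, envir = .ens_cache)) assign(name, fn(), envir = .ens_cache)
  get(name, envir = .ens_cache)
}

acc_K <- 2000
acc_seed <- 101

acc_microhabitats <- function() {
  cached("mhs", function() sample_microhabitats(acc_K, seed = acc_seed))
}

acc_phen <- function() cached("phen", load_fixture_phenologies)

acc_ensemble <- function(name) {
  mhs <- acc_microhabitats()
  phen <- acc_phen()
  tr <- default_traits(phenology = phen$foraging)
  cached(name, function() {
    if (name == "baseline") {
      run_ensemble(mhs, tr, phen$resource)
    } else if (grepl("^equalize_", name)) {
      run_ensemble(mhs, tr, phen$resource,
                   equalize = sub("equalize_", "", name), seed = acc_seed + 1)
    } else if (grepl("^shift", name)) {
      w <- as.integer(sub("shift", "", name))
      si <- scenario_inputs("shift", tr, phen$resource, weeks = w)
      run_ensemble(mhs, si$traits, si$resource)
    } else if (grepl("^single_ar_shift", name)) {
      w <- as.integer(sub("single_ar_shift", "", name))
      si <- scenario_inputs("shift", tr, phen$resource, weeks = w)
      run_single_species(mhs, si$traits, si$resource, "a_rudis")
    } else if (name == "single_ar_baseline") {
      run_single_species(mhs, tr, phen$resource, "a_rudis")
    } else {
      stop("unknown cached ensemble: ", name)
    }
  })
}
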