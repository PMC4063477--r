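test_that("microhabitat sampling: determinism, ranges, and uniform means", {
  rg <- default_ranges()
  a <- sample_microhabitats(50, rg, seed = 7)
  b <- sample_microhabitats(50, rg, seed = 7)
  expect_identical(a, b)
  deg <- rg; deg$lo <- c(5, 5, 1, 0.15); deg$hi <- deg$lo
  one <- sample_microhabitats(1, deg, seed = 1)
  expect_equal(unlist(one[1, -1], use.names = FALSE), deg$lo)
  bad <- rg; bad$hi[1] <- -1
  expect_error(sample_microhabitats(10, bad), "inverted")
  big <- sample_microhabitats(10000, rg, seed = 2)
  for (j in seq_len(nrow(rg))) {
    x <- big[[rg$parameter[j]]]
    expect_gte(min(x), rg$lo[j]); expect_lte(max(x), rg$hi[j])
    se <- (rg$hi[j] - rg$lo[j]) / sqrt(12 * 10000)
    expect_lt(abs(mean(x) - (rg$lo[j] + rg$hi[j]) / 2), 3 * se)
  }
})

test_that("trait equalization replaces exactly one axis of variation", {
  phen <- load_fixture_phenologies()
  tr <- default_traits(phenology = phen$foraging)
  th <- equalize_trait(tr, "thermal_niche")
  expect_true(all(vapply(th$traits$foraging, function(f) {
    all(pheno_at(f, 0:364) == 1)
  }, logical(1))))
  expect_identical(th$traits$r, tr$r)
  set.seed(3)
  for (i in 1:20) {
    m <- equalize_trait(tr, "mass")
    expect_equal(length(unique(m$traits$w)), 1L)
    expect_gte(m$traits$w[1], 0.1); expect_lte(m$traits$w[1], 1.3)
  }
  d <- equalize_trait(tr, "dominance")
  expect_equal(d$w_mode, "equal")
  expect_identical(d$traits$w, tr$w)
  expect_error(equalize_trait(tr, "speed"), "arg")
})

test_that("an ensemble row reproduces a direct equilibrium call", {
  phen <- load_fixture_phenologies()
  tr <- default_traits(phenology = phen$foraging)
  mhs <- sample_microhabitats(1, seed = 5)
  ens <- run_ensemble(mhs, tr, phen$resource)
  direct <- iterate_to_equilibrium(
    tr, microhabitat(mhs$lambda_s, mhs$lambda_c, mhs$eps_prime, mhs$b),
    phen$resource)
  expect_equal(ens$N, direct$N)
  expect_equal(ens$present, direct$present)
  expect_equal(ens$workers, tr$a * direct$N)
  expect_equal(ens$biomass, tr$w * tr$a * direct$N)
})

test_that("scenarios at the same seed share the microhabitat stream", {
  m1 <- sample_microhabitats(200, seed = 99)
  m2 <- sample_microhabitats(200, seed = 99)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("a species alone never does worse than in the community", {
  phen <- load_fixture_phenologies()
  tr <- default_traits(phenology = phen$foraging)
  mhs <- sample_microhabitats(25, seed = 13)
  full <- run_ensemble(mhs, tr, phen$resource)
  for (sp in tr$name) {
    alone <- run_single_species(mhs, tr, phen$resource, sp)
    joint <- full$N[full$species == sp]
    expect_true(all(alone$N >= joint - 1e-6 * pmax(alone$N, 1e-9)))
  }
  # a species that cannot forage is extinct even alone
  tr0 <- tr
  tr0$foraging[[1]] <- phenology_curve(c(0, 100), c(0, 0))
  dead <- run_single_species(mhs[1:3, ], tr0, phen$resource, "n_faisonensis")
  expect_true(all(dead$N == 0))
})

test_that("percent change aggregates ensemble totals", {
  phen <- load_fixture_phenologies()
  tr <- default_traits(phenology = phen$foraging)
  mhs <- sample_microhabitats(4, seed = 21)
  ens <- run_ensemble(mhs, tr, phen$resource)
  expect_equal(percent_change(ens, ens)$pct_change, c(0, 0, 0))
  scaled <- ens
  scaled$N <- 1.5 * ens$N
  scaled$workers <- 1.5 * ens$workers
  scaled$biomass <- 1.5 * ens$biomass
  expect_equal(percent_change(ens, scaled)$pct_change, c(50, 50, 50))
  # doubling one species in half the microhabitats: hand-computed aggregate
  half <- ens
  sel <- half$species == "a_rudis" & half$k <= 2
  half$N[sel] <- 2 * half$N[sel]
  tot_ref <- sum(ens$N[ens$species == "a_rudis"])
  tot_trt <- sum(half$N[half$species == "a_rudis"])
  pc <- percent_change(ens, half)
  expect_equal(pc$pct_change[pc$species == "a_rudis"],
               100 * (tot_trt - tot_ref) / tot_ref)
  bad <- ens
  attr(bad, "K") <- 5
  expect_error(percent_change(ens, bad), "same number")
})

test_that("the scenario grid enumerates the experiment set", {
  g <- scenario_grid()
  expect_equal(nrow(g), 15)
  expect_equal(sum(g$family == "baseline"), 1)
  expect_equal(sum(g$family == "equalize"), 5)
  expect_equal(sort(g$weeks[g$family == "shift"]), 1:4)
  expect_equal(sort(g$delta_t[g$family == "warm"]), 1:5)
  expect_identical(g, scenario_grid())
  expect_equal(nrow(scenario_grid(expand_competition = TRUE)), 60)
})

test_that("scenario inputs transform the right curves", {
  phen <- load_fixture_phenologies()
  tr <- default_traits(phenology = phen$foraging)
  sh <- scenario_inputs("shift", tr, phen$resource, weeks = 2)
  expect_false(isTRUE(all.equal(pheno_at(sh$resource, 0:364),
                                pheno_at(phen$resource, 0:364))))
  wa <- scenario_inputs("warm", tr, phen$resource, delta_t = 3)
  expect_identical(wa$resource, phen$resource)  # resources stay at baseline
  expect_false(isTRUE(all.equal(pheno_at(wa$traits$foraging[[2]], 0:364),
                                pheno_at(tr$foraging[[2]], 0:364))))
  expect_error(scenario_inputs("cooling", tr, phen$resource), "unknown")
})

test_that("headline summaries respond smoothly to the P. imparis discovery
           rate", {
  phen <- load_fixture_phenologies()
  mhs <- sample_microhabitats(60, seed = 31)
  ev <- vapply(c(0.5, 1, 2), function(r3) {
    tr <- default_traits(r3 = r3, phenology = phen$foraging)
    ens <- run_ensemble(mhs, tr, phen$resource)
    pielou_evenness(
      mean_relative_abundance(ens, unit = "biomass")$mean_rel_abundance)
  }, numeric(1))
  expect_true(all(is.finite(ev)))
  expect_true(all(ev > 0 & ev <= 1))
  # a faster-discovering dominant cannot make the community less even here
  expect_lt(max(abs(diff(ev))), 0.5)
})
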