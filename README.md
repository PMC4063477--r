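# antcoex

Mechanistic coexistence modelling for a three-species guild of
ground-foraging ants — *Nylanderia faisonensis*, *Aphaenogaster rudis*, and
*Prenolepis imparis* ("the winter ant") — common in Eastern North American
deciduous forests, and simulation of how that community restructures under
climate change. The package is aimed at community ecologists who want a
worked, fully tested example of a temperature-dependent, hybrid dynamical
competition model driven entirely by printed trait parameters and packaged
(editable) phenology inputs.

## The model

Species compete for discrete food patches. With $N_i$ colonies per unit
area, $a_i$ foragers per colony, relative discovery rate $r_i$ and seasonal
foraging effort $f_i(t)$, species $i$ attacks patches at rate
$D_i = \lambda_r r_i a_i N_i f_i(t)$. Patches appear at rate
$\lambda_s\sigma(t)$, are cleared by their holder at rate $\lambda_c c_i$,
removed by non-focal species at rate $b$, and change hands along a strict
behavioural dominance hierarchy (win matrix $W$):

$$\dot p_0 = \lambda_s\sigma - p_0\textstyle\sum_j D_j - b p_0, \qquad
\dot p_i = D_i\big(p_0 + \textstyle\sum_{j\ne i} W_{ij}p_j\big)
 - p_i\textstyle\sum_{j\ne i} W_{ji}D_j - (\lambda_c c_i + b)p_i.$$

Patch dynamics are fast relative to the seasons, so occupancy is solved at
quasi-steady state once per day (a triangular or dense linear solve).
Between years, colony densities follow a discrete update
$N_i \leftarrow N_i + \mu(B_i - L N_i)$ with yearly birth potential
$B_i = \varepsilon'\lambda_c c_i/(w_i a_i)\sum_d p_i^*(d)$, iterated to
equilibrium. The four resource parameters
($\lambda_s, \lambda_c, \varepsilon', b$) define a "microhabitat" and are
sampled uniformly; all reported quantities are ensemble summaries over
thousands of microhabitats (composition fractions, mean relative
abundances, Pielou's evenness, percent changes between scenarios run on
common random draws).

Scenarios: equalization of each single trait (discovery, clearance, mass,
dominance, thermal niche), phenological shifts of 1–4 weeks (spring
earlier, fall later), uniform warming of 1–5 °C through per-species thermal
performance curves, single-species (no-competition) contrasts, and a Latin
hypercube + partial-rank-correlation (PRCC) analysis of seasonal food
supplementation. See the methods vignette
(`vignettes/ant-coexistence-model.Rmd`) for assumptions, parameter
meanings, and design decisions.

## A worked example

```r
library(antcoex)

phen   <- load_fixture_phenologies()
traits <- default_traits(phenology = phen$foraging)
mhs    <- sample_microhabitats(500, seed = 11)

baseline <- run_ensemble(mhs, traits, phen$resource)
thermal  <- run_ensemble(mhs, traits, phen$resource,
                         equalize = "thermal_niche", seed = 12)

glance(summarize_ensemble(baseline, "baseline", unit = "biomass"))
#> # A tibble: 1 x 6
#>   scenario     K evenness frac_coexist frac_single n_nonconverged
#>   <chr>    <int>    <dbl>        <dbl>       <dbl>          <dbl>
#> 1 baseline   500    0.960        0.314        0.05              1

glance(summarize_ensemble(thermal, "thermal_niche", unit = "biomass"))
#> # A tibble: 1 x 6
#>   scenario          K evenness frac_coexist frac_single n_nonconverged
#>   <chr>         <int>    <dbl>        <dbl>       <dbl>          <dbl>
#> 1 thermal_niche   500    0.899        0.044         0.6              1

percent_change(baseline, thermal, measure = "share", unit = "biomass")
#> # A tibble: 3 x 4
#>   species       reference treated pct_change
#>   <chr>             <dbl>   <dbl>      <dbl>
#> 1 a_rudis           0.284   0.149      -47.8
#> 2 n_faisonensis     0.473   0.524       10.7
#> 3 p_imparis         0.242   0.328       35.1
```

Reading: with the full trait set, all three species coexist in 31% of
microhabitats and the community biomass distribution is nearly even
(Pielou's J = 0.96). Removing thermal-niche differences (every species
forages year-round) collapses *local* coexistence — 60% of microhabitats
end up with a single species and only 4% keep all three — while the winter
ant, freed from its cool-season restriction, gains 35% in relative
abundance at *A. rudis*' expense. Coexistence shifts from within
microhabitats to across them.

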