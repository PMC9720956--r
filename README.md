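# dsbr — multiscale kinetics of DNA double-strand-break repair in yeast

Gene-editing assays in *S. cerevisiae* can report successful double-strand-break
repair (DSBR) through reconstitution of a bipartite GFP gene: an endonuclease
(Cas9 or Cpf1) cuts inside a microsatellite separating the two overlapping GFP
halves, and successful single-strand annealing reassembles a functional gene.
The repair dynamics are observed at two very different scales: population-level
molecular time courses (Southern-blot band fractions of uncut, cut and repaired
chromosomes every 2 h after induction) and single-lineage microwell time-lapses
(one founder cell per 100-µm well, cell counts and GFP+ counts every 20 min for
24 h). `dsbr` is a toolbox for analysing, simulating and linking these scales.
It is aimed at quantitative biologists who want to turn such measurements into
break and repair *rates*, and to ask whether the single-lineage statistics are
consistent with those rates.

## The model

Cells occupy three states: **modified** (intact cassette, count *m*),
**broken** (cut chromosome, checkpoint-arrested and non-dividing, count *b*)
and **repaired** (reassembled GFP gene, count *g*). With division rate α,
break rate β and repair rate ρ (all per hour), the expected counts obey the
linear system

    dm/dt = (α − β) m
    db/dt = β m − ρ b
    dg/dt = α g + ρ b

frozen during a post-induction lag τ (no growth, breakage or repair while the
cells switch metabolism to galactose). Two observation-layer constants
complete the forward model: a delay γ (default 3 h) between completed repair
and detectable fluorescence, and a Gaussian measurement noise σ on observed
band fractions. The same process, read as a continuous-time Markov jump
process with per-capita event rates (broken cells never divide), is simulated
exactly with the Gillespie algorithm to produce per-well lineage trajectories.

Parameters (α, β, ρ, τ, σ) are inferred from fraction time courses by MCMC
with independent, weakly informative gamma priors parameterised by mean and
coefficient of variation: α ~ (ln2/3 h⁻¹, CV 1), β and ρ ~ (ln2/6 h⁻¹, CV 2)
(identical, so that neither breakage nor repair is presumed rate-limiting),
τ ~ (4 h, CV 0.1), σ ~ (ln2/3, CV 2).

## Worked example

Simulate a molecular time course at known kinetics, refit it, then simulate
and classify a matching microwell experiment:

```r
library(dsbr)

truth <- repair_params(alpha = 0.23, beta = 0.12, rho = 0.40,
                       tau = 4, sigma = 0.05)
blot <- sim_southern(truth, seed = 1)   # 7 time points, 0-12 h every 2 h

fit <- fit_repair_model(blot, n_chains = 4, n_draws = 10000, seed = 1)
summary(fit)
#> Posterior summary (mean, sd, median, central 95% interval):
#>  parameter    mean      sd  median    q2.5   q97.5  rhat   ess
#>      alpha 0.27570 0.22320 0.21980 0.01491 0.82700 1.005 623.9
#>       beta 0.11340 0.03210 0.10760 0.06830 0.20190 1.004 422.8
#>        rho 0.34230 0.10320 0.33180 0.17940 0.57730 1.005 676.3
#>        tau 3.87100 0.30490 3.87700 3.27500 4.49000 1.005 685.4
#>      sigma 0.05303 0.01183 0.05089 0.03556 0.08062 1.007 867.5
#> converged: TRUE; mean acceptance rate 0.18
```

The 95% credible intervals cover the generating β = 0.12, ρ = 0.40 and
τ = 4 h, and the posteriors of β and ρ are much narrower than their priors
(prior SD 0.231 for both). α is poorly determined — fractions carry no
absolute-number information — which is expected and harmless for the
downstream questions. `plot(fit)` overlays posterior model curves on the
data; `predict(fit)`, `residuals(fit)` and `simulate(fit)` give posterior
predictive curves, fit residuals and replicate datasets.

```r
pre <- condition_preset("high_efficacy")         # beta 0.15, rho 0.5
wells <- sim_wells(pre$params, p_escape = pre$p_escape, seed = 1)
wells
#> Microwell ensemble: 108 wells, 73 frames (0-24 h)

classify_condition(wells)
#> Repair-behaviour classification: high_efficacy_error_free
#>   median delay 4.33 h | final R_global 0.566 | growth ratio 0.79 |
#>   non-monotone 0.16 | GFP+ wells 76
```

A median 4.3 h between a well's first division and its first GFP+ cell, with
57% of all pooled cells GFP+ at 24 h, is the signature of early, efficient,
error-free repair; 32 of 108 wells never fluoresce (the escaper peak at
`r_local = 0`). `global_fraction()`, `delay_distribution()`,
`final_fraction_histogram()` and `heatmap_matrix()` expose the individual
statistics behind the classification.

A thin command-line pipeline wraps the same functions
(`simulate-southern`, `fit`, `simulate-wells`, `analyze-wells`, `classify`,
`recover`, `report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dsbr.R", package = "dsbr"))')" \
    simulate-southern --preset NR_Cas9 --seed 1 --out fractions.csv
```

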