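# palaeomix

Multi-proxy Bayesian inference of diet and residential mobility from the
stable isotope chemistry of archaeological bone and tooth samples.

Bioarchaeologists routinely measure δ¹³C and δ¹⁵N in bone collagen, and
δ¹³C and δ¹⁸O in bone/enamel bioapatite carbonate, across the humans and
fauna of a cemetery. Turning those numbers into statements about diet
("C₃ cereals dominated calories; marine fish was a minor, high-status
food") and mobility ("five individuals grew up in a colder, higher
region") requires a chain of statistical machinery that is usually
scattered across ad-hoc scripts. palaeomix packages that chain as tested,
seeded, configurable stages:

1. **Collagen quality control** — atomic C/N screening (2.9–3.6 window),
   collagen-yield floor, and propagation of collagen failure to the
   sample's carbonate values; group summaries and Mann–Whitney U
   comparisons (min(U₁,U₂) convention, exact null when tie-free).
2. **Oxygen conversion** — the three-step affine chain
   δ¹⁸O carbonate (VPDB) → carbonate (VSMOW) → phosphate → drinking water
   (δ¹⁸O_VSMOW = 1.03092·δ¹⁸O_VPDB + 30.92;
   δ¹⁸O_p = 1.0322·δ¹⁸O_c − 9.6849; δ¹⁸O_w = 1.55·δ¹⁸O_p − 33.49), with a
   conservative 2‰ uncertainty per individual and an exact algebraic
   inverse.
3. **Bayesian dietary mixing** (FRUITS-style) — caloric contributions α
   on the simplex, concentration-dependent mixing within protein/energy
   macronutrient fractions, routing into tissue proxies, diet-to-tissue
   offsets, inequality priors (e.g. α_C3 ≥ 0.3), latent source/offset
   uncertainty, compiled random-walk Metropolis sampler with R-hat/ESS
   diagnostics:

   pred_i = Δ_i + Σ_f r_if · (Σ_k α_k c_kf s_kfi) / (Σ_k α_k c_kf)

4. **Mixture clustering** — 2-D Gaussian mixtures on (δ¹³C, δ¹⁵N) fit by
   EM with BIC model selection across covariance families, and trimmed
   1-D clustering of water δ¹⁸O (classification EM with a 5% trimming
   concentration step) that flags outliers.
5. **Isoscape & residence assignment** — Gaussian-process smoothing
   (Matérn-5/2, per-point noise, marginal-likelihood hyperparameters) of
   a water-δ¹⁸O point table into a gridded baseline, and per-cell
   Gaussian assignment probabilities normalized into a residence map.
6. **Synthetic-data generators** — seeded, ground-truth-emitting
   simulators of the whole assemblage structure (dietary mixing lines,
   resident/migrant water mixture with planted outliers, QC failures,
   isoscape fields), so every stage is testable without downloads.
7. **Pipeline orchestration** — `run_pipeline()` drives all stages from
   one YAML/JSON config and writes a manifest with seeds and file
   digests; `inst/cli/palaeomix.R` is a thin command-line wrapper.

## Worked example

Trimmed clustering of converted water values from a simulated assemblage
(57 residents at −7.7 ± 0.8‰, 5 migrants at −12.9 ± 0.9‰, 4 planted
extreme values), then a constrained dietary model:

```r
library(palaeomix)

spec  <- population_spec(seed = 1)
mob   <- generate_mobility(spec, n = 66, seed = 1)
water <- carbonate_vpdb_to_water(mob$d18O_carb_vpdb)$value
sol   <- fit_trimmed_1d(water, k = 2, trim_fraction = 0.05,
                        restarts = 20, seed = 1)
print(sol)
#> Cluster solution: k = 2 (free_var), n_outliers = 4
#> means: -12.58, -7.6

table(sol$assignments, useNA = "ifany")
#>    1    2 <NA>
#>    5   57    4
```

The two fitted components sit at −12.6‰ and −7.6‰ — the planted migrant
and resident means — with cluster sizes 5 and 57, and the four planted
extremes are set aside as outliers (`NA` assignments). A dietary model
for a consumer group with collagen δ¹³C −18.8 ± 0.5‰, δ¹⁵N 9.9 ± 0.9‰,
carbonate δ¹³C −12.4 ± 1.3‰, under a prior that C₃ plants provide at
least 30% of calories:

```r
pr <- build_problem(default_sources(),
                    default_proxies(d13C_coll = c(-18.8, 0.5),
                                    d15N      = c(9.9, 0.9),
                                    d13C_carb = c(-12.4, 1.3)),
                    list(mixing_constraint(c("C3 plants" = 1), 0.3)))
post <- sample_posterior(pr, chains = 4, iter = 25000, thin = 5, seed = 1)
print(post)
#> Dietary posterior: 10000 draws x 7 sources (max R-hat 1.026)
#>        source   mean ci95_low ci68_low median ci68_high ci95_high
#> 1   C3 plants 0.5504 0.315650  0.40071 0.5543    0.6917    0.7865
#> 2  C4 cereals 0.0757 0.003353  0.02249 0.0673    0.1300    0.1926
#> 3      cattle 0.0934 0.002766  0.01733 0.0684    0.1719    0.3189
#> 4   ovicaprid 0.1010 0.002548  0.01898 0.0722    0.1887    0.3452
#> 5         pig 0.0957 0.002663  0.01714 0.0676    0.1796    0.3352
#> 6     poultry 0.0686 0.001776  0.01219 0.0480    0.1258    0.2513
#> 7 marine fish 0.0152 0.000673  0.00304 0.0111    0.0275    0.0535
```

C₃ plants dominate calories (posterior mean 55%, 95% CI 32–79%), animal
products contribute moderately with wide overlapping intervals, and
marine fish is small but non-zero — the characteristic resolution of
group-level isotope mixing. `summarize_posterior()` additionally reports
the protein-vs-energy caloric split.

The full pipeline, from simulation through residence maps:

```r
man <- run_pipeline(default_config(seed = 1), outdir = "run1")
```

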