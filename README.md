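# wolfpva

Individual-based demographic–genetic population viability analysis (PVA) for
a reintroduced social carnivore descended from a small captive founder
group, modeled on the Mexican wolf recovery program. The package is for
conservation scientists who want to understand *why* two PVAs built from
similar data can support very different recovery criteria: it simulates the
wild and captive populations under two packaged parameterizations
("2013"-style and "2017"-style), partitions the contrast between their
outputs into biological, policy and mixed sources, and maps extinction risk
and genetic-diversity retention over the two management levers (population
cap, releases from captivity).

## The models

**Simulator.** An annual cycle for a diploid, socially monogamous species:
pair formation with breeder monopolization (a proportion `p_pair` of adult
females pair, optionally density dependent), reproduction with inbreeding
depression acting on whelping failure and litter size as `exp(-B F)` (`B`
lethal equivalents) and *masked* in packs receiving supplemental feeding,
age-class mortality with environmental variance, disease catastrophes,
population-cap removals, and scheduled releases chosen by lowest mean
kinship to the wild population. Genetics are classical gene dropping:
uniquely labelled founder alleles transmitted Mendelianly at `n_loci`
independent loci (compiled kernels), giving each individual an inbreeding
coefficient and each population a gene diversity `GD = 1 − f̄` (mean
kinship, ordered pairs including self-pairs) and founder genome equivalents
`FGE = 1/(2 f̄)`. Exact recursive pedigree kinship, Monte-Carlo gene drop,
and `Ne` from the drift equation `GD_t = GD_0 (1 − 1/(2Ne))^t` are provided
alongside.

**Sensitivity analysis.** Six factors are crossed between their 2013 and
2017 values — pairing, disease (biological); releases, cap (policy);
inbreeding-with-feeding, adult mortality (mixed); the inbreeding and feeding
columns are crossed separately, giving 2^7 = 128 scenarios. Per response
metric (extinction probability, quasi-extinction probability below a census
of 150, mean retained gene diversity), a regression over scenarios yields
standardized coefficients (z or t = coefficient / SE) whose absolute values
are converted to per-factor and per-category percentage shares. The quartile
coefficient of dispersion `(Q3 − Q1)/(Q3 + Q1)` compares the robustness of
the three metrics to parameter uncertainty.

## Worked example

```r
library(wolfpva)
captive <- make_founder_pedigree(seed = 1)      # 7-founder captive history
pop     <- make_initial_population(captive, n = 220, seed = 1)
gene_diversity(pop$ped, pop$wild_ids)           # 0.7521
founder_genome_equivalents(pop$ped, pop$wild_ids)  # 2.017
mean(inbreeding_coefficient(pop$ped, pop$wild_ids))  # 0.237

sets <- default_parameter_sets()
run_scenario(sets[["2013"]], pop, n_iter = 100, years = 100, seed = 1)
#> <pva_scenario> 2013: n_iter=100 years=100 | P(ext)=1.000 P(quasi)=1.000 mean GD=NA
run_scenario(sets[["2017"]], pop, n_iter = 100, years = 100, seed = 1)
#> <pva_scenario> 2017: n_iter=100 years=100 | P(ext)=0.000 P(quasi)=0.000 mean GD=0.7052
```

The synthetic captive population sits in the depleted regime (about two
founder genome equivalents out of seven founders) and the wild cohort
descends from it, so its mean inbreeding coefficient is near the
full-sibling level (0.25). Under the harsher 2013-style rates the starting
population collapses within decades; under the optimistic 2017-style rates
(higher pairing, widespread feeding that masks inbreeding depression, milder
disease) it persists at its cap of 379 while retaining ~70% gene diversity —
the two parameterizations bracket the contrast the sensitivity analysis then
decomposes:

```r
fac <- run_factorial(build_factorial_design(), pop, n_iter = 100,
                     years = 100, seed = 1)
qcd_summary(fac)                       # dispersion of the three metrics
contrast_shares(fit_contrast_model(fac, "extinction"))$category_shares
```

`run_config()` drives the same pipeline from a YAML config
(`fixtures` / `simulate` / `sensitivity` / `surface` subcommands, CSV
artifacts plus a manifest listing every placeholder parameter), and
`inst/cli/wolfpva.R` is a thin command-line wrapper around it.

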