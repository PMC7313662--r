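# mmcscan

Genomic scans for selective sweeps, framed as coalescent **model choice**
rather than outlier rejection.

## The problem

Sweep scans compare windowed summary statistics against a neutral
Wright–Fisher / Kingman-coalescent expectation and flag outliers. Under
non-equilibrium demography this logic fails in a characteristic way: a
population bottleneck rescales coalescent branch lengths much like a sweep
does, so bottlenecked neutral windows become "outliers" too, and
false-positive rates climb. What a neutral size change *cannot* do is alter
the branching structure: only a sweep (or genuinely skewed reproduction)
makes more than two lineages coalesce at once. That structure is the domain
of **multiple-merger coalescents (MMC)**.

`mmcscan` asks, for every genomic window, which of two generative models
fits better:

* **Kingman** — neutral Wright–Fisher reproduction under the assumed
  demographic history;
* **MMC (ψ-coalescent)** — the same history plus an episode of sweepstakes
  reproduction, in which a single individual contributes a fraction ψ of
  the next generation each generation until a focal allele fixes, with
  ψ ~ U[0.004, 0.08] at its reference population size.

It is aimed at population geneticists who want sweep candidates that are
robust to bottleneck-driven false positives, and at methodologists studying
when sweeps and demography are (or are not) distinguishable.

## The method

1. **Forward simulation** (C++ engine): diploid Wright–Fisher with
   recombination ρ and infinite-sites mutation μ per site; 10 *N*-generation
   burn-in; optional instantaneous bottleneck to β*N* for 0.005 × 4*N*
   generations; fixation-conditioned sweeps with fitnesses
   1 : 1 + *hs* : 1 + *s*; ψ-episodes implemented as direct offspring-count
   assignment (`round(2Nψ)` slots from one carrier per generation).
2. **Summary statistics** per window: *S*, π, Tajima's *D*, Fu & Li's *D*
   and *F* (unfolded), haplotype diversity, Wall's *B* and *Q*, Rozas's
   *ZA* and *ZZ*, Kelly's *ZnS*.
3. **Rejection ABC**: statistics pruned at |r| > 0.8, centred and scaled on
   the pooled training set; Euclidean distance to all training replicates;
   the nearest 10% vote, giving each window a posterior probability of the
   MMC model. Leave-one-out cross-validation reports per-model
   misclassification.
4. **Calling**: a window is *sweep-like* when its MMC posterior exceeds the
   99% nearest-rank percentile of the posterior over matched neutral
   simulations; a TPR/FPR harness evaluates detection within the window(s)
   overlapping the selected site.

See `vignettes/coalescent-model-choice.Rmd` for the full model description,
parameter meanings, numerical conventions, and the desk-scale profile used
throughout the tests.

## A worked example

Train on window-sized replicates, calibrate the neutral threshold, scan a
sweep chromosome (desk scale, ~4 minutes):

```r
library(mmcscan)

params <- desk_params(N = 500)                 # 10-kb windows, 50-kb chromosome
prior  <- rescale_psi_prior(psi_model(), N_ref = 5000, N = 500)

train <- simulate_training_set(params, psi_prior = prior,
                               n_per_model = 1000, window_size = 1e4,
                               seed = 101)
tr <- abc_training(train)
tr
#> <abc_training> 2000 replicates (1000 kingman / 1000 mmc), 5 of 11 statistics kept
#>   kept: S, tajimas_d, hap_div, walls_b, kellys_zns

loo_cv(tr, n_folds = 500, seed = 102)
#> <abc_cv> 500 folds, tolerance 0.1
#>   misclassification: kingman 0.035, mmc 0.159

thr <- neutral_threshold(unlist(lapply(derive_seeds(103, 20), function(s) {
  m <- simulate_observed(params, seed = s)
  scan_chromosome(m, tr, size = 1e4, step = 5e3)$p_mmc
})), 0.99)
thr
#> [1] 0.75

swept <- simulate_observed(params, selection = selection_model(s = 0.25),
                           seed = 104)         # 2Ns = 250, sweep at 25 kb
scan_chromosome(swept, tr, size = 1e4, step = 5e3, threshold = thr)
#> # A tibble: 9 × 4
#>   start   end p_mmc call
#>   <int> <int> <dbl> <lgl>
#> 1     0 10000 0.41  FALSE
#> 2  5000 15000 0.54  FALSE
#> 3 10000 20000 0.72  FALSE
#> 4 15000 25000 1     TRUE
#> 5 20000 30000 1     TRUE
#> 6 25000 35000 0.6   FALSE
#> 7 30000 40000 0.515 FALSE
#> 8 35000 45000 0.27  FALSE
#> 9 40000 50000 0.195 FALSE
```

The MMC posterior peaks at exactly the two windows containing the selected
site (25 kb) and decays with distance; under this equilibrium history the
Kingman and MMC training sets are well separated (the MMC replicates, which
include near-Kingman ψ draws, misclassify more often — an asymmetry the
method inherits from the model, not a bug). `autoplot()` on the scan draws
the posterior track with the threshold line.

A command-line interface wrapping the same functions ships in
`inst/cli/mmcscan` (`simulate`, `train`, `cv`, `threshold`, `scan`,
`evaluate`, each driven by a YAML config; see `?read_run_config`).

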