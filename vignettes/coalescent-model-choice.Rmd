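---
title: "Sweep detection as coalescent model choice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep detection as coalescent model choice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The idea

Classical genome scans treat a selective sweep as a *rejection* problem:
find windows whose summary statistics are unlikely under a neutral
Kingman-coalescent null. The weakness of that framing is well known — a
population bottleneck also rescales branch lengths, so bottlenecked neutral
windows reject the null too, and false-positive rates explode.

A sweep, however, does something a neutral size change cannot: the haplotype
carrying the beneficial allele leaves very many descendants in a handful of
generations, so more than two sampled lineages coalesce effectively
simultaneously. That *branching structure* is the signature of the
multiple-merger coalescent (MMC) family. `mmcscan` therefore asks a sharper
question per window: *is this window better fit by a Kingman genealogy or by
a multiple-merger genealogy?* A bottleneck changes branch lengths but not
branching structure, so the comparison retains power where outlier scans
drown in false positives — up to the point (extreme contractions) where the
two are genuinely indistinguishable and no polymorphism-based method works.

The MMC used here is the psi-coalescent of Eldon and Wakeley, chosen because
psi has a direct biological reading: the fraction of the next generation
contributed by a single "sweepstakes" parent.

## The forward engine

All data are produced by a forward-in-time diploid Wright-Fisher simulator
(C++ core): `2N` haplotypes, random mating without selfing, per-gamete
recombination at rate `rho` per site, infinite-sites mutation at `mu` per
site on discrete positions with collision redraw (ancestral states known, so
all statistics are unfolded). Every scenario starts from a monomorphic
population and runs a burn-in of `10 N` neutral generations to reach
mutation-drift equilibrium.

Three scenario layers follow the burn-in:

* **Demography.** Either equilibrium, or an instantaneous bottleneck to
  `round(beta * N)` individuals held for `0.005 * 4N` generations (the
  default) and restored instantaneously by one round of offspring sampling
  from the bottlenecked pool.
* **Selective sweep.** A de novo beneficial mutation at `floor(L/2)` with
  diploid fitnesses `1 : 1 + hs : 1 + s` (`h = 0.5` by default — genic
  selection, since dominance is not otherwise constrained) is introduced at
  the moment of recovery and conditioned on fixation: replicates that lose
  the allele restart from the pre-sweep population state. Sweep replicates
  are sampled at fixation.
* **Psi episode (the MMC generator).** A neutral focal mutation m2 arises in
  one individual; each generation, one m2-carrier is chosen uniformly and
  contributes exactly `round(2 N psi)` haplotype slots of the next
  generation through its recombinant gametes (one per offspring individual),
  while the remaining slots come from ordinary Wright-Fisher reproduction
  among the other individuals. The episode ends when m2 fixes; losses
  restart with a fresh m2. We implement the sweepstakes contribution as a
  direct offspring-count assignment rather than through a migration trick
  with an auxiliary subpopulation: the intended offspring distribution is
  identical, and withholding the chosen parent from the ordinary pool for
  that generation mirrors its temporary placement in a separate
  subpopulation (and makes its contribution exactly `round(2 N psi)` slots,
  which the tests verify by tagging parents).

Neutral ("Kingman") replicates are sampled at a time `tau ~ U[0, tau_max]`
after the demographic event, where `tau_max` defaults to the expected
fixation time of the weakest sweep considered (`~ 4 log(2N) / s_min`
generations). This mirrors the fixation-conditioned sweeps: both replicate
classes then cover the same distribution of post-event sampling times. MMC
replicates are summarised either at the fixation of m2 or at one of 20
random later time points; since no range is prescribed for those time
points, we draw them from the same `U[0, tau_max]` used for the neutral
replicates, and each replicate contributes one uniformly chosen time point
(fixation with probability 1/21) rather than 21 correlated vectors.

## Summary statistics

Eleven statistics per window, in a fixed canonical order (`S`, `pi`,
Tajima's `D`, Fu & Li's `D` and `F`, haplotype diversity, Wall's `B` and
`Q`, Rozas's `ZA` and `ZZ`, Kelly's `ZnS`): counts and diversity, the site
frequency spectrum (excess of rare and derived variants — unfolded Fu & Li
from derived singletons), haplotype structure, and linkage disequilibrium,
which together capture the known MMC signatures (skewed SFS, elevated LD).
`pi` and `S` are reported per window, not per site, because the ABC layer
compares whole windows of fixed physical size. Windows with `S = 0` — an
expected outcome of strong sweepstakes episodes, not an error — are flagged
degenerate; their undefined statistics are imputed with the most extreme
value observed for that statistic in the training set (largest absolute
deviation from the column mean), so that zero-variation windows remain
classifiable instead of being silently biased against the MMC.

## Rejection ABC model choice

Training data are `n` replicates per model simulated at the scan window
size under the *same demography* as the data to be scanned, so training and
observed windows are exchangeable under the null. Statistics are pruned
greedily in the canonical column order (drop any column with absolute
Pearson correlation above 0.8 against an already-kept column; computed on
non-degenerate rows), then centred and scaled on the pooled training set;
target windows reuse the training centring. Classification is plain
rejection: Euclidean distance to every training row, accept the nearest
`round(0.1 R)` (ties at the boundary all included), posterior probability
of the MMC model = its share of accepted rows. No regression adjustment is
applied, deliberately.

A window is called *sweep-like* when its MMC posterior exceeds the 99%
point of the posterior over windows of matched neutral simulations, pooled
across window positions. The percentile uses the nearest-rank definition
(value at rank `ceiling(0.99 n)` of the sorted sample) — stated explicitly
because interpolation conventions differ between implementations.
Leave-one-out cross-validation (`loo_cv()`) reports per-model
misclassification, with posterior ties counted as misclassified;
at large training sizes folds are uniformly subsampled (default 1000).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `N` | profile | diploid population size |
| `mu`, `rho` | profile | per-site, per-generation rates |
| `lam` | 1 | rescaling `N/lam`, `mu*lam`, `rho*lam`; preserves `4NmuL` |
| `2Ns` | 100–500 | scaled sweep strength at the simulated `N` |
| `h` | 0.5 | dominance of the beneficial allele |
| psi prior | `U[0.004, 0.08]` at `N = 5000` | sweepstakes fraction |
| window, step | 100 kb, 50 kb (full scale) | scan geometry |
| tolerance | 0.10 | accepted fraction of training rows |
| level | 0.99 | neutral credible level for calls |

The psi prior bounds are tied to the population size at which they are
stated: the genealogical weight of sweepstakes events relative to drift
scales as `2 N psi^2`, so `rescale_psi_prior()` maps the prior to a smaller
simulated `N` by `psi -> psi * sqrt(N_ref / N)`. Without this, shrinking
`N` would silently weaken the MMC signal.

## Desk-scale profile and problem sizes

Full-scale runs (human-like `N = 10^4`, `lambda = 2`, 5-Mb chromosomes,
30,000 training replicates per model) are multi-day computations. The
package's tests and the acceptance script use a *desk profile* chosen once:

* `N = 500` (`N = 1000` for the 0.2% bottleneck, the smallest `N` at which
  `round(beta * N) >= 2`), `n_sample = 20` haplotypes;
* 10-kb windows with `4*N*mu*window = 24` and `4*N*rho*window = 20`
  (`mu = 6e-4 / N`, `rho = 5e-4 / N`), giving roughly 85 segregating sites
  per neutral window — enough for stable statistics at a fraction of the
  cost;
* 50-kb observed chromosomes (9 overlapping windows);
* 2,000 + 2,000 training replicates for the equilibrium cross-validation
  study; power comparisons across demographies use training sets of matched
  size (400 per model at `N = 500`, 250 at `N = 1000` — an iid subsample of
  the large set for the equilibrium cells), because classifier sharpness
  scales with training size and would otherwise confound the comparison;
  thresholds pooled over 20–40 neutral chromosomes; 20–80 sweep replicates
  per power cell.

The profile preserves the quantities that control the biology: `2Ns`,
`beta`, the bottleneck intensity (duration over `2 * beta * N`), the
per-window mutation input, and `2 N psi^2`. What it cannot preserve is the
ratio of chromosome length to sweep footprint — at desk scale a strong
sweep shadows a larger fraction of the 50-kb chromosome than it would on 5
Mb — so desk-scale false-positive rates and power are qualitative
reproductions (orderings, calibration), not numerical reproductions of
full-scale values.

## What the generator does and does not emulate

The synthetic data embody the model's assumptions exactly: panmixia, known
ancestral states, biallelic loci, constant rates along the chromosome, a
single sweep or a single psi episode. Passing tests therefore demonstrate
internal consistency and the claimed statistical behaviour of the method
under its own model — they say nothing about robustness to background
selection, mutation-rate heterogeneity, mispolarised alleles, missing data,
or population structure, none of which the generator produces. Empirical
ms/VCF input is accepted, but those caveats transfer to any real-data use.

## Numerical and degenerate-input conventions

* Coordinates are 0-based, half-open everywhere; the sweep sits at
  `floor(L / 2)`; trailing partial windows are dropped.
* If the focal mutation's target position is already segregating, the next
  free position to the right is used (infinite sites requires distinctness).
* Fixation-conditioning restarts are capped (default 10,000) and restart
  from a snapshot of the pre-episode population, so conditioning never
  contaminates the pre-event state.
* Rejection boundary ties are all accepted; cross-validation posterior ties
  count as misclassified; `round()` follows R's banker's rounding.
* Zero-variance statistic columns cannot be standardized and must be pruned
  first; `standardize_stats()` errors rather than guessing.
* All randomness flows from one integer seed through counter-based child
  seeds (`derive_seeds()`); identical seeds give bit-identical haplotype
  matrices.

## Known limitations

* Rejection-only ABC: no posterior for psi, no regression adjustment.
* One psi episode / one sweep per replicate; no recurrent sweeps.
* No back-mutation, gene conversion, selfing, or structured populations.
* The backward-in-time MMC genealogy simulator is out of scope; the psi
  process is generated forward in time only.
* Under extreme bottlenecks the method, like every polymorphism-based scan,
  has essentially no power — the genealogies are genuinely confounded; the
  compensation is that the matching neutral threshold also keeps
  false-positive calls rare there.

## A worked desk-scale run

```{r example}
library(mmcscan)

params <- desk_params(N = 500)
prior <- rescale_psi_prior(psi_model(), N_ref = 5000, N = 500)

train <- simulate_training_set(params, psi_prior = prior,
                               n_per_model = 2000, window_size = 1e4,
                               seed = 101)
tr <- abc_training(train)
loo_cv(tr, n_folds = 1000, seed = 102)

thr <- neutral_threshold(unlist(lapply(derive_seeds(103, 20), function(s) {
  m <- simulate_observed(params, seed = s)
  scan_chromosome(m, tr, size = 1e4, step = 5e3)$p_mmc
})), 0.99)

swept <- simulate_observed(params, selection = selection_model(s = 0.25),
                           seed = 104)
scan <- scan_chromosome(swept, tr, size = 1e4, step = 5e3, threshold = thr)
autoplot(scan)
```
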