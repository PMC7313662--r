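# Desk-scale study fixtures shared across the acceptance tests. Everything is
# generated in code at fixed seeds and cached for the duration of one test
# run; nothing is stored on disk.
#
# Desk profile: N = 500 (N = 1000 for the 0.2% bottleneck so that
# round(beta * N) >= 2), 10-kb scan windows with theta_w = 24 and
# rho_w/theta_w = 5/6, 50-kb observed chromosomes, n_sample = 20 haplotypes,
# 2Ns preserved at the simulated N, psi prior U[0.004, 0.08] rescaled to
# preserve 2 N psi^2 from its reference N of 5000. Power comparisons across
# demographies use training sets of matched size (400 per model; 250 at
# N = 1000), since classifier sharpness scales with training size and would
# otherwise confound the comparison.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

fx_psi_prior <- function(N) rescale_psi_prior(psi_model(), N_ref = 5000, N = N)

fx_demog <- function(beta) {
  if (beta >= 1) demography_model("equilibrium")
  else demography_model("bottleneck", beta = beta)
}

# labelled training set + fitted abc_training for one demography
fx_training <- function(key, N, beta, n_per_model, seed, window = 1e4) {
  fx_memo(key, function() {
    p <- desk_params(N = N)
    reps <- simulate_training_set(p, fx_demog(beta), fx_psi_prior(N),
                                  n_per_model = n_per_model,
                                  window_size = window, seed = seed)
    list(replicates = reps, training = abc_training(reps))
  })
}

fx_eq_training <- function()
  fx_training("eq", N = 500, beta = 1, n_per_model = 2000, seed = 811001)

# matched-size training for the power comparison: an iid subsample of the
# equilibrium training replicates, refit
fx_eq_training_small <- function(n_per_model = 400) {
  fx_memo("eq_small", function() {
    reps <- fx_eq_training()$replicates
    idx <- with_seed(811010, unlist(lapply(c("kingman", "mmc"), function(m)
      sample(which(reps$model == m), n_per_model))))
    abc_training(reps[idx, ])
  })
}

fx_b10_training <- function()
  fx_training("b10", N = 500, beta = 0.10, n_per_model = 400, seed = 811002)
fx_b2_training <- function()
  fx_training("b2", N = 500, beta = 0.02, n_per_model = 400, seed = 811003)
fx_b02_training <- function()
  fx_training("b02", N = 1000, beta = 0.002, n_per_model = 250, seed = 811004)

# pooled neutral threshold for one demography (99% level)
fx_threshold <- function(key, N, beta, training, seed, n_chrom = 40) {
  fx_memo(paste0(key, "_thr"), function() {
    p <- desk_params(N = N)
    pm <- unlist(lapply(derive_seeds(seed, n_chrom), function(s) {
      m <- simulate_observed(p, fx_demog(beta), NULL, seed = s)
      scan_chromosome(m, training, size = 1e4, step = 5e3)$p_mmc
    }))
    neutral_threshold(pm, 0.99)
  })
}

# detected-count for one (demography, 2Ns) cell
fx_power_cell <- function(N, beta, two_Ns, training, threshold, seed,
                          n_reps) {
  p <- desk_params(N = N)
  sel <- selection_model(s = two_Ns / (2 * N))
  pos <- p$L %/% 2
  scans <- lapply(derive_seeds(seed, n_reps), function(s) {
    m <- simulate_observed(p, fx_demog(beta), sel, seed = s)
    scan_chromosome(m, training, size = 1e4, step = 5e3,
                    threshold = threshold)
  })
  tpr <- evaluate_power(scans, pos)$tpr
  list(tpr = tpr, hits = round(tpr * n_reps), n = n_reps)
}
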