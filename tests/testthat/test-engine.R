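# Forward-engine behaviour: reproduction mechanics, conditioning, demography,
# sampling, and agreement with neutral-coalescent expectations.

# hand-built population: `haps` is a list of integer position vectors
make_pop <- function(haps, L, tracked = -1L, generation = 0) {
  pos <- sort(unique(unlist(haps)))
  st <- list(generation = as.double(generation), L = as.integer(L),
             haplotypes = lapply(haps, as.integer),
             variant_pos = as.integer(pos),
             variant_origin = rep(0L, length(pos)),
             tracked = as.integer(tracked))
  mmcscan:::new_wf_population(st)
}

test_that("reproduction conserves the haplotype count and the generation counter", {
  p <- sim_params(N = 20, mu = 1e-5, rho = 1e-5, L = 2000)
  pop <- new_population(20, 2000)
  pop <- burn_in(pop, p, seed = 1)
  expect_equal(length(pop$haplotypes), 40)
  expect_equal(as.integer(pop$generation), 200)  # exactly 10 N
  nxt <- wf_generation(pop, p, seed = 2)
  expect_equal(length(nxt$haplotypes), 40)
  expect_equal(nxt$generation, pop$generation + 1)
  # instantaneous size change via next_N
  big <- wf_generation(pop, p, seed = 3, next_N = 35)
  expect_equal(length(big$haplotypes), 70)
})

test_that("without mutation the population stays monomorphic through burn-in", {
  p <- sim_params(N = 15, mu = 0, rho = 1e-5, L = 1000)
  pop <- burn_in(new_population(15, 1000), p, seed = 4)
  expect_equal(length(pop$variant_pos), 0)
  m <- sample_haplotypes(pop, 10, seed = 5)
  expect_equal(ncol(m), 0)
})

test_that("neutral drift is a martingale: mean offspring frequency equals 0.5", {
  # 50 of 100 individuals carry the tracked allele on both haplotypes
  haps <- c(rep(list(c(7L)), 100), rep(list(integer(0)), 100))
  pop <- make_pop(haps, L = 1000, tracked = 7L)
  p <- sim_params(N = 100, mu = 0, rho = 0, L = 1000)
  freqs <- vapply(derive_seeds(99, 600), function(s)
    tracked_frequency(wf_generation(pop, p, seed = s)), numeric(1))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 4 * se)
})

test_that("a fixed beneficial allele stays fixed under selection", {
  haps <- rep(list(c(3L)), 40)
  pop <- make_pop(haps, L = 100, tracked = 3L)
  p <- sim_params(N = 20, mu = 0, rho = 0, L = 100)
  nxt <- wf_generation(pop, p, selection_model(s = 0.5), seed = 8)
  expect_equal(tracked_frequency(nxt), 1)
})

test_that("neutral fixation probability of a new mutation is about 1/(2N)", {
  # psi below 1/(4N) makes the episode a pure neutral conditioning loop, so
  # restart counts give the attempts-per-fixation (geometric) directly
  p <- sim_params(N = 50, mu = 0, rho = 0, L = 1000)
  pop <- new_population(50, 1000)
  seeds <- derive_seeds(123, 150)
  attempts <- vapply(seeds, function(s)
    run_psi_phase(pop, p, psi = 1e-4, seed = s)$restarts + 1, numeric(1))
  phat <- length(attempts) / sum(attempts)
  p0 <- 1 / 100
  se <- sqrt(p0 * (1 - p0) / sum(attempts))
  expect_lt(abs(phat - p0), 4 * se)
})

test_that("the sweepstakes parent contributes exactly round(2 N psi) haplotype slots", {
  # individual i is tagged by a private variant at position i on both of its
  # haplotypes; with mu = rho = 0 every transmitted gamete keeps its tag
  N <- 100
  haps <- unlist(lapply(seq_len(N) - 1L, function(i)
    list(sort(unique(c(i, if (i == 0) 500L))), i)), recursive = FALSE)
  haps <- lapply(haps, as.integer)
  pop <- make_pop(haps, L = 1000, tracked = 500L)
  p <- sim_params(N = N, mu = 0, rho = 0, L = 1000)
  expect_equal(tracked_frequency(pop), 1 / (2 * N))
  for (s in 11:13) {
    nxt <- psi_generation(pop, p, psi = 0.08, seed = s)
    from_parent <- sum(vapply(nxt$haplotypes, function(h) 0L %in% h, TRUE))
    expect_equal(from_parent, round(2 * N * 0.08))  # = 16 of 200 slots
  }
})

test_that("psi reproduction pushes the m2 frequency upward in expectation", {
  # 20 of 100 individuals carry m2 on one haplotype: p = 0.1
  haps <- unlist(lapply(1:100, function(i)
    list(if (i <= 20) 5L else integer(0), integer(0))), recursive = FALSE)
  pop <- make_pop(lapply(haps, as.integer), L = 1000, tracked = 5L)
  p <- sim_params(N = 100, mu = 0, rho = 0, L = 1000)
  dp <- vapply(derive_seeds(7, 4000), function(s)
    tracked_frequency(psi_generation(pop, p, psi = 0.2, seed = s)) - 0.1,
    numeric(1))
  expect_gt(mean(dp), 4 * sd(dp) / sqrt(length(dp)))
})

test_that("degenerate psi (round(2 N psi) = 0) reproduces the plain WF generation", {
  haps <- c(rep(list(c(9L)), 30), rep(list(integer(0)), 70))
  pop <- make_pop(haps, L = 1000, tracked = 9L)
  p <- sim_params(N = 50, mu = 1e-5, rho = 1e-5, L = 1000)
  a <- psi_generation(pop, p, psi = 0.001, seed = 77)   # round(100*0.001) = 0
  b <- wf_generation(pop, p, seed = 77)
  expect_identical(a$haplotypes, b$haplotypes)
})

test_that("psi episodes always end fixed, faster for larger psi", {
  p <- sim_params(N = 100, mu = 1e-6, rho = 0, L = 1000)
  pop <- burn_in(new_population(100, 1000), p, seed = 31)
  lens <- sapply(c(lo = 0.05, hi = 0.25), function(psi) {
    mean(vapply(derive_seeds(1000 * psi, 60), function(s) {
      r <- run_psi_phase(pop, p, psi = psi, seed = s)
      expect_equal(r$outcome, "fixed")
      r$phase_length
    }, numeric(1)))
  })
  expect_gt(lens["lo"], lens["hi"])
  # and the post-phase population carries m2 at frequency exactly 1
  r <- run_psi_phase(pop, p, psi = 0.2, seed = 5150)
  expect_equal(tracked_frequency(r$population), 1)
})

test_that("stronger sweeps fix faster and end at frequency 1", {
  p <- sim_params(N = 100, mu = 1e-6, rho = 1e-6, L = 2000)
  pop <- burn_in(new_population(100, 2000), p, seed = 41)
  t_weak <- vapply(derive_seeds(42, 50), function(s)
    run_sweep(pop, p, selection_model(s = 0.5), seed = s)$phase_length,
    numeric(1))
  t_strong <- vapply(derive_seeds(43, 50), function(s)
    run_sweep(pop, p, selection_model(s = 2.5), seed = s)$phase_length,
    numeric(1))
  expect_lt(mean(t_strong), mean(t_weak))
  r <- run_sweep(pop, p, selection_model(s = 1), seed = 44)
  expect_equal(tracked_frequency(r$population), 1)
})

test_that("a sweep depresses diversity around the selected site", {
  p <- desk_params(N = 200, L = 3e4)
  sel <- selection_model(s = 250 / (2 * 200))   # 2Ns = 250
  hits <- 0
  for (s in derive_seeds(808, 20)) {
    m <- simulate_observed(p, selection = sel, seed = s)
    pis <- vapply(0:5, function(k)
      window_stats(m, k * 5000, (k + 1) * 5000)$pi, numeric(1))
    centre <- window_stats(m, 12500, 17500)$pi  # window centred on the site
    if (centre < median(pis)) hits <- hits + 1
    # the beneficial site itself is fixed in the sample, hence absent
    expect_false((3e4 %/% 2) %in% positions(m))
  }
  expect_gte(hits / 20, 0.9)
})

test_that("bottleneck arithmetic and guards follow the definitions", {
  d <- mmcscan:::resolve_demog(demography_model("bottleneck", beta = 0.002),
                               N = 5000)
  expect_equal(round(0.002 * 5000), 10)
  expect_equal(d$duration, 100)                 # 0.005 * 4N at N = 5000
  p <- sim_params(N = 500, mu = 0, rho = 0, L = 1000)
  pop <- new_population(500, 1000)
  expect_error(
    apply_bottleneck(pop, p, demography_model("bottleneck", beta = 0.002),
                     seed = 1),
    "invalid demography")
  # beta = 1 is the identity
  eq <- demography_model("equilibrium")
  expect_identical(apply_bottleneck(pop, p, eq, seed = 1), pop)
  # size is restored after the bottleneck
  bn <- apply_bottleneck(pop, p,
                         demography_model("bottleneck", beta = 0.1,
                                          duration = 5), seed = 2)
  expect_equal(length(bn$haplotypes), 1000)
})

test_that("a severe bottleneck with recovery leaves negative Tajima's D on average", {
  p <- desk_params(N = 200, L = 1e4)
  demog <- demography_model("bottleneck", beta = 0.01, duration = 10,
                            tau_max = 30)
  td <- vapply(derive_seeds(2024, 200), function(s) {
    m <- simulate_observed(p, demog, seed = s)
    window_stats(m)$tajimas_d
  }, numeric(1))
  expect_lt(mean(td, na.rm = TRUE), 0)
})

test_that("sampling drops monomorphic sites and matches census frequencies", {
  # hand-built population with known derived counts
  haps <- c(rep(list(c(10L, 50L)), 3), rep(list(c(50L)), 5),
            rep(list(integer(0)), 12))
  pop <- make_pop(haps, L = 100)
  m <- sample_haplotypes(pop, 20, seed = 3)     # census: n = 2N
  expect_equal(positions(m), c(10L, 50L))
  expect_equal(unname(colSums(m)), c(3L, 8L))
  # derived counts always within [1, n - 1]
  p <- desk_params(N = 100, L = 1e4)
  mm <- simulate_observed(p, seed = 99)
  cnt <- colSums(mm)
  expect_true(all(cnt >= 1 & cnt <= nrow(mm) - 1))
  # span restriction
  sub <- sample_haplotypes(pop, 10, seed = 4, span = c(0L, 30L))
  expect_true(all(positions(sub) < 30))
})

test_that("identical seeds give bit-identical replicates, different seeds differ", {
  p <- desk_params(N = 100, L = 1e4)
  a <- simulate_observed(p, seed = 314)
  b <- simulate_observed(p, seed = 314)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_identical(positions(a), positions(b))
  c <- simulate_observed(p, seed = 315)
  expect_false(identical(positions(a), positions(c)))
})

test_that("neutral engine output matches an independent coalescent simulator (msprime)", {
  # same 4NmuL and 4NrhoL; compare mean S and mean pi across replicates
  N <- 100; mu <- 4e-6; rho <- 4e-6; L <- 5000; n <- 15
  p <- sim_params(N = N, mu = mu, rho = rho, L = L, n_sample = n)
  eng <- t(vapply(derive_seeds(61, 150), function(s) {
    m <- simulate_observed(p, seed = s)
    b <- basic_stats(m)
    c(S = as.numeric(b$S), pi = b$pi)
  }, numeric(2)))
  py <- sprintf(
    "import msprime\nimport numpy as np\nS=[];P=[]\nfor seed in range(1,301):\n    ts=msprime.sim_ancestry(samples=%d,ploidy=1,population_size=%d,recombination_rate=%g,sequence_length=%d,random_seed=seed)\n    ts=msprime.sim_mutations(ts,rate=%g,random_seed=seed+10000,discrete_genome=True)\n    S.append(ts.num_sites)\n    P.append(ts.diversity(span_normalise=False))\nprint(np.mean(S),np.std(S),np.mean(P),np.std(P))\n",
    n, 2 * N, rho, L, mu)
  out <- suppressWarnings(system2("python", c("-c", shQuote(py)),
                                  stdout = TRUE, stderr = FALSE))
  expect_true(length(out) >= 1)
  vals <- as.numeric(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  for (stat in c("S", "pi")) {
    i <- if (stat == "S") 1 else 3
    se <- sqrt(vals[i + 1]^2 / 300 + var(eng[, stat]) / nrow(eng))
    expect_lt(abs(mean(eng[, stat]) - vals[i]), 4 * se)
  }
})
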