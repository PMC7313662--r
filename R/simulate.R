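# Whole-replicate simulation pipelines. These stay inside the C++ engine for
# an entire replicate (burn-in -> demography -> scenario -> sampling), which
# is what makes training-set generation tractable.

resolve_demog <- function(demog, N, two_Ns_min = 100) {
  demog <- demog %||% demography_model("equilibrium")
  list(
    beta = if (demog$kind == "bottleneck") demog$beta else 1,
    duration = if (demog$kind == "bottleneck")
      (demog$duration %||% round(0.005 * 4 * N)) else 0,
    tau_max = demog$tau_max %||% tau_max_default(N, two_Ns_min)
  )
}

sim_replicate_raw <- function(params, beta, duration, scenario, s, h, psi,
                              focal_pos, tau, seed, L = params$L,
                              n_sample = params$n_sample,
                              max_restarts = 10000) {
  cpp_simulate_replicate(
    params$N, params$mu, params$rho, as.integer(L),
    10 * params$N, beta, duration,
    as.integer(scenario), s, h, psi, as.integer(focal_pos), as.double(tau),
    as.integer(n_sample), as.integer(max_restarts), as.double(seed))
}

#' Simulate an observed chromosome
#'
#' Runs the full forward pipeline for one "observed" replicate: neutral
#' burn-in of `10 N` generations, the demographic history, then either a
#' fixation-conditioned selective sweep (sampled at fixation) or a neutral
#' continuation sampled `tau ~ U[0, tau_max]` generations after the
#' demographic event, and finally a haplotype sample of the whole chromosome.
#'
#' @param params A [sim_params()] (apply [scale_params()] first if `lam > 1`).
#' @param demog A [demography_model()]; `NULL` means equilibrium.
#' @param selection A [selection_model()] or `NULL` for a neutral replicate.
#' @param seed Integer seed; all randomness of the replicate derives from it.
#' @param max_restarts Cap on fixation-conditioning restarts.
#' @return A [hap_matrix()] spanning `[0, L)` with attributes `scenario`
#'   (a list recording the demography, selection, sampling time `tau`,
#'   sweep length and restart count) and `seed`.
#' @export
#' @examples
#' p <- desk_params(N = 100, L = 2e4)
#' m <- simulate_observed(p, seed = 1)
simulate_observed <- function(params, demog = NULL, selection = NULL, seed,
                              max_restarts = 10000) {
  stopifnot(inherits(params, "sim_params"))
  params <- scale_params(params)
  d <- resolve_demog(demog, params$N)
  if (is.null(selection)) {
    tau <- with_seed(seed, floor(runif(1, 0, d$tau_max + 1)))
    r <- sim_replicate_raw(params, d$beta, d$duration, 0L, 0, 0, 0, 0L, tau,
                           seed, max_restarts = max_restarts)
    info <- list(model = "neutral", tau = tau)
  } else {
    pos <- selection$position %||% (params$L %/% 2)
    r <- sim_replicate_raw(params, d$beta, d$duration, 1L, selection$s,
                           selection$dominance, 0, pos, 0, seed,
                           max_restarts = max_restarts)
    info <- list(model = "sweep", s = selection$s, position = pos,
                 phase_length = r$phase_length, restarts = r$restarts)
  }
  m <- hap_matrix(r$matrix, r$positions, c(0L, params$L))
  attr(m, "scenario") <- c(info, list(demography = demog, N = params$N))
  attr(m, "seed") <- seed
  m
}

#' Simulate one training replicate and summarise it
#'
#' Training regions are window-sized so that training and observed scan
#' windows are exchangeable under the null. A Kingman replicate is the
#' neutral scenario sampled at `tau ~ U[0, tau_max]`; an MMC replicate adds
#' one psi episode (psi drawn from the prior) starting at the epoch where a
#' sweep would start, with the summary statistics sampled either at the
#' fixation of m2 or at one of 20 random later time points (one of the 21
#' candidate time points is chosen uniformly per replicate).
#'
#' @param model `"kingman"` or `"mmc"`.
#' @param params A [sim_params()]; its `L` is ignored in favour of
#'   `window_size`.
#' @param demog A [demography_model()] or `NULL` for equilibrium.
#' @param psi_prior A [psi_model()]; used only for `model = "mmc"`.
#' @param window_size Training-region length in bp (the scan window size).
#' @param seed Integer seed.
#' @param max_restarts Cap on fixation-conditioning restarts.
#' @return A one-row [tibble::tibble()]: `model`, `psi` (`NA` for Kingman),
#'   `tau`, and the eleven summary statistics of [window_stats()].
#' @export
simulate_training_replicate <- function(model = c("kingman", "mmc"), params,
                                        demog = NULL, psi_prior = psi_model(),
                                        window_size = 1e4, seed,
                                        max_restarts = 10000) {
  model <- match.arg(model)
  stopifnot(inherits(params, "sim_params"))
  params <- scale_params(params)
  d <- resolve_demog(demog, params$N)
  if (model == "kingman") {
    tau <- with_seed(seed, floor(runif(1, 0, d$tau_max + 1)))
    r <- sim_replicate_raw(params, d$beta, d$duration, 0L, 0, 0, 0, 0L, tau,
                           seed, L = window_size, max_restarts = max_restarts)
    psi <- NA_real_
  } else {
    draws <- with_seed(seed, list(
      psi = if (is.null(psi_prior$psi))
        runif(1, psi_prior$prior_low, psi_prior$prior_high)
      else psi_prior$psi,
      # one of 21 time points: fixation itself, or one of 20 uniform times
      tau = if (runif(1) < 1 / 21) 0 else floor(runif(1, 0, d$tau_max + 1))
    ))
    psi <- draws$psi
    r <- sim_replicate_raw(params, d$beta, d$duration, 2L, 0, 0, psi,
                           window_size %/% 2, draws$tau, seed,
                           L = window_size, max_restarts = max_restarts)
    tau <- draws$tau
  }
  m <- hap_matrix(r$matrix, r$positions, c(0L, as.integer(window_size)))
  out <- window_stats(m)
  tibble::tibble(model = model, psi = psi, tau = tau, out)
}

#' Simulate a labelled training set
#'
#' Generates `n_per_model` Kingman and `n_per_model` MMC training replicates
#' under a common demographic history, with deterministic per-replicate child
#' seeds derived from `seed`.
#'
#' @inheritParams simulate_training_replicate
#' @param n_per_model Replicates per model.
#' @param progress Print a dot every 200 replicates.
#' @return A tibble with one row per replicate (`model`, `psi`, `tau`, the
#'   eleven statistics, `degenerate`), suitable for [abc_training()].
#' @export
simulate_training_set <- function(params, demog = NULL,
                                  psi_prior = psi_model(),
                                  n_per_model = 2000, window_size = 1e4,
                                  seed, progress = FALSE) {
  seeds <- derive_seeds(seed, 2 * n_per_model)
  one <- function(i) {
    model <- if (i <= n_per_model) "kingman" else "mmc"
    if (progress && i %% 200 == 0) cat(".")
    simulate_training_replicate(model, params, demog, psi_prior,
                                window_size, seeds[i])
  }
  out <- dplyr::bind_rows(lapply(seq_len(2 * n_per_model), one))
  if (progress) cat("\n")
  out
}
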