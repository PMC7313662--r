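#' Population-genetic simulation parameters
#'
#' Bundles the parameters of the forward Wright-Fisher engine: diploid
#' population size, per-site mutation and recombination rates, chromosome
#' length, an optional rescaling factor, and the haplotype sample size.
#'
#' @param N Diploid population size (individuals), `>= 2`.
#' @param mu Mutation rate per site per generation.
#' @param rho Recombination rate per site per generation.
#' @param L Chromosome length in base pairs.
#' @param lam Rescaling factor `lambda >= 1`; see [scale_params()].
#' @param n_sample Number of haplotypes drawn when sampling, in `[2, 2N]`
#'   (default 40, capped at `2N`).
#' @param seed Optional default seed attached to the parameter set.
#' @return An object of class `sim_params`.
#' @seealso [scale_params()], [desk_params()]
#' @export
#' @examples
#' sim_params(N = 1e4, mu = 1.2e-8, rho = 1e-8, L = 5e6, lam = 2)
sim_params <- function(N, mu, rho, L, lam = 1, n_sample = min(40, 2 * N),
                       seed = NA_integer_) {
  stopifnot(N >= 2, mu >= 0, rho >= 0, L >= 1, lam >= 1)
  if (n_sample < 2 || n_sample > 2 * N)
    abort("`n_sample` must lie in [2, 2N]")
  structure(
    list(N = as.integer(N), mu = mu, rho = rho, L = as.integer(L),
         lam = lam, n_sample = as.integer(n_sample), seed = seed),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> N = %d, mu = %g, rho = %g, L = %d bp, lambda = %g, n_sample = %d\n",
    x$N, x$mu, x$rho, x$L, x$lam, x$n_sample))
  cat(sprintf("  theta = 4*N*mu*L = %g, 4*N*rho*L = %g\n",
              4 * x$N * x$mu * x$L, 4 * x$N * x$rho * x$L))
  invisible(x)
}

#' Rescale simulation parameters by lambda
#'
#' Applies the standard population-genetic rescaling used to shrink runtime:
#' `N -> round(N / lambda)`, `mu -> mu * lambda`, `rho -> rho * lambda`.
#' The compound parameters `theta = 4*N*mu*L` and `4*N*rho*L` are preserved,
#' while times in generations contract by `lambda`. After scaling, `lam` is
#' reset to 1 so that scaling is not applied twice.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_params` object with scaled `N`, `mu`, `rho`.
#' @export
#' @examples
#' scale_params(sim_params(N = 1e4, mu = 1.2e-8, rho = 1e-8, L = 5e6, lam = 2))
scale_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  lam <- params$lam
  if (lam == 1) return(params)
  N2 <- round(params$N / lam)
  if (N2 < 2) abort("invalid scaling: round(N / lambda) < 2")
  sim_params(N = N2, mu = params$mu * lam, rho = params$rho * lam,
             L = params$L, lam = 1, n_sample = min(params$n_sample, 2 * N2),
             seed = params$seed)
}

#' Demographic history descriptor
#'
#' Either a constant-size (equilibrium) history or a single instantaneous
#' bottleneck: the population is reduced to `round(beta * N)` individuals for
#' `duration` generations and then recovers instantaneously to `N`.
#'
#' @param kind `"equilibrium"` or `"bottleneck"`.
#' @param beta Bottleneck severity as a fraction of `N` (`0 < beta <= 1`).
#' @param duration Bottleneck length in generations. `NULL` means the default
#'   `0.005 * 4N`, resolved against the `N` in use at simulation time.
#' @param t_b Bottleneck start time in units of `4N` generations before the
#'   sampling epoch. In forward simulations the bottleneck is placed at the
#'   end of the burn-in, so `t_b` is emergent rather than prescribed; the
#'   field is retained for configuration round-trips.
#' @param tau_max Maximum post-event neutral sampling time in generations for
#'   neutral replicates. `NULL` means "the fixation time of the weakest sweep
#'   considered", see [tau_max_default()].
#' @return An object of class `demography_model`.
#' @export
#' @examples
#' demography_model("bottleneck", beta = 0.02)
demography_model <- function(kind = c("equilibrium", "bottleneck"), beta = 1,
                             duration = NULL, t_b = NA_real_, tau_max = NULL) {
  kind <- match.arg(kind)
  if (kind == "equilibrium") {
    beta <- 1
    duration <- 0
  } else {
    if (!(beta > 0 && beta <= 1)) abort("`beta` must lie in (0, 1]")
    if (!is.null(duration) && duration < 1)
      abort("bottleneck `duration` must be at least 1 generation")
  }
  if (!is.null(tau_max) && tau_max < 0) abort("`tau_max` must be >= 0")
  structure(list(kind = kind, beta = beta, duration = duration, t_b = t_b,
                 tau_max = tau_max),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  if (x$kind == "equilibrium") {
    cat("<demography_model> equilibrium (constant N)\n")
  } else {
    cat(sprintf("<demography_model> bottleneck: beta = %g, duration = %s generations\n",
                x$beta,
                if (is.null(x$duration)) "0.005 * 4N (default)" else format(x$duration)))
  }
  invisible(x)
}

#' Selective sweep descriptor
#'
#' A single de novo beneficial mutation with diploid fitnesses
#' `1 : 1 + h s : 1 + s`. Sweeps are conditioned on fixation: replicates in
#' which the beneficial allele is lost are restarted.
#'
#' @param s Selection coefficient, `> 0`. The conventional scaled strength is
#'   `2 N s` at the simulated `N`.
#' @param position 0-based site of the beneficial mutation; `NULL` means the
#'   chromosome midpoint `floor(L / 2)`.
#' @param dominance Dominance coefficient `h`; the default 0.5 gives genic
#'   (semidominant) selection.
#' @param condition_on_fixation Restart lost replicates so that all retained
#'   replicates end at allele frequency 1.
#' @return An object of class `selection_model`.
#' @export
#' @examples
#' selection_model(s = 0.1)           # 2Ns = 100 at N = 500
selection_model <- function(s, position = NULL, dominance = 0.5,
                            condition_on_fixation = TRUE) {
  stopifnot(s > 0, dominance >= 0)
  if (!is.null(position) && position < 0) abort("`position` must be >= 0")
  structure(list(s = s, position = position, dominance = dominance,
                 condition_on_fixation = condition_on_fixation),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> s = %g, h = %g, position = %s\n",
              x$s, x$dominance,
              if (is.null(x$position)) "floor(L/2)" else format(x$position)))
  invisible(x)
}

#' Sweepstakes (psi) reproduction descriptor
#'
#' Under the psi (Eldon-Wakeley) model a single individual occasionally
#' contributes a fraction `psi` of the next generation, producing
#' multiple-merger genealogies. Here psi episodes run each generation of a
#' "psi phase" that tracks a focal neutral mutation m2 until its fixation.
#'
#' @param psi A fixed psi value, or `NULL` to draw from the uniform prior.
#' @param prior_low,prior_high Bounds of the uniform prior on psi.
#' @return An object of class `psi_model`.
#' @seealso [rescale_psi_prior()]
#' @export
#' @examples
#' psi_model()                         # the U[0.004, 0.08] prior
psi_model <- function(psi = NULL, prior_low = 0.004, prior_high = 0.08) {
  stopifnot(prior_low > 0, prior_high < 1, prior_low <= prior_high)
  if (!is.null(psi) && !(psi > 0 && psi < 1))
    abort("`psi` must lie in (0, 1)")
  structure(list(psi = psi, prior_low = prior_low, prior_high = prior_high),
            class = "psi_model")
}

#' @export
print.psi_model <- function(x, ...) {
  cat(sprintf("<psi_model> psi = %s, prior = U[%g, %g]\n",
              if (is.null(x$psi)) "~prior" else format(x$psi),
              x$prior_low, x$prior_high))
  invisible(x)
}

#' Rescale a psi prior to a different population size
#'
#' The genealogical weight of sweepstakes events relative to ordinary drift
#' scales as `2 N psi^2`, so preserving the multiple-merger intensity when
#' shrinking a reference population of size `N_ref` down to `N` requires
#' `psi -> psi * sqrt(N_ref / N)`.
#'
#' @param prior A [psi_model()].
#' @param N_ref Reference population size at which the prior bounds are stated.
#' @param N Population size actually simulated.
#' @return A rescaled `psi_model` (bounds capped below 0.5).
#' @export
#' @examples
#' rescale_psi_prior(psi_model(), N_ref = 5000, N = 500)
rescale_psi_prior <- function(prior, N_ref, N) {
  f <- sqrt(N_ref / N)
  psi_model(psi = if (is.null(prior$psi)) NULL else min(prior$psi * f, 0.499),
            prior_low = min(prior$prior_low * f, 0.499),
            prior_high = min(prior$prior_high * f, 0.499))
}

#' Draw psi values from the prior
#'
#' @param prior A [psi_model()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of psi values. A fixed `psi` in the model is
#'   recycled instead of drawn.
#' @export
draw_psi <- function(prior, n, seed) {
  if (!is.null(prior$psi)) return(rep(prior$psi, n))
  with_seed(seed, runif(n, prior$prior_low, prior$prior_high))
}

#' Default maximum post-event sampling time
#'
#' Neutral replicates are sampled at a time `tau ~ U[0, tau_max]` after the
#' demographic event, where `tau_max` is the expected fixation time of the
#' weakest beneficial mutation considered: approximately
#' `4 * log(2N) / s_min` generations for semidominant selection. This makes
#' neutral and fixation-conditioned sweep replicates comparable, since both
#' then cover the same distribution of post-event sampling times.
#'
#' @param N Diploid population size.
#' @param two_Ns_min Weakest scaled selection strength considered (default 100).
#' @return Number of generations (integer).
#' @export
#' @examples
#' tau_max_default(500)
tau_max_default <- function(N, two_Ns_min = 100) {
  s_min <- two_Ns_min / (2 * N)
  as.integer(ceiling(4 * log(2 * N) / s_min))
}

#' Desk-scale parameter profile
#'
#' A reduced problem size for interactive use and testing: it preserves the
#' scaled sweep strengths `2Ns`, the bottleneck severities `beta` and the
#' bottleneck intensity (duration over `2 * beta * N`), while shrinking the
#' population, the chromosome, and the window. Mutation and recombination
#' rates are set so a 10-kb window has `4*N*mu*w = 24` and `4*N*rho*w = 20`,
#' giving on the order of 85 segregating sites per sampled window.
#'
#' @param N Diploid population size (default 500).
#' @param L Observed chromosome length in bp (default 50 kb).
#' @return A `sim_params` object with `n_sample = 20`.
#' @export
#' @examples
#' desk_params()
desk_params <- function(N = 500, L = 5e4) {
  sim_params(N = N, mu = 6e-4 / N, rho = 5e-4 / N, L = L, lam = 1,
             n_sample = 20)
}
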