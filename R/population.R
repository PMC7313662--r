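# Granular forward-simulation operations. A population is an R-side value
# object (list of haplotypes as sorted derived-allele positions plus a
# variant table); each operation round-trips it through the C++ engine.
# Bulk pipelines should prefer simulate_observed() / simulate_training_set(),
# which stay inside C++ for a whole replicate.

new_wf_population <- function(state) {
  structure(state, class = "wf_population")
}

#' Initialise a monomorphic Wright-Fisher population
#'
#' @param N Diploid population size.
#' @param L Chromosome length in base pairs.
#' @return A `wf_population`: `2N` haplotypes carrying no derived alleles,
#'   generation counter 0.
#' @export
#' @examples
#' pop <- new_population(10, 1000)
new_population <- function(N, L) {
  stopifnot(N >= 2, L >= 1)
  new_wf_population(cpp_pop_new(as.integer(N), as.integer(L)))
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("<wf_population> %d haplotypes, L = %d bp, generation %d, %d variants%s\n",
              length(x$haplotypes), x$L, as.integer(x$generation),
              length(x$variant_pos),
              if (x$tracked >= 0) sprintf(", tracked allele at %d", x$tracked) else ""))
  invisible(x)
}

#' Neutral burn-in
#'
#' Runs `10 * N` generations of neutral Wright-Fisher reproduction (mutation
#' and recombination, no selection) so the population reaches
#' mutation-drift equilibrium before any scenario is applied.
#'
#' @param pop A `wf_population`.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param generations Override for the number of generations (default `10 N`).
#' @return The evolved `wf_population`.
#' @export
burn_in <- function(pop, params, seed, generations = 10 * params$N) {
  stopifnot(inherits(pop, "wf_population"))
  new_wf_population(cpp_pop_evolve(unclass(pop), as.double(generations),
                                   params$mu, params$rho, as.double(seed)))
}

#' One Wright-Fisher generation
#'
#' Forms the next generation of `2N` haplotypes: diploid parents are sampled
#' (fitness-weighted `1 : 1+hs : 1+s` on the tracked beneficial genotype when
#' `selection` is given), each transmits one recombinant gamete, and new
#' mutations arrive at rate `mu` per site per gamete.
#'
#' @inheritParams burn_in
#' @param selection A [selection_model()] acting on the tracked allele, or
#'   `NULL` for neutrality.
#' @param next_N Diploid size of the offspring generation (defaults to the
#'   current size; used for instantaneous size changes).
#' @return The next-generation `wf_population`.
#' @export
wf_generation <- function(pop, params, selection = NULL, seed,
                          next_N = length(pop$haplotypes) / 2) {
  stopifnot(inherits(pop, "wf_population"))
  s <- if (is.null(selection)) 0 else selection$s
  h <- if (is.null(selection)) 0 else selection$dominance
  new_wf_population(cpp_pop_step(unclass(pop), as.integer(next_N), params$mu,
                                 params$rho, s, h, 0L, as.double(seed)))
}

#' One generation of sweepstakes (psi) reproduction
#'
#' One individual carrying the tracked neutral mutation m2, chosen uniformly
#' among carriers, contributes exactly `round(2 N psi)` haplotype slots of
#' the next generation through its recombinant gametes (one per offspring
#' individual); it is withheld from the ordinary parent pool for that
#' generation, mirroring its placement in a separate subpopulation. The
#' remaining slots are filled by standard Wright-Fisher reproduction.
#'
#' @inheritParams burn_in
#' @param psi Fraction of the next generation contributed by the sweepstakes
#'   parent.
#' @return The next-generation `wf_population`.
#' @export
psi_generation <- function(pop, params, psi, seed) {
  stopifnot(inherits(pop, "wf_population"), psi >= 0, psi < 1)
  N <- length(pop$haplotypes) / 2
  k <- round(2 * N * psi)
  if (k > 0) {
    f <- tracked_frequency(pop)
    if (is.na(f) || f <= 0 || f >= 1)
      abort("psi_generation requires a segregating tracked m2 allele")
  }
  new_wf_population(cpp_pop_step(unclass(pop), as.integer(N), params$mu,
                                 params$rho, 0, 0, as.integer(k),
                                 as.double(seed)))
}

#' Introduce the focal tracked mutation
#'
#' Places a new derived allele (the beneficial mutation of a sweep, or the
#' neutral m2 of a psi episode) on one uniformly chosen haplotype. If the
#' requested position is already segregating the next free position to the
#' right is used.
#'
#' @inheritParams burn_in
#' @param position 0-based target site.
#' @return The `wf_population` with a tracked allele at frequency `1 / (2N)`.
#' @export
introduce_mutation <- function(pop, position, seed) {
  stopifnot(inherits(pop, "wf_population"), position >= 0, position < pop$L)
  new_wf_population(cpp_pop_introduce(unclass(pop), as.integer(position),
                                      as.double(seed)))
}

#' Frequency of the tracked allele
#'
#' @param pop A `wf_population`.
#' @return Frequency in `[0, 1]`, or `NA` if no allele is tracked.
#' @export
tracked_frequency <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  cpp_pop_tracked_freq(unclass(pop))
}

#' Run a psi episode to fixation of m2
#'
#' Introduces a neutral tracked mutation m2 and iterates [psi_generation()]
#' until m2 fixes or is lost; on loss the episode restarts from the
#' pre-episode population with a fresh m2, so returned populations always
#' carry the episode to fixation (the restart count is reported).
#'
#' @inheritParams burn_in
#' @param psi Sweepstakes fraction for the episode.
#' @param position 0-based site of m2; `NULL` means `floor(L / 2)`.
#' @param max_restarts Cap on restarts before an error is thrown.
#' @return A list with elements `population` (post-fixation state), `outcome`
#'   (always `"fixed"`), `phase_length` (generations in the successful
#'   episode) and `restarts`.
#' @export
run_psi_phase <- function(pop, params, psi, seed, position = NULL,
                          max_restarts = 10000) {
  stopifnot(inherits(pop, "wf_population"), psi > 0, psi < 1)
  pos <- position %||% (pop$L %/% 2)
  r <- cpp_pop_run_phase(unclass(pop), 2L, params$mu, params$rho, 0, 0, psi,
                         as.integer(pos), as.integer(max_restarts),
                         as.double(seed))
  list(population = new_wf_population(r$state), outcome = "fixed",
       phase_length = r$phase_length, restarts = r$restarts)
}

#' Run a selective sweep to fixation
#'
#' Introduces the beneficial mutation and iterates selected Wright-Fisher
#' generations until fixation, restarting from the pre-sweep population when
#' the allele is lost (conditioning on fixation).
#'
#' @inheritParams run_psi_phase
#' @param selection A [selection_model()].
#' @return A list with `population`, `fixation_generation`, `phase_length`
#'   (generations from introduction to fixation) and `restarts`.
#' @export
run_sweep <- function(pop, params, selection, seed, max_restarts = 10000) {
  stopifnot(inherits(pop, "wf_population"), selection$s > 0)
  pos <- selection$position %||% (pop$L %/% 2)
  r <- cpp_pop_run_phase(unclass(pop), 1L, params$mu, params$rho,
                         selection$s, selection$dominance, 0,
                         as.integer(pos), as.integer(max_restarts),
                         as.double(seed))
  pop2 <- new_wf_population(r$state)
  list(population = pop2, fixation_generation = pop2$generation,
       phase_length = r$phase_length, restarts = r$restarts)
}

#' Apply an instantaneous bottleneck
#'
#' Downsamples the population uniformly to `round(beta * N)` individuals,
#' runs `duration` generations of neutral reproduction at the reduced size,
#' then restores size `N` instantaneously by one round of offspring sampling
#' from the bottlenecked pool.
#'
#' @inheritParams burn_in
#' @param demog A [demography_model()] with `kind = "bottleneck"`.
#' @return The post-recovery `wf_population`.
#' @export
apply_bottleneck <- function(pop, params, demog, seed) {
  stopifnot(inherits(pop, "wf_population"),
            inherits(demog, "demography_model"))
  if (demog$kind != "bottleneck" || demog$beta == 1) return(pop)
  N <- length(pop$haplotypes) / 2
  Nb <- round(demog$beta * N)
  if (Nb < 2) abort("invalid demography: round(beta * N) < 2")
  dur <- demog$duration %||% round(0.005 * 4 * N)
  seeds <- derive_seeds(seed, 3)
  st <- cpp_pop_bottleneck(unclass(pop), as.integer(Nb), as.double(seeds[1]))
  if (dur > 0)
    st <- cpp_pop_evolve(st, as.double(dur), params$mu, params$rho,
                         as.double(seeds[2]))
  st <- cpp_pop_step(st, as.integer(N), params$mu, params$rho, 0, 0, 0L,
                     as.double(seeds[3]))
  new_wf_population(st)
}

#' Sample haplotypes from a population
#'
#' Draws `n_sample` haplotypes uniformly without replacement and returns the
#' binary derived-allele matrix at sites segregating within the sample
#' (sample-monomorphic variants, including population-fixed ones, are
#' dropped), restricted to `span`.
#'
#' @param pop A `wf_population`.
#' @param n_sample Number of haplotypes to draw.
#' @param seed Integer seed.
#' @param span Half-open 0-based interval `c(start, end)`; default the whole
#'   chromosome.
#' @return A [hap_matrix()].
#' @export
sample_haplotypes <- function(pop, n_sample, seed, span = NULL) {
  stopifnot(inherits(pop, "wf_population"))
  if (n_sample > length(pop$haplotypes))
    abort("`n_sample` exceeds the number of haplotypes (2N)")
  span <- span %||% c(0L, pop$L)
  r <- cpp_pop_sample(unclass(pop), as.integer(n_sample),
                      as.integer(span[1]), as.integer(span[2]),
                      as.double(seed))
  hap_matrix(r$matrix, r$positions, span)
}
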