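# The eleven summary statistics used for model choice, computed on a binary
# haplotype matrix with known ancestral states (unfolded). Frequencies are
# always of the derived allele; pi and S are reported per window, not per
# site, matching how the ABC layer consumes them.

#' Names of the summary statistics, in their canonical order
#'
#' The order matters: correlation pruning iterates columns in exactly this
#' order, so it is part of the method's definition.
#'
#' @return Character vector of length 11.
#' @export
summary_stat_names <- function() {
  c("S", "pi", "tajimas_d", "fu_li_d", "fu_li_f", "hap_div",
    "walls_b", "walls_q", "rozas_za", "rozas_zz", "kellys_zns")
}

#' Segregating sites, nucleotide diversity, haplotype diversity
#'
#' `S` is the number of segregating sites; `pi` the mean number of pairwise
#' differences, computed from derived-allele frequencies as
#' `sum(2 p (1 - p)) * n / (n - 1)`; `hap_div` the sample haplotype diversity
#' `n / (n - 1) * (1 - sum(f_k^2))` over distinct haplotype strings.
#'
#' @param m A [hap_matrix()] or 0/1 matrix (haplotypes in rows).
#' @return Named list with `S`, `pi`, `hap_div`.
#' @export
#' @examples
#' m <- rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 1))
#' basic_stats(m)   # S = 2, pi = 7/6, hap_div = 5/6
basic_stats <- function(m) {
  n <- nrow(m)
  stopifnot(n >= 2)
  S <- ncol(m)
  if (S == 0) return(list(S = 0L, pi = 0, hap_div = 0))
  p <- colMeans(m)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  key <- apply(m, 1, paste, collapse = "")
  f <- table(key) / n
  hap_div <- n / (n - 1) * (1 - sum(f^2))
  list(S = S, pi = pi, hap_div = hap_div)
}

# harmonic-number helpers shared by the frequency-spectrum tests
a_harmonic <- function(k) sum(1 / seq_len(k))

#' Tajima's D
#'
#' The standardised difference between pi (pairwise estimator of theta) and
#' S / a1 (Watterson's estimator), with Tajima's (1989) variance constants.
#'
#' @inheritParams basic_stats
#' @return A single numeric value; `NA` when `S = 0` (degenerate).
#' @export
tajimas_d <- function(m) {
  n <- nrow(m)
  S <- ncol(m)
  if (S < 1 || n < 4) return(NA_real_)
  a1 <- a_harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  p <- colMeans(m)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D and F (unfolded, outgroup known)
#'
#' Uses the number of derived singletons (mutations on external branches,
#' `eta_s`) against the total number of segregating mutations `eta`, with the
#' corrected normalising constants of the original test:
#' `D = (eta - a_n eta_s) / sqrt(u_D eta + v_D eta^2)` and
#' `F = (pi - eta_s) / sqrt(u_F eta + v_F eta^2)`. Ancestral states are known
#' from the simulation, so the singleton count is the unfolded one.
#'
#' @inheritParams basic_stats
#' @return Named list with `fu_li_d`, `fu_li_f`; both `NA` when `S = 0`.
#' @export
fu_li_d_f <- function(m) {
  n <- nrow(m)
  S <- ncol(m)
  if (S < 1 || n < 4) return(list(fu_li_d = NA_real_, fu_li_f = NA_real_))
  an <- a_harmonic(n - 1)
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- a_harmonic(n)
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  eta <- S
  eta_s <- sum(colSums(m) == 1)
  p <- colMeans(m)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  list(fu_li_d = (eta - an * eta_s) / sqrt(uD * eta + vD * eta^2),
       fu_li_f = (pi - eta_s) / sqrt(uF * eta + vF * eta^2))
}

# canonical bipartition key of a 0/1 column: flip so the first entry is 0
partition_key <- function(col) {
  if (col[1] == 1) col <- 1L - col
  paste(col, collapse = "")
}

#' Wall's B and Q
#'
#' A pair of adjacent segregating sites is congruent when the two columns
#' induce the same bipartition of the sample (identical or complementary 0/1
#' labellings). `B = B' / (S - 1)` with `B'` the number of congruent adjacent
#' pairs; `Q = (B' + A) / S` with `A` the number of distinct bipartitions
#' among congruent pairs.
#'
#' @inheritParams basic_stats
#' @return Named list with `walls_b` (`NA` when `S < 2`) and `walls_q`
#'   (`NA` when `S < 1`).
#' @export
walls_b_q <- function(m) {
  n <- nrow(m)
  S <- ncol(m)
  if (S < 1) return(list(walls_b = NA_real_, walls_q = NA_real_))
  if (S == 1) return(list(walls_b = NA_real_, walls_q = 0))
  left <- m[, -S, drop = FALSE]
  right <- m[, -1, drop = FALSE]
  same <- colSums(left == right) == n
  comp <- colSums(left != right) == n
  congruent <- same | comp
  bprime <- sum(congruent)
  A <- if (bprime > 0) {
    keys <- vapply(which(congruent), function(j) partition_key(m[, j]), "")
    length(unique(keys))
  } else 0L
  list(walls_b = bprime / (S - 1), walls_q = (bprime + A) / S)
}

#' Linkage-disequilibrium statistics: Kelly's ZnS, Rozas's ZA and ZZ
#'
#' `r^2` between two sites is `D^2 / (p_i (1 - p_i) p_j (1 - p_j))` with
#' `D = p_ij - p_i p_j` on derived alleles. `ZnS` averages `r^2` over all
#' site pairs, `ZA` over the `S - 1` adjacent pairs, and `ZZ = ZA - ZnS`.
#'
#' @inheritParams basic_stats
#' @return Named list with `kellys_zns`, `rozas_za`, `rozas_zz`; all `NA`
#'   when `S < 2`.
#' @export
ld_stats <- function(m) {
  n <- nrow(m)
  S <- ncol(m)
  if (S < 2)
    return(list(kellys_zns = NA_real_, rozas_za = NA_real_,
                rozas_zz = NA_real_))
  p <- colMeans(m)
  v <- p * (1 - p)
  D <- crossprod(m) / n - tcrossprod(p)
  r2 <- D^2 / tcrossprod(v)
  zns <- mean(r2[upper.tri(r2)])
  za <- mean(r2[cbind(seq_len(S - 1), seq_len(S - 1) + 1)])
  list(kellys_zns = zns, rozas_za = za, rozas_zz = za - zns)
}

#' All eleven summary statistics for a window
#'
#' Restricts the matrix to the half-open window `[start, end)`, drops sites
#' monomorphic within it, and computes the full panel. `S` and `pi` are
#' per-window totals. Statistics that are undefined at the observed number of
#' segregating sites are `NA` and the row is flagged degenerate when `S = 0`
#' (zero-variation windows are an expected product of strong sweepstakes
#' episodes, so they are kept and handled downstream, not discarded).
#'
#' @param m A [hap_matrix()].
#' @param start,end Window bounds in bp (0-based, half-open); default the
#'   whole span of `m`.
#' @return A one-row tibble: `start`, `end`, the eleven statistics in the
#'   order of [summary_stat_names()], and `degenerate`.
#' @export
#' @examples
#' m <- hap_matrix(rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 1)),
#'                 positions = c(10, 40), span = c(0, 100))
#' window_stats(m)
window_stats <- function(m, start = span(m)[1], end = span(m)[2]) {
  stopifnot(inherits(m, "hap_matrix"))
  w <- window_slice(m, start, end)
  b <- basic_stats(w)
  fl <- fu_li_d_f(w)
  wq <- walls_b_q(w)
  ld <- ld_stats(w)
  tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    S = as.numeric(b$S), pi = b$pi,
    tajimas_d = tajimas_d(w),
    fu_li_d = fl$fu_li_d, fu_li_f = fl$fu_li_f,
    hap_div = b$hap_div,
    walls_b = wq$walls_b, walls_q = wq$walls_q,
    rozas_za = ld$rozas_za, rozas_zz = ld$rozas_zz,
    kellys_zns = ld$kellys_zns,
    degenerate = b$S == 0
  )
}
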