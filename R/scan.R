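# Sliding-window genome scan and the power-evaluation harness.

#' Sliding windows along a chromosome
#'
#' Windows `[k * step, k * step + size)` for `k = 0, 1, ...` while the window
#' end does not pass `L`; a trailing partial window is excluded.
#'
#' @param L Chromosome length in bp.
#' @param size Window size in bp (default 100 kb).
#' @param step Step between window starts in bp (default 50 kb).
#' @return Tibble with `start`, `end` (0-based, half-open).
#' @export
#' @examples
#' nrow(make_windows(5e6, 1e5, 5e4))   # 99 windows
make_windows <- function(L, size = 1e5, step = 5e4) {
  if (size > L) abort("window `size` exceeds chromosome length")
  stopifnot(step >= 1, step <= size)
  starts <- seq(0L, as.integer(L - size), by = as.integer(step))
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(starts + size))
}

#' Scan a chromosome for sweep-like windows
#'
#' Computes the eleven summary statistics in each sliding window,
#' standardizes them with the training parameters, and estimates each
#' window's posterior probability of the MMC model by rejection ABC. If a
#' `threshold` is given, windows are also called sweep-like.
#'
#' @param m A [hap_matrix()] covering the chromosome.
#' @param training An [abc_training()] built at the same window size and
#'   demography.
#' @param size,step Window geometry in bp; the training-region length should
#'   equal `size`.
#' @param tolerance Rejection acceptance fraction (default 0.10).
#' @param threshold Optional neutral threshold from [neutral_threshold()].
#' @return A tibble of class `mmc_scan`: `start`, `end`, `p_mmc`, and `call`
#'   (`NA` until a threshold is applied), with the threshold and window
#'   geometry stored as attributes.
#' @export
scan_chromosome <- function(m, training, size = 1e5, step = 5e4,
                            tolerance = 0.1, threshold = NULL) {
  stopifnot(inherits(m, "hap_matrix"), inherits(training, "abc_training"))
  sp <- span(m)
  win <- make_windows(sp[2] - sp[1], size, step)
  win$start <- win$start + sp[1]
  win$end <- win$end + sp[1]
  stats <- dplyr::bind_rows(
    lapply(seq_len(nrow(win)),
           function(i) window_stats(m, win$start[i], win$end[i])))
  z <- standardize_targets(stats, training)
  post <- posterior_mmc(z, training$stats, training$labels, tolerance)
  out <- tibble::tibble(start = win$start, end = win$end,
                        p_mmc = post$p_mmc, call = NA)
  out <- tibble::new_tibble(out, class = "mmc_scan",
                            tolerance = tolerance, threshold = NA_real_,
                            window_size = size, window_step = step)
  if (!is.null(threshold)) out <- call_sweeps(out, threshold)
  out
}

#' Call sweep-like windows against a neutral threshold
#'
#' @param scan An `mmc_scan` tibble from [scan_chromosome()].
#' @param threshold Neutral credible threshold; a window is sweep-like when
#'   `p_mmc > threshold` (strict).
#' @return The scan with its `call` column set (logical).
#' @export
call_sweeps <- function(scan, threshold) {
  stopifnot(inherits(scan, "mmc_scan"), is.finite(threshold))
  scan$call <- scan$p_mmc > threshold
  attr(scan, "threshold") <- threshold
  scan
}

#' @export
#' @method tidy mmc_scan
tidy.mmc_scan <- function(x, ...) tibble::as_tibble(x)

#' @export
#' @method glance mmc_scan
glance.mmc_scan <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x),
                 n_called = sum(x$call, na.rm = TRUE),
                 threshold = attr(x, "threshold"),
                 tolerance = attr(x, "tolerance"))
}

#' Plot a scan's MMC-posterior track
#'
#' @param object An `mmc_scan`.
#' @param ... Unused.
#' @return A ggplot: per-window MMC posterior against window midpoint, with
#'   the neutral threshold as a dashed line when set.
#' @export
#' @method autoplot mmc_scan
autoplot.mmc_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$p_mmc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position (bp)", y = "P(MMC model)",
                  colour = "sweep-like") +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (is.finite(thr))
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  p
}

#' True- and false-positive rates of the scan
#'
#' A sweep replicate counts as detected when at least one called window
#' overlaps the sweep position (with the default 50% overlap that is at most
#' two windows). The false-positive rate is the fraction of all windows
#' across matched neutral replicates that are called sweep-like.
#'
#' @param sweep_scans List of called `mmc_scan` objects from sweep
#'   replicates.
#' @param sweep_position 0-based bp position of the beneficial mutation.
#' @param neutral_scans Optional list of called `mmc_scan` objects from
#'   matched neutral replicates, for the per-window FPR.
#' @return A one-row tibble of class `mmc_power`: `tpr`, `fpr`,
#'   `n_replicates`, `n_neutral_windows`.
#' @export
evaluate_power <- function(sweep_scans, sweep_position, neutral_scans = NULL) {
  detected <- vapply(sweep_scans, function(sc) {
    hit <- sc$start <= sweep_position & sweep_position < sc$end
    any(sc$call[hit], na.rm = TRUE)
  }, logical(1))
  fpr <- NA_real_
  n_nw <- 0L
  if (!is.null(neutral_scans)) {
    calls <- unlist(lapply(neutral_scans, function(sc) sc$call))
    fpr <- mean(calls, na.rm = TRUE)
    n_nw <- length(calls)
  }
  tibble::new_tibble(
    tibble::tibble(tpr = mean(detected), fpr = fpr,
                   n_replicates = length(sweep_scans),
                   n_neutral_windows = n_nw),
    class = "mmc_power")
}
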