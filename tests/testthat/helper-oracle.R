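# Brute-force reference implementations of the eleven summary statistics,
# written by direct enumeration (all haplotype pairs, all site pairs,
# explicit partition comparison) and kept deliberately independent of the
# package's vectorised code paths.

oracle_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

oracle_hap_div <- function(m) {
  n <- nrow(m)
  keys <- apply(m, 1, paste, collapse = "|")
  f <- as.numeric(table(keys)) / n
  n / (n - 1) * (1 - sum(f^2))
}

oracle_tajimas_d <- function(m) {
  n <- nrow(m)
  S <- ncol(m)
  if (S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (oracle_pi(m) - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

oracle_fu_li <- function(m) {
  n <- nrow(m)
  S <- ncol(m)
  if (S < 1) return(list(d = NA_real_, f = NA_real_))
  i <- seq_len(n - 1)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  eta_s <- 0
  for (j in seq_len(S)) if (sum(m[, j]) == 1) eta_s <- eta_s + 1
  list(d = (S - an * eta_s) / sqrt(uD * S + vD * S^2),
       f = (oracle_pi(m) - eta_s) / sqrt(uF * S + vF * S^2))
}

# partition of the sample induced by a 0/1 column, as an unordered pair of
# row-index sets
oracle_partition <- function(col) {
  a <- which(col == 0)
  b <- which(col == 1)
  sets <- list(a, b)
  ord <- order(vapply(sets, function(s) paste(s, collapse = ","), ""))
  paste(vapply(sets[ord], function(s) paste(s, collapse = ","), ""),
        collapse = ";")
}

oracle_walls <- function(m) {
  S <- ncol(m)
  if (S < 1) return(list(b = NA_real_, q = NA_real_))
  if (S == 1) return(list(b = NA_real_, q = 0))
  parts <- vapply(seq_len(S), function(j) oracle_partition(m[, j]), "")
  congruent_parts <- character(0)
  bprime <- 0
  for (j in seq_len(S - 1)) {
    if (parts[j] == parts[j + 1]) {
      bprime <- bprime + 1
      congruent_parts <- c(congruent_parts, parts[j])
    }
  }
  list(b = bprime / (S - 1),
       q = (bprime + length(unique(congruent_parts))) / S)
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  pa <- sum(x) / n
  pb <- sum(y) / n
  pab <- sum(x == 1 & y == 1) / n
  d <- pab - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

oracle_ld <- function(m) {
  S <- ncol(m)
  if (S < 2) return(list(zns = NA_real_, za = NA_real_, zz = NA_real_))
  vals <- c()
  for (i in seq_len(S - 1))
    for (j in (i + 1):S)
      vals <- c(vals, oracle_r2(m[, i], m[, j]))
  zns <- mean(vals)
  za <- mean(vapply(seq_len(S - 1),
                    function(i) oracle_r2(m[, i], m[, i + 1]), 0))
  list(zns = zns, za = za, zz = za - zns)
}

# random polymorphic haplotype matrix (every column segregating)
random_hap_matrix <- function(n = NULL, S = NULL, span_len = 1000) {
  n <- n %||% sample(4:10, 1)
  S <- S %||% sample(0:8, 1)
  draw_col <- function() {
    repeat {
      p <- runif(1, 0.1, 0.9)
      col <- rbinom(n, 1, p)
      if (sum(col) > 0 && sum(col) < n) return(col)
    }
  }
  m <- if (S > 0) vapply(seq_len(S), function(i) draw_col(), integer(n))
       else matrix(0L, n, 0)
  pos <- sort(sample.int(span_len, S)) - 1L
  hap_matrix(m, pos, c(0L, as.integer(span_len)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the worked four-haplotype example used across the statistic tests
example_matrix <- function() {
  hap_matrix(rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L)),
             positions = c(100L, 200L), span = c(0L, 1000L))
}
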