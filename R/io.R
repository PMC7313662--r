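# File formats: ms-dialect haplotype blocks, TSV/BED artifacts, optional
# phased-VCF input, and the YAML run configuration.

#' Write haplotype matrices in ms format
#'
#' Each matrix becomes one `//` block with `segsites:` and `positions:` lines
#' (positions as fractions of the span) followed by one 0/1 row per
#' haplotype. A header line records the span and provenance (seed), so the
#' file round-trips through [read_ms()] at 1-bp resolution.
#'
#' @param x A [hap_matrix()] or list of them (all with the same span).
#' @param path Output file.
#' @param seed Optional provenance seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_ms <- function(x, path, seed = NA) {
  if (inherits(x, "hap_matrix")) x <- list(x)
  stopifnot(length(x) >= 1, all(vapply(x, inherits, TRUE, "hap_matrix")))
  sp <- span(x[[1]])
  n <- nrow(x[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("mmcscan %d %d", n, length(x)), con)
  writeLines(sprintf("# span: %d %d seed: %s", sp[1], sp[2], format(seed)),
             con)
  len <- sp[2] - sp[1]
  for (m in x) {
    if (!identical(span(m), sp)) abort("all matrices must share one span")
    writeLines("", con)
    writeLines("//", con)
    S <- ncol(m)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      frac <- (positions(m) - sp[1]) / len
      writeLines(paste("positions:",
                       paste(sprintf("%.10f", frac), collapse = " ")), con)
      writeLines(apply(m, 1, paste, collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read ms-format haplotype matrices
#'
#' Parses the standard ms dialect: blocks introduced by `//`, a
#' `segsites:` line, a `positions:` line with fractions in `[0, 1]`, and one
#' 0/1 row per haplotype. Fractional positions are quantized to base pairs
#' within `span`; quantized positions must be strictly increasing.
#'
#' @param path Input file.
#' @param span Half-open bp interval the fractional positions refer to; when
#'   `NULL` it is taken from a `# span:` header (as written by [write_ms()]).
#' @return A list of [hap_matrix()] objects.
#' @export
read_ms <- function(path, span = NULL) {
  lines <- readLines(path)
  # an ms-style command line ("<cmd> <nsam> <nreps> ...") fixes the number of
  # haplotype rows, which blocks with zero segregating sites cannot convey
  n_expected <- NA_integer_
  tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(tok) >= 3 && !is.na(suppressWarnings(as.integer(tok[2]))))
    n_expected <- as.integer(tok[2])
  if (is.null(span)) {
    h <- grep("^# span:", lines, value = TRUE)
    if (length(h) == 0)
      abort("no `span` given and no `# span:` header found")
    sp <- as.integer(strsplit(trimws(sub("^# span:", "", h[1])), "\\s+")[[1]][1:2])
    span <- sp
  }
  span <- as.integer(span)
  len <- span[2] - span[1]
  starts <- which(trimws(lines) == "//")
  if (length(starts) == 0) abort("no `//` block found")
  bounds <- c(starts, length(lines) + 1)
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(bounds[b] + 1):(bounds[b + 1] - 1)]
    block <- block[nzchar(trimws(block))]
    segline <- grep("^segsites:", block)
    if (length(segline) != 1)
      abort(sprintf("malformed block %d (line %d): missing `segsites:`",
                    b, starts[b]))
    S <- as.integer(sub("^segsites:\\s*", "", block[segline]))
    if (S == 0) {
      n <- if (!is.na(n_expected)) n_expected else length(block) - segline
      out[[b]] <- hap_matrix(matrix(0L, n, 0), integer(0), span)
      next
    }
    posline <- grep("^positions:", block)
    if (length(posline) != 1)
      abort(sprintf("malformed block %d (line %d): missing `positions:`",
                    b, starts[b]))
    frac <- as.numeric(strsplit(trimws(sub("^positions:", "", block[posline])),
                                "\\s+")[[1]])
    if (length(frac) != S || any(frac < 0) || any(frac > 1))
      abort(sprintf("malformed block %d: positions do not match segsites", b))
    pos <- span[1] + as.integer(round(frac * len))
    pos <- pmin(pos, span[2] - 1L)
    if (any(diff(pos) <= 0))
      abort(sprintf("block %d: positions not strictly increasing after 1-bp quantization", b))
    rows <- block[seq(posline + 1, length(block))]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]])
    }))
    if (ncol(mat) != S)
      abort(sprintf("malformed block %d: row length differs from segsites", b))
    out[[b]] <- hap_matrix(mat, pos, span)
  }
  out
}

#' Write a scan result as BED and TSV
#'
#' BED columns: chrom, start, end, p_mmc, call. A comment header records the
#' threshold, tolerance and provenance.
#'
#' @param scan An `mmc_scan`.
#' @param path Output file (`.bed` layout; use [write_tsv_provenance()] for
#'   general tables).
#' @param chrom Chromosome label for the first column.
#' @param seed,config_hash Provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scan_bed <- function(scan, path, chrom = "chr1", seed = NA,
                           config_hash = NA) {
  stopifnot(inherits(scan, "mmc_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mmcscan threshold: %s tolerance: %s seed: %s config: %s",
                     format(attr(scan, "threshold")),
                     format(attr(scan, "tolerance")),
                     format(seed), format(config_hash)), con)
  df <- data.frame(chrom = chrom, start = scan$start, end = scan$end,
                   p_mmc = scan$p_mmc, call = scan$call)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV with a provenance header
#'
#' @param x Data frame.
#' @param path Output file.
#' @param seed,config_hash Provenance recorded in a `#` comment header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mmcscan seed: %s config: %s", format(seed),
                     format(config_hash)), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_provenance()]
#'
#' @param path Input file.
#' @return A tibble.
#' @export
read_tsv_provenance <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE))
}

#' Serialise / restore an ABC training set
#'
#' The statistics, labels and psi draws go to a TSV; centring, scaling, kept
#' columns, sentinels and provenance go to a YAML sidecar (`<path>.meta.yaml`).
#'
#' @param training An [abc_training()].
#' @param path TSV path.
#' @param seed Provenance seed.
#' @return `path`, invisibly.
#' @export
write_training <- function(training, path, seed = NA) {
  df <- as.data.frame(training$stats)
  df$model <- training$labels
  df$psi <- training$psi
  write_tsv_provenance(df, path, seed = seed)
  meta <- list(kept_columns = as.list(training$kept_columns),
               center = as.list(training$center),
               scale = as.list(training$scale),
               sentinels = as.list(setNames(training$sentinels,
                                            names(training$kept_columns))),
               cor_threshold = training$cor_threshold,
               seed = seed)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_training
#' @export
read_training <- function(path) {
  df <- read_tsv_provenance(path)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  kept <- unlist(meta$kept_columns)
  stats <- as.matrix(df[, names(kept), drop = FALSE])
  structure(
    list(stats = stats, labels = df$model, psi = df$psi,
         kept_columns = kept,
         center = unlist(meta$center), scale = unlist(meta$scale),
         sentinels = unname(unlist(meta$sentinels)),
         cor_threshold = meta$cor_threshold),
    class = "abc_training")
}

#' Read a phased biallelic VCF as a haplotype matrix
#'
#' Maps phased GT fields of a biallelic VCF to a [hap_matrix()] (two
#' haplotypes per sample, ALT coded as derived). Multi-allelic or unphased
#' records are rejected with an error, as are missing genotypes.
#'
#' @param path VCF file (requires the `vcfR` package).
#' @param span Half-open bp interval; default `[0, max position + 1)`.
#' @return A [hap_matrix()].
#' @export
read_vcf_haplotypes <- function(path, span = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    abort("multi-allelic records are not supported; split or filter first")
  gt <- vcfR::extract.gt(v)
  if (any(grepl("/", gt)) || anyNA(gt))
    abort("all genotypes must be phased ('|') and non-missing")
  pos <- as.integer(vcfR::getPOS(v)) - 1L  # VCF is 1-based
  split_gt <- function(row) as.integer(unlist(strsplit(row, "\\|")))
  m <- t(apply(gt, 1, split_gt))           # sites x haplotypes
  m <- t(m)                                # haplotypes x sites
  o <- order(pos)
  pos <- pos[o]
  m <- m[, o, drop = FALSE]
  cnt <- colSums(m)
  poly <- cnt > 0 & cnt < nrow(m)
  m <- m[, poly, drop = FALSE]
  pos <- pos[poly]
  span <- span %||% c(0L, max(pos) + 1L)
  hap_matrix(m, pos, span)
}

# ------------------------------------------------------------- config ----

#' Read and validate a YAML run configuration
#'
#' Expected top-level keys: `population` (N, mu, rho, L, lam, n_sample),
#' `demography` (kind, beta, duration, tau_max), `selection` (two_Ns or s,
#' position, dominance), `psi` (prior_low, prior_high, rescale), `scan`
#' (window, step, tolerance, level), `abc` (n_per_model, cor_threshold,
#' cv_folds), `seeds` (seed), `replicates` (observed, neutral). Component
#' invariants are validated before anything is simulated.
#'
#' @param path YAML file.
#' @return A named list of class `run_config` with constructed parameter
#'   objects and a `hash` for provenance.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(cfg[[key]]))
      abort(sprintf("config error: missing required key '%s'", key))
    cfg[[key]]
  }
  p <- need("population")
  for (k in c("N", "mu", "rho", "L"))
    if (is.null(p[[k]]))
      abort(sprintf("config error: population.%s is required", k))
  params <- sim_params(N = p$N, mu = p$mu, rho = p$rho, L = p$L,
                       lam = p$lam %||% 1, n_sample = p$n_sample %||% 40)
  d <- cfg$demography %||% list(kind = "equilibrium")
  demog <- demography_model(kind = d$kind %||% "equilibrium",
                            beta = d$beta %||% 1,
                            duration = d$duration,
                            tau_max = d$tau_max)
  sel <- NULL
  if (!is.null(cfg$selection)) {
    sN <- scale_params(params)$N
    s <- cfg$selection$s %||% (cfg$selection$two_Ns / (2 * sN))
    sel <- selection_model(s = s, position = cfg$selection$position,
                           dominance = cfg$selection$dominance %||% 0.5)
  }
  ps <- cfg$psi %||% list()
  prior <- psi_model(prior_low = ps$prior_low %||% 0.004,
                     prior_high = ps$prior_high %||% 0.08)
  if (isTRUE(ps$rescale))
    prior <- rescale_psi_prior(prior, N_ref = ps$N_ref %||% 5000,
                               N = scale_params(params)$N)
  sc <- cfg$scan %||% list()
  ab <- cfg$abc %||% list()
  seeds <- need("seeds")
  structure(list(
    params = params, demography = demog, selection = sel, psi_prior = prior,
    window = sc$window %||% 1e5, step = sc$step %||% 5e4,
    tolerance = sc$tolerance %||% 0.1, level = sc$level %||% 0.99,
    n_per_model = ab$n_per_model %||% 2000,
    cor_threshold = ab$cor_threshold %||% 0.8,
    cv_folds = ab$cv_folds %||% 1000,
    seed = seeds$seed %||% 1,
    n_observed = (cfg$replicates %||% list())$observed %||% 20,
    n_neutral = (cfg$replicates %||% list())$neutral %||% 20,
    hash = rlang::hash(cfg)
  ), class = "run_config")
}
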