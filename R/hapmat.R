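#' Binary haplotype matrix
#'
#' The sampled data container: `n` haplotypes by `S` segregating sites, coded
#' 1 for the derived allele (ancestral states are known because simulations
#' track derived mutations), with strictly increasing 0-based base-pair
#' positions inside a half-open span.
#'
#' @param m Integer or logical matrix of 0/1 values, haplotypes in rows.
#' @param positions Integer vector of 0-based site coordinates, strictly
#'   increasing, one per column.
#' @param span Half-open interval `c(start, end)` in bp containing the
#'   positions.
#' @return An object of class `hap_matrix`.
#' @export
#' @examples
#' hap_matrix(rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 1)),
#'            positions = c(10, 40), span = c(0, 100))
hap_matrix <- function(m, positions, span) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  positions <- as.integer(positions)
  span <- as.integer(span)
  if (length(positions) != ncol(m))
    abort("`positions` must have one entry per column")
  if (ncol(m) > 1 && any(diff(positions) <= 0))
    abort("`positions` must be strictly increasing")
  if (length(span) != 2 || span[1] >= span[2])
    abort("`span` must be a half-open interval c(start, end) with start < end")
  if (ncol(m) > 0 && (min(positions) < span[1] || max(positions) >= span[2]))
    abort("positions must lie within `span`")
  if (ncol(m) > 0 && !all(m %in% c(0L, 1L)))
    abort("entries must be 0/1")
  structure(m, positions = positions, span = span,
            class = c("hap_matrix", "matrix", "array"))
}

#' @rdname hap_matrix
#' @param x A `hap_matrix`.
#' @export
positions <- function(x) attr(x, "positions")

#' @rdname hap_matrix
#' @export
span <- function(x) attr(x, "span")

#' @export
print.hap_matrix <- function(x, ...) {
  sp <- span(x)
  cat(sprintf("<hap_matrix> %d haplotypes x %d segregating sites, span [%d, %d)\n",
              nrow(x), ncol(x), sp[1], sp[2]))
  if (ncol(x) > 0) {
    k <- min(ncol(x), 8)
    cat("  positions:", paste(head(positions(x), k), collapse = " "),
        if (ncol(x) > k) "...\n" else "\n")
  }
  invisible(x)
}

#' @export
as.matrix.hap_matrix <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Restrict a hap_matrix to a half-open window, dropping sites monomorphic
# within the (unchanged) sample.
window_slice <- function(m, start, end) {
  pos <- positions(m)
  keep <- which(pos >= start & pos < end)
  sub <- m[, keep, drop = FALSE]
  if (length(keep)) {
    cnt <- colSums(sub)
    poly <- cnt > 0 & cnt < nrow(sub)
    sub <- sub[, poly, drop = FALSE]
    keep <- keep[poly]
  }
  hap_matrix(sub, pos[keep], c(start, end))
}
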