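#' One-dimensional chain clustering (DBSCAN with min_samples = 1)
#'
#' With `min_samples = 1`, DBSCAN on one-dimensional points reduces to
#' single-linkage chaining: two points belong to the same cluster when they
#' can be connected by steps of at most `eps`. Cluster ids are assigned in
#' order of increasing position.
#'
#' @param positions Numeric vector of 1-D coordinates.
#' @param eps Maximum gap (same units as `positions`) joining neighbours.
#' @return Integer vector of cluster ids, parallel to `positions`.
#' @examples
#' chain_cluster_1d(c(100, 550, 2000), eps = 500)
#' @export
chain_cluster_1d <- function(positions, eps = 500) {
  stopifnot(is.numeric(positions), eps >= 0)
  n <- length(positions)
  if (n == 0L) return(integer(0))
  ord <- order(positions)
  sorted <- positions[ord]
  breaks <- c(FALSE, diff(sorted) > eps)
  ids_sorted <- cumsum(breaks) + 1L
  ids <- integer(n)
  ids[ord] <- ids_sorted
  ids
}

#' Linear-interpolation percentile
#'
#' Thin wrapper around [stats::quantile()] type 7 (linear interpolation,
#' inclusive), the convention used for every percentile threshold in the
#' package (bit-score retention, coordinate-difference threshold,
#' control-gene floor). Recorded here so all callers share one method.
#'
#' @param x Numeric vector.
#' @param p Probability in \[0, 1\].
#' @return The percentile as a single number.
#' @export
percentile <- function(x, p) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1)
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of raw p-values (NA allowed; kept as NA).
#' @return Adjusted p-values.
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Internal: deterministic RNG scope. Evaluates `expr` with the supplied seed
# without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Internal: stopifnot with formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
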