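# Hilbert curve index arithmetic.
#
# Coordinate convention (recorded in all export metadata): x is the column,
# y is the row, origin at the top-left of the rendered image.  The level-1
# curve visits (0,0) -> (0,1) -> (1,1) -> (1,0), a "U" opening upward in
# image coordinates; higher levels derive from it by the standard quadrant
# rotations.  Implemented with iterative bitwise transforms so high levels
# stay cheap; the recursive subdivision definition is kept in the test
# suite as an independent oracle.

#' Validate a Hilbert curve level
#'
#' A level-`k` Hilbert curve fills a `2^k` by `2^k` grid, visiting each of
#' its `4^k` cells exactly once.
#'
#' @param k Curve level, a single integer `>= 1`.
#' @return `k` as an integer, invisibly usable downstream.
#' @keywords internal
check_level <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != floor(k)) {
    rlang::abort("`k` must be a single integer >= 1.", class = "micromaps_domain_error")
  }
  as.integer(k)
}

#' Minimal curve level for a collection
#'
#' Returns the smallest level `k` such that the `2^k` by `2^k` grid has at
#' least `n_taxa` cells, i.e. the minimal `k` with `4^k >= n_taxa`.  A
#' reference collection rarely matches a power of four exactly; the layout
#' stage absorbs the surplus by merging adjacent curve segments.
#'
#' @param n_taxa Number of taxa to place, a single integer `>= 1`.
#' @return A single integer level (always `>= 1`).
#' @examples
#' hilbert_level(16)    # 2: 4^2 = 16 exactly
#' hilbert_level(44048) # 8
#' @export
hilbert_level <- function(n_taxa) {
  if (length(n_taxa) != 1L || !is.finite(n_taxa) || n_taxa < 1 ||
      n_taxa != floor(n_taxa)) {
    rlang::abort("`n_taxa` must be a single integer >= 1.",
                 class = "micromaps_domain_error")
  }
  k <- 1L
  while (4^k < n_taxa) k <- k + 1L
  k
}

#' Convert curve indices to grid cells
#'
#' Maps distances along the level-`k` Hilbert curve to 0-based `(x, y)`
#' grid coordinates.  The map is a bijection from `0:(4^k - 1)` onto the
#' `2^k` by `2^k` grid, and consecutive indices always land in
#' edge-adjacent cells.
#'
#' @param k Curve level (`>= 1`).
#' @param d Integer vector of curve indices, each in `0:(4^k - 1)`.
#' @return A tibble with columns `d`, `x`, `y` (one row per input index).
#' @examples
#' hilbert_cell(1, 0:3)
#' @export
hilbert_cell <- function(k, d) {
  k <- check_level(k)
  n_cells <- 4^k
  if (length(d) == 0L) {
    return(tibble::tibble(d = integer(), x = integer(), y = integer()))
  }
  if (any(!is.finite(d) | d < 0 | d >= n_cells | d != floor(d))) {
    rlang::abort(
      sprintf("curve indices must lie in 0..%.0f for level %d.", n_cells - 1, k),
      class = "micromaps_domain_error"
    )
  }
  # doubles are exact for the integer ranges in play (k <= 26)
  t <- as.numeric(d)
  x <- numeric(length(d))
  y <- numeric(length(d))
  s <- 1
  while (s < 2^k) {
    rx <- (t %/% 2) %% 2
    ry <- (t + rx) %% 2  # t XOR rx for the low bit
    # rotate/flip the quadrant contents built so far
    flip <- ry == 0 & rx == 1
    x[flip] <- s - 1 - x[flip]
    y[flip] <- s - 1 - y[flip]
    swap <- ry == 0
    tmp <- x[swap]
    x[swap] <- y[swap]
    y[swap] <- tmp
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4
    s <- s * 2
  }
  tibble::tibble(d = as.integer(d), x = as.integer(x), y = as.integer(y))
}

#' Convert grid cells to curve indices
#'
#' Inverse of [hilbert_cell()]: for each `(x, y)` cell of the level-`k`
#' grid, returns its distance along the curve.
#'
#' @param k Curve level (`>= 1`).
#' @param x,y Integer vectors of 0-based column and row coordinates, each
#'   in `0:(2^k - 1)`; recycled to common length.
#' @return Integer vector of curve indices.
#' @examples
#' hilbert_index(2, x = 3, y = 0) # 15: the level-2 curve ends at (3, 0)
#' @export
hilbert_index <- function(k, x, y) {
  k <- check_level(k)
  side <- 2^k
  if (length(x) != length(y)) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n)
    y <- rep_len(y, n)
  }
  if (length(x) == 0L) return(integer())
  if (any(!is.finite(x) | !is.finite(y) | x < 0 | y < 0 |
          x >= side | y >= side | x != floor(x) | y != floor(y))) {
    rlang::abort(
      sprintf("cell coordinates must lie in 0..%d for level %d.", side - 1L, k),
      class = "micromaps_domain_error"
    )
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  d <- numeric(length(x))
  s <- side / 2
  while (s >= 1) {
    rx <- as.numeric((x %/% s) %% 2 == 1)
    ry <- as.numeric((y %/% s) %% 2 == 1)
    # quadrant rank along the curve: (3 * rx) XOR ry over bits {0, 1}
    d <- d + s * s * ifelse(rx == 0, ry, 3 - ry)
    # rotate/flip
    flip <- ry == 0 & rx == 1
    x[flip] <- side - 1 - x[flip]
    y[flip] <- side - 1 - y[flip]
    swap <- ry == 0
    tmp <- x[swap]
    x[swap] <- y[swap]
    y[swap] <- tmp
    s <- s / 2
  }
  as.integer(d)
}

#' Enumerate the full curve path
#'
#' Lists every cell of the level-`k` grid in curve order.  Useful for
#' overlaying the curve's path on a map, and for understanding how the 1D
#' taxon order wraps into 2D.
#'
#' @param k Curve level (`>= 1`).
#' @return A tibble with columns `d`, `x`, `y` and `4^k` rows; row `d + 1`
#'   is the `d`-th cell visited, and consecutive rows are edge-adjacent
#'   (Manhattan distance exactly 1).
#' @examples
#' hilbert_path(1) # the four initial squares, in visiting order
#' @export
hilbert_path <- function(k) {
  k <- check_level(k)
  hilbert_cell(k, 0:(4^k - 1))
}
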