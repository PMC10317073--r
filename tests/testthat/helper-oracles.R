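# Independent oracles and small fixture builders shared across tests.

# Recursive-subdivision enumeration of the Hilbert curve, straight from the
# geometric definition: the level-k curve is four level-(k-1) curves, the
# first transposed, the last anti-transposed, connected in the level-1
# "U" order (0,0) -> (0,1) -> (1,1) -> (1,0).  Deliberately independent of
# the package's bitwise implementation.
hilbert_oracle <- function(k) {
  if (k == 0L) return(data.frame(x = 0L, y = 0L))
  p <- hilbert_oracle(k - 1L)
  m <- 2L^(k - 1L)
  rbind(
    data.frame(x = p$y, y = p$x),                       # transpose
    data.frame(x = p$x, y = p$y + m),                   # below-left
    data.frame(x = p$x + m, y = p$y + m),               # below-right
    data.frame(x = 2L * m - 1L - p$y, y = m - 1L - p$x) # anti-transpose
  )
}

# Toy taxonomy shaped like the classic 16-leaf example: 2 genera, each
# with 2 species of 4 strains.
toy_records <- function() micromaps::simulate_taxonomy(2, 2, 4)

# Hand-buildable wide abundance tibble from a named list of sample rows.
abund_tbl <- function(rows) {
  tibble::as_tibble(
    cbind(data.frame(sample_id = names(rows), stringsAsFactors = FALSE),
          do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r)))))
  )
}

# Brute-force boundary edges of a cell set: every unit edge of a member
# cell whose far side is not a member of the same run.
brute_boundary <- function(cells_xy, all_xy_run, side) {
  key <- function(x, y) paste(x, y)
  run_of <- stats::setNames(all_xy_run$run, key(all_xy_run$x, all_xy_run$y))
  edges <- list()
  for (i in seq_len(nrow(cells_xy))) {
    x <- cells_xy$x[i]; y <- cells_xy$y[i]; r <- cells_xy$run[i]
    nb <- list(c(x - 1, y, x, y, x, y + 1), c(x + 1, y, x + 1, y, x + 1, y + 1),
               c(x, y - 1, x, y, x + 1, y), c(x, y + 1, x, y + 1, x + 1, y + 1))
    for (e in nb) {
      other <- run_of[key(e[1], e[2])]
      if (is.na(other) || other != r) {
        edges[[length(edges) + 1L]] <- c(r, e[3], e[4], e[5], e[6])
      }
    }
  }
  out <- as.data.frame(do.call(rbind, edges))
  names(out) <- c("run", "x0", "y0", "x1", "y1")
  out[do.call(order, out), ]
}

sort_edges <- function(e) {
  e <- as.data.frame(e)[c("run", "x0", "y0", "x1", "y1")]
  e[do.call(order, e), , drop = FALSE]
}
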