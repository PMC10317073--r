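# Hilbert layouts: assign each taxon of a linear order a contiguous run of
# curve indices (segment merging), look cells up in both directions, and
# extract microbial-neighborhood geometry.

#' Assign a linear order of taxa to Hilbert curve segments
#'
#' Places the `n` taxa of an order onto the `4^k` curve indices of a
#' level-`k` grid.  When the grid has more cells than taxa, adjacent curve
#' segments are merged so the number of map regions always equals the
#' number of taxa: every taxon receives `floor(4^k / n)` or
#' `ceil(4^k / n)` consecutive indices, with earlier-ordered taxa taking
#' the larger share — a deterministic rule that keeps clade starts aligned
#' with curve starts.  Because the curve is continuous, each taxon's cells
#' form a 4-connected patch, and each clade's patches are contiguous along
#' the curve.
#'
#' With `reserve = TRUE`, blank cells are set aside for future additions
#' to the collection: each top-level group gets an aligned block of
#' `4^g` indices (`g` minimal with `4^g >=` group size), one index per
#' member taxon, the rest reserved, so every following group starts at the
#' boundary of an aligned `2^g` by `2^g` subsquare.
#'
#' @param order An `mm_order` (from [linearize()] or [labeled_order()]),
#'   or any tibble with a `taxon_id` column in the desired order.
#' @param level Curve level; `NULL` (default) picks the minimal level
#'   whose grid holds the order.
#' @param reserve Gap policy flag; off by default.
#' @return An `mm_layout`: a tibble with one row per taxon —
#'   `taxon_id`, `d_start`, `d_end`, `n_cells`, `x_start`, `y_start`, and
#'   any grouping columns of the order — with attributes `level`,
#'   `ordering`, `groups` and `reserve`.
#' @examples
#' lay <- build_layout(linearize(build_taxonomy(simulate_taxonomy(2, 2, 4))))
#' lay
#' @export
build_layout <- function(order, level = NULL, reserve = FALSE) {
  if (!is.data.frame(order) || !"taxon_id" %in% names(order)) {
    rlang::abort("`order` must be a data frame with a taxon_id column.",
                 class = "micromaps_input_error")
  }
  n <- nrow(order)
  if (n == 0L) {
    rlang::abort("`order` has no taxa.", class = "micromaps_input_error")
  }
  groups <- attr(order, "groups")
  ordering <- attr(order, "ordering") %||% "as-given"

  if (reserve) {
    top <- top_level_runs(order, groups)
    sizes <- top$end - top$start + 1L
    g <- vapply(sizes, function(s) hilbert_level(max(s, 1L)), integer(1))
    starts <- numeric(length(sizes))
    cur <- 0
    for (i in seq_along(sizes)) {
      block <- 4^g[i]
      cur <- ceiling(cur / block) * block  # align to the group's subsquare
      starts[i] <- cur
      cur <- cur + sizes[i]
    }
    needed <- starts[length(starts)] + 4^g[length(g)]
    auto_k <- hilbert_level(max(needed, 1))
    if (is.null(level)) level <- auto_k
    level <- check_level(level)
    if (needed > 4^level) {
      rlang::abort(sprintf(
        "%d taxa with reserved gaps need level >= %d (got %d).",
        n, auto_k, level), class = "micromaps_capacity_error")
    }
    d_start <- unlist(purrr::map2(starts, sizes, function(s, sz) s + 0:(sz - 1)))
    d_end <- d_start
  } else {
    if (is.null(level)) level <- hilbert_level(n)
    level <- check_level(level)
    S <- 4^level
    if (n > S) {
      rlang::abort(sprintf(
        "%d taxa exceed the %d cells of a level-%d grid; minimal sufficient level is %d.",
        n, S, level, hilbert_level(n)), class = "micromaps_capacity_error")
    }
    base <- S %/% n
    rem <- S %% n
    len <- rep(base, n)
    if (rem > 0) len[seq_len(rem)] <- base + 1
    d_end <- cumsum(len) - 1
    d_start <- d_end - len + 1
  }

  start_cells <- hilbert_cell(level, d_start)
  keep <- setdiff(names(order), c("position", "d_start", "d_end"))
  out <- tibble::tibble(
    taxon_id = order$taxon_id,
    d_start = as.numeric(d_start),
    d_end = as.numeric(d_end),
    n_cells = as.numeric(d_end - d_start + 1),
    x_start = start_cells$x,
    y_start = start_cells$y
  )
  extra <- setdiff(keep, names(out))
  if (length(extra) > 0L) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(order)[extra])
  }
  structure(out, level = level, ordering = ordering, groups = groups,
            reserve = reserve,
            class = c("mm_layout", class(tibble::tibble())))
}

top_level_runs <- function(order, groups) {
  if (!is.null(groups) && nrow(groups) > 0L) {
    groups[groups$grouping == groups$grouping[1L], , drop = FALSE]
  } else {
    tibble::tibble(grouping = "all", label = "all",
                   start = 1L, end = nrow(order))
  }
}

#' @export
print.mm_layout <- function(x, ...) {
  cat(sprintf(
    "<mm_layout> level %d (%d x %d grid), %d taxa over %.0f cells%s, %s ordering\n",
    attr(x, "level"), 2^attr(x, "level"), 2^attr(x, "level"), nrow(x),
    sum(x$n_cells),
    if (isTRUE(attr(x, "reserve"))) " + reserved gaps" else "",
    attr(x, "ordering")))
  NextMethod()
}

#' Expand a layout to one row per grid cell
#'
#' @param layout An `mm_layout`.
#' @return A tibble with one row per cell of the grid: `d`, `x`, `y`, and
#'   `taxon_id` (`NA` on reserved-gap cells), plus the layout's grouping
#'   columns.
#' @export
layout_cells <- function(layout) {
  stopifnot(inherits(layout, "mm_layout"))
  k <- attr(layout, "level")
  path <- hilbert_path(k)
  idx <- rep(NA_integer_, 4^k)
  d_all <- sequence(layout$n_cells, from = layout$d_start + 1)
  idx[d_all] <- rep(seq_len(nrow(layout)), times = layout$n_cells)
  cells <- path
  cells$taxon_id <- layout$taxon_id[idx]
  extra <- setdiff(names(layout),
                   c("taxon_id", "d_start", "d_end", "n_cells",
                     "x_start", "y_start"))
  for (col in extra) cells[[col]] <- layout[[col]][idx]
  cells
}

#' Cells occupied by one taxon
#'
#' @param layout An `mm_layout`.
#' @param taxon_id A single taxon identifier present in the layout.
#' @return A tibble of the taxon's cells (`d`, `x`, `y`); they are always
#'   4-connected because the curve is continuous.
#' @export
cells_of <- function(layout, taxon_id) {
  stopifnot(inherits(layout, "mm_layout"))
  i <- match(taxon_id, layout$taxon_id)
  if (length(taxon_id) != 1L || is.na(i)) {
    rlang::abort(sprintf("unknown taxon: %s", paste(taxon_id, collapse = ", ")),
                 class = "micromaps_lookup_error")
  }
  hilbert_cell(attr(layout, "level"), layout$d_start[i]:layout$d_end[i])
}

#' Taxon at a grid cell
#'
#' @param layout An `mm_layout`.
#' @param x,y 0-based cell coordinates.
#' @return The taxon_id whose interval covers the cell, or `NA_character_`
#'   for a reserved-gap cell.
#' @export
taxon_at <- function(layout, x, y) {
  stopifnot(inherits(layout, "mm_layout"))
  d <- hilbert_index(attr(layout, "level"), x, y)
  hit <- findInterval(d, layout$d_start)
  out <- rep(NA_character_, length(d))
  ok <- hit >= 1L & d <= layout$d_end[pmax(hit, 1L)]
  out[ok] <- layout$taxon_id[hit[ok]]
  out
}

#' Microbial neighborhoods of a layout
#'
#' A neighborhood is the connected map region holding one contiguous group
#' run — a taxonomic clade or a condition block.  For each run this
#' returns its member cells, its boundary (the unit edges separating a
#' member cell from a non-member or out-of-grid cell, ready to draw), and
#' a label anchor cell (the member cell nearest the region centroid, for
#' captions).  Region size is proportional to the number of member taxa
#' (times their merged-segment share).
#'
#' @param layout An `mm_layout` whose order carried group annotations.
#' @param grouping Which grouping to outline, e.g. `"genus"` or
#'   `"condition"`; must be one of the layout's grouping columns.
#' @return An `mm_neighborhoods` list with tibbles `regions` (`label`,
#'   `run`, `n_taxa`, `n_cells`, `anchor_x`, `anchor_y`), `cells`
#'   (`label`, `run`, `d`, `x`, `y`), and `edges` (`label`, `run`, segment
#'   endpoints `x0`, `y0`, `x1`, `y1` in cell-corner coordinates).
#' @export
neighborhoods <- function(layout, grouping) {
  stopifnot(inherits(layout, "mm_layout"))
  groups <- attr(layout, "groups")
  if (is.null(groups) || !grouping %in% groups$grouping) {
    rlang::abort(sprintf("unknown grouping: %s", grouping),
                 class = "micromaps_input_error")
  }
  runs <- groups[groups$grouping == grouping, , drop = FALSE]
  k <- attr(layout, "level")
  side <- 2^k

  run_cells <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    members <- layout[runs$start[i]:runs$end[i], , drop = FALSE]
    d <- sequence(members$n_cells, from = members$d_start + 1) - 1
    cells <- hilbert_cell(k, d)
    cells$label <- runs$label[i]
    cells$run <- i
    cells
  })

  # membership grid: run id per cell, 0 = unassigned
  grid <- matrix(0L, nrow = side, ncol = side)  # [y+1, x+1]
  grid[cbind(run_cells$y + 1L, run_cells$x + 1L)] <- run_cells$run

  edges <- boundary_edges(run_cells, grid, side)
  edges$label <- runs$label[edges$run]

  regions <- dplyr::group_by(run_cells, .data$run, .data$label)
  regions <- dplyr::summarise(
    regions,
    n_cells = dplyr::n(),
    anchor_x = anchor_coord(.data$x, .data$y)[1L],
    anchor_y = anchor_coord(.data$x, .data$y)[2L],
    .groups = "drop"
  )
  regions$n_taxa <- runs$end[regions$run] - runs$start[regions$run] + 1L
  regions <- dplyr::relocate(regions, "label", "run", "n_taxa", "n_cells")

  structure(list(regions = regions,
                 cells = dplyr::relocate(run_cells, "label", "run"),
                 edges = dplyr::relocate(edges, "label", "run"),
                 grouping = grouping, level = k),
            class = "mm_neighborhoods")
}

# member cell closest to the region centroid
anchor_coord <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  i <- which.min((x - cx)^2 + (y - cy)^2)
  c(x[i], y[i])
}

# unit edges between member cells and out-of-run neighbors, as segments in
# cell-corner coordinates (cell (x, y) spans [x, x+1] x [y, y+1])
boundary_edges <- function(run_cells, grid, side) {
  x <- run_cells$x; y <- run_cells$y; run <- run_cells$run
  neighbor_run <- function(nx, ny) {
    out <- rep(0L, length(nx))
    ok <- nx >= 0 & nx < side & ny >= 0 & ny < side
    out[ok] <- grid[cbind(ny[ok] + 1L, nx[ok] + 1L)]
    out
  }
  seg <- function(sel, x0, y0, x1, y1) {
    tibble::tibble(run = run[sel], x0 = x0[sel], y0 = y0[sel],
                   x1 = x1[sel], y1 = y1[sel])
  }
  dplyr::bind_rows(
    seg(neighbor_run(x - 1L, y) != run, x, y, x, y + 1),        # left
    seg(neighbor_run(x + 1L, y) != run, x + 1, y, x + 1, y + 1), # right
    seg(neighbor_run(x, y - 1L) != run, x, y, x + 1, y),        # top
    seg(neighbor_run(x, y + 1L) != run, x, y + 1, x + 1, y + 1) # bottom
  )
}

#' @export
print.mm_neighborhoods <- function(x, ...) {
  cat(sprintf("<mm_neighborhoods> %d regions by %s on a level-%d grid\n",
              nrow(x$regions), x$grouping, x$level))
  print(x$regions)
  invisible(x)
}

#' Write / read a layout as a portable TSV
#'
#' Persisting the geometry lets the identical map layout be reused across
#' samples and studies, which is what makes cross-sample comparison and
#' animation meaningful.  The level, ordering and gap policy ride along in
#' `# key: value` header comments.
#'
#' @param layout An `mm_layout`.
#' @param path Output / input path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns
#'   the `mm_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "mm_layout"))
  groups <- attr(layout, "groups")
  header <- c(
    sprintf("# level: %d", attr(layout, "level")),
    sprintf("# ordering: %s", attr(layout, "ordering")),
    sprintf("# reserve: %s", attr(layout, "reserve")),
    "# orientation: x=column, y=row, origin top-left; level-1 visits (0,0) (0,1) (1,1) (1,0)",
    sprintf("# groups: %s", jsonlite::toJSON(groups, digits = NA))
  )
  writeLines(header, path)
  readr::write_tsv(tibble::as_tibble(layout), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1L])
  tbl <- readr::read_tsv(I(lines[!grepl("^#", lines)]), progress = FALSE,
                         show_col_types = FALSE)
  groups <- tibble::as_tibble(jsonlite::fromJSON(get("groups")))
  structure(tibble::as_tibble(tbl),
            level = as.integer(get("level")),
            ordering = get("ordering"),
            reserve = as.logical(get("reserve")),
            groups = groups,
            class = c("mm_layout", class(tibble::tibble())))
}
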