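# ggplot2 rendering and deterministic PNG export.
#
# autoplot() is the vector-graphics route (save with ggplot2::ggsave());
# write_map_png() rasterizes the cell grid directly through png::writePNG
# with no graphics device, so exports are byte-stable across machines.

map_fill_colors <- function(map) {
  switch(attr(map, "scale"),
    diverging = list(low = "#2166AC", mid = "#F7F7F7", high = "#B2182B"),
    list(low = "#10002B", high = "#FFD60A")
  )
}

#' Plot a microbiome map
#'
#' Renders the per-cell intensity grid with ggplot2: tiles for cells, a
#' neutral tone for reserved-gap cells, the colormap floor for
#' zero/sub-threshold cells, optional neighborhood boundaries (attached
#' with [overlay_boundaries()]) and curve-path overlay (attached with
#' [overlay_path()]).  The y axis is reversed so the curve origin sits at
#' the top-left, matching the declared orientation.
#'
#' @param object An `mm_map`.
#' @param ... Ignored.
#' @return A ggplot object; save as PNG/SVG/PDF with [ggplot2::ggsave()].
#' @method autoplot mm_map
#' @export
autoplot.mm_map <- function(object, ...) {
  cells <- tibble::as_tibble(object)
  kind <- attr(object, "kind")
  gap_col <- "#BBBBBB"
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y))
  if (kind == "colorless") {
    p <- p + ggplot2::geom_tile(
      data = cells[cells$class != "gap", , drop = FALSE],
      ggplot2::aes(fill = .data$label), width = 1, height = 1,
      show.legend = TRUE) +
      ggplot2::scale_fill_hue(na.value = gap_col, name = attr(object, "metadata")$grouping)
  } else {
    cols <- map_fill_colors(object)
    plot_int <- ifelse(cells$class == "gap", NA_real_, cells$intensity)
    cells$plot_intensity <- plot_int
    p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$plot_intensity),
                         width = 1, height = 1)
    p <- if (attr(object, "scale") == "diverging") {
      p + ggplot2::scale_fill_gradient2(
        low = cols$low, mid = cols$mid, high = cols$high,
        limits = c(-1, 1), na.value = gap_col, name = "difference")
    } else {
      p + ggplot2::scale_fill_gradient(
        low = cols$low, high = cols$high, limits = c(0, 1),
        na.value = gap_col, name = "intensity")
    }
  }
  nb <- attr(object, "neighborhoods")
  if (!is.null(nb)) {
    p <- p + ggplot2::geom_segment(
      data = nb$edges,
      ggplot2::aes(x = .data$x0 - 0.5, y = .data$y0 - 0.5,
                   xend = .data$x1 - 0.5, yend = .data$y1 - 0.5),
      inherit.aes = FALSE, linewidth = 0.4, color = "white")
  }
  path <- attr(object, "path")
  if (!is.null(path)) {
    p <- p + ggplot2::geom_path(
      data = path, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, linewidth = 0.25, color = "#00000088")
  }
  if (!is.null(nb)) {
    p <- p + ggplot2::geom_text(
      data = nb$regions,
      ggplot2::aes(x = .data$anchor_x, y = .data$anchor_y,
                   label = .data$label),
      inherit.aes = FALSE, size = 2.6, color = "white")
  }
  p + ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map (level %d)", kind,
                                  attr(object, "level"))) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 9))
}

#' @export
plot.mm_map <- function(x, ...) print(autoplot.mm_map(x, ...))

#' Write a map as a deterministic PNG
#'
#' Rasterizes the cell grid straight into a PNG (one `pixel_size` x
#' `pixel_size` block per cell) via [png::writePNG()] — no graphics
#' device, so identical inputs give byte-identical files.  A sidecar JSON
#' with the render metadata (level, orientation, scale, tau, order hash)
#' is written next to the image.
#'
#' @param map An `mm_map`.
#' @param path Output file (`.png`).
#' @param pixel_size Square pixels per grid cell (default 4).
#' @param metadata Write the sidecar `<path>.json` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path, pixel_size = 4L, metadata = TRUE) {
  stopifnot(inherits(map, "mm_map"))
  side <- 2^attr(map, "level")
  cells <- tibble::as_tibble(map)
  img <- array(0, dim = c(side, side, 3L))
  if (attr(map, "kind") == "colorless") {
    labels <- sort(unique(stats::na.omit(cells$label)))
    pal <- grDevices::hcl(h = seq(15, 375, length.out = length(labels) + 1L)[-1L],
                          l = 65, c = 100)
    rgbv <- t(grDevices::col2rgb(pal[match(cells$label, labels)]) / 255)
    rgbv[is.na(cells$label), ] <- 0.95
  } else if (attr(map, "scale") == "diverging") {
    ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
    rgbv <- ramp((cells$intensity + 1) / 2) / 255
  } else {
    ramp <- grDevices::colorRamp(c("#10002B", "#FFD60A"))
    rgbv <- ramp(cells$intensity) / 255
  }
  gap <- cells$class == "gap"
  rgbv[gap, ] <- matrix(rep(c(0.733, 0.733, 0.733), each = sum(gap)),
                        ncol = 3L)
  for (ch in 1:3) {
    img[cbind(cells$y + 1L, cells$x + 1L, ch)] <- rgbv[, ch]
  }
  if (pixel_size > 1L) {
    up <- array(0, dim = c(side * pixel_size, side * pixel_size, 3L))
    rep_idx <- rep(seq_len(side), each = pixel_size)
    up <- img[rep_idx, rep_idx, , drop = FALSE]
    img <- up
  }
  png::writePNG(img, target = path)
  if (metadata) {
    jsonlite::write_json(attr(map, "metadata"),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write animation frames as a numbered PNG sequence
#'
#' Emits `frame_001.png`, `frame_002.png`, ... into a directory; any
#' standard encoder can assemble them into a GIF or MP4.
#'
#' @param frames An `mm_map_series` from [animation_frames()].
#' @param dir Output directory (created if needed).
#' @param pixel_size Square pixels per grid cell.
#' @return Character vector of frame paths, invisibly.
#' @export
write_frames_png <- function(frames, dir, pixel_size = 4L) {
  stopifnot(inherits(frames, "mm_map_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(unclass(frames), function(f, id) {
    i <- match(id, names(frames))
    p <- file.path(dir, sprintf("frame_%03d.png", i))
    write_map_png(f, p, pixel_size = pixel_size)
    p
  })
  invisible(unname(paths))
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a Hilbert layout
#'
#' @param x An `mm_layout`.
#' @param ... Ignored.
#' @return The per-taxon interval table as a plain tibble.
#' @method tidy mm_layout
#' @export
tidy.mm_layout <- function(x, ...) tibble::as_tibble(x)

#' One-row layout summary
#'
#' @param x An `mm_layout`.
#' @param ... Ignored.
#' @return A one-row tibble: `level`, `side`, `n_cells_grid`, `n_taxa`,
#'   `n_assigned_cells`, `n_gap_cells`, `min_interval`, `max_interval`,
#'   `ordering`, `reserve`.
#' @method glance mm_layout
#' @export
glance.mm_layout <- function(x, ...) {
  k <- attr(x, "level")
  tibble::tibble(
    level = k, side = 2^k, n_cells_grid = 4^k, n_taxa = nrow(x),
    n_assigned_cells = sum(x$n_cells),
    n_gap_cells = 4^k - sum(x$n_cells),
    min_interval = min(x$n_cells), max_interval = max(x$n_cells),
    ordering = attr(x, "ordering"), reserve = isTRUE(attr(x, "reserve"))
  )
}

#' Tidy a map raster
#'
#' @param x An `mm_map`.
#' @param ... Ignored.
#' @return The per-cell table as a plain tibble.
#' @method tidy mm_map
#' @export
tidy.mm_map <- function(x, ...) tibble::as_tibble(x)

#' One-row map summary
#'
#' @param x An `mm_map`.
#' @param ... Ignored.
#' @return A one-row tibble with kind, scale, tau, level and cell-class
#'   counts.
#' @method glance mm_map
#' @export
glance.mm_map <- function(x, ...) {
  tibble::tibble(
    kind = attr(x, "kind"), scale = attr(x, "scale"), tau = attr(x, "tau"),
    level = attr(x, "level"),
    n_assigned = sum(x$class == "assigned"),
    n_zero = sum(x$class == "zero"),
    n_gap = sum(x$class == "gap"),
    max_value = if (all(is.na(x$value %||% NA))) NA_real_ else
      suppressWarnings(max(x$value, na.rm = TRUE))
  )
}
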