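# Map rasters: turn a layout plus abundance vectors into per-cell
# intensity grids, with overlays, ggplot2 rendering and deterministic PNG
# export.
#
# An mm_map is a tibble with one row per grid cell: d, x, y, taxon_id,
# value (raw, on the abundance scale), intensity (scaled to [0,1], or
# [-1,1] for differential maps) and class (assigned / zero / gap).
# Attributes carry the level, scale type, tau, map kind and metadata.

new_map <- function(cells, layout, kind, scale, tau, extra = list()) {
  meta <- c(list(
    kind = kind, scale = scale, tau = tau,
    level = attr(layout, "level"),
    ordering = attr(layout, "ordering"),
    orientation = "x=column, y=row, origin top-left",
    order_hash = rlang::hash(layout$taxon_id)
  ), extra)
  structure(cells, level = attr(layout, "level"), kind = kind,
            scale = scale, tau = tau, metadata = meta,
            groups = attr(layout, "groups"),
            class = c("mm_map", class(tibble::tibble())))
}

#' @export
print.mm_map <- function(x, ...) {
  cat(sprintf("<mm_map> %s map, level %d, scale %s, tau %.3g\n",
              attr(x, "kind"), attr(x, "level"), attr(x, "scale"),
              attr(x, "tau")))
  NextMethod()
}

check_vector <- function(sample, layout) {
  if (is.data.frame(sample)) {
    taxa <- abundance_taxa(sample)
    if (nrow(sample) != 1L) {
      rlang::abort("expected a single sample row.",
                   class = "micromaps_input_error")
    }
    sample <- stats::setNames(as.numeric(sample[1L, taxa]), taxa)
  }
  missing_taxa <- setdiff(layout$taxon_id, names(sample))
  if (length(missing_taxa) > 0L) {
    rlang::abort(sprintf("abundance vector is missing %d layout taxa: %s%s",
                         length(missing_taxa),
                         paste(utils::head(missing_taxa, 5L), collapse = ", "),
                         if (length(missing_taxa) > 5L) ", ..." else ""),
                 class = "micromaps_input_error")
  }
  sample[layout$taxon_id]
}

scale_intensity <- function(value, scale, tau, max_value = NULL) {
  present <- !is.na(value) & value >= tau
  top <- max_value %||% if (any(present)) max(value[present]) else 0
  intensity <- rep(0, length(value))
  if (top > 0) {
    if (scale == "log") {
      if (tau <= 0) {
        rlang::abort("log scale requires tau > 0.",
                     class = "micromaps_input_error")
      }
      rng <- log10(top) - log10(tau)
      intensity[present] <- if (rng > 0) {
        (log10(value[present]) - log10(tau)) / rng
      } else {
        1
      }
    } else {
      intensity[present] <- value[present] / top
    }
  }
  pmin(pmax(intensity, 0), 1)
}

#' Render one sample as a microbiome map
#'
#' Paints every cell of the layout with the relative abundance of its
#' taxon in one sample: a taxon holding several merged cells paints all of
#' them with the same value.  Abundances below the noise threshold tau are
#' classed `"zero"` (presence below noise is not meaningful) and reserved
#' gap cells keep their own `"gap"` class so the two are visually
#' distinguishable.  Intensities are max-normalized over the sample;
#' `scale = "log"` stretches `[tau, max]` on a log10 axis instead, which
#' keeps low-abundance taxa visible under skewed profiles.
#'
#' @param sample A named abundance vector covering the layout's taxa, or a
#'   one-row wide abundance tibble.
#' @param layout An `mm_layout`.
#' @param scale `"linear"` (default) or `"log"`.
#' @param tau Noise threshold; defaults to the value stored on `sample`'s
#'   matrix if present, else `1e-5`.
#' @return An `mm_map` tibble (one row per grid cell).
#' @examples
#' sim <- simulate_profiles(simulate_taxonomy(), seed = 1)
#' ab <- normalize_abundance(sim$abundance)
#' lay <- build_layout(linearize(build_taxonomy(simulate_taxonomy())))
#' intensity_map(ab[1, ], lay)
#' @export
intensity_map <- function(sample, layout, scale = c("linear", "log"),
                          tau = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(layout, "mm_layout"))
  tau <- tau %||% attr(sample, "tau") %||% 1e-5
  v <- check_vector(sample, layout)
  cells <- layout_cells(layout)
  cells$value <- unname(v[cells$taxon_id])
  cells$intensity <- scale_intensity(cells$value, scale, tau)
  cells$class <- dplyr::case_when(
    is.na(cells$taxon_id) ~ "gap",
    is.na(cells$value) | cells$value < tau ~ "zero",
    TRUE ~ "assigned"
  )
  new_map(cells, layout, kind = "single", scale = scale, tau = tau)
}

#' Colorless map of a reference collection
#'
#' A map with no abundance channel at all: just the neighborhood geometry
#' of one grouping.  Shows how the reference collection is distributed
#' across clades — region area is proportional to clade size.
#'
#' @param layout An `mm_layout`.
#' @param grouping Grouping to outline (e.g. `"genus"`).
#' @return An `mm_map` of kind `"colorless"`; `value`/`intensity` are
#'   absent, `label` holds the group of each cell.  The neighborhood
#'   geometry rides in the `neighborhoods` attribute.
#' @export
colorless_map <- function(layout, grouping) {
  stopifnot(inherits(layout, "mm_layout"))
  nb <- neighborhoods(layout, grouping)
  cells <- layout_cells(layout)
  memb <- nb$cells[c("d", "label")]
  cells <- dplyr::left_join(cells, memb, by = "d")
  cells$class <- ifelse(is.na(cells$taxon_id), "gap", "assigned")
  out <- new_map(cells, layout, kind = "colorless", scale = "none",
                 tau = 0, extra = list(grouping = grouping))
  attr(out, "neighborhoods") <- nb
  out
}

reduce_samples <- function(samples, layout, reducer) {
  if (is.data.frame(samples)) {
    taxa <- abundance_taxa(samples)
    rows <- purrr::map(seq_len(nrow(samples)),
                       function(i) check_vector(samples[i, ], layout))
  } else {
    rows <- purrr::map(samples, check_vector, layout = layout)
  }
  if (length(rows) < 1L) {
    rlang::abort("need at least one sample.", class = "micromaps_input_error")
  }
  mat <- do.call(rbind, rows)
  apply(mat, 2L, reducer)
}

#' Average and aggregate maps
#'
#' Reduces several samples to one map on a shared layout: cell-wise
#' arithmetic mean for `average_map()`, or any reducer (`sum`, `median`,
#' `max`, ...) for `aggregate_map()`; reduction happens on the abundance
#' scale, before intensity scaling.
#'
#' @param samples A wide abundance tibble (one row per sample) or list of
#'   named vectors, all covering the layout's taxa.
#' @param layout An `mm_layout`.
#' @param reducer Function collapsing one taxon's abundances across
#'   samples to a scalar.
#' @inheritParams intensity_map
#' @return An `mm_map`.
#' @export
average_map <- function(samples, layout, scale = c("linear", "log"),
                        tau = NULL) {
  scale <- match.arg(scale)
  tau <- tau %||% attr(samples, "tau") %||% 1e-5
  v <- reduce_samples(samples, layout, mean)
  map_from_vector(v, layout, "average", scale, tau)
}

#' @rdname average_map
#' @export
aggregate_map <- function(samples, layout, reducer = sum,
                          scale = c("linear", "log"), tau = NULL) {
  scale <- match.arg(scale)
  tau <- tau %||% attr(samples, "tau") %||% 1e-5
  v <- reduce_samples(samples, layout, reducer)
  map_from_vector(v, layout, "aggregate", scale, tau)
}

map_from_vector <- function(v, layout, kind, scale, tau, extra = list()) {
  cells <- layout_cells(layout)
  cells$value <- unname(v[cells$taxon_id])
  cells$intensity <- scale_intensity(cells$value, scale, tau)
  cells$class <- dplyr::case_when(
    is.na(cells$taxon_id) ~ "gap",
    is.na(cells$value) | cells$value < tau ~ "zero",
    TRUE ~ "assigned"
  )
  new_map(cells, layout, kind = kind, scale = scale, tau = tau, extra = extra)
}

#' Differential map between two samples
#'
#' Cell value is `abundance(a) - abundance(b)` on a shared layout,
#' rendered on a signed diverging scale centered at 0 (intensity in
#' `[-1, 1]`, normalized by the largest absolute difference).  The operand
#' order is recorded in the metadata.
#'
#' @param a,b Named abundance vectors or one-row wide tibbles on the same
#'   layout.
#' @param layout An `mm_layout`.
#' @param tau Noise threshold recorded in metadata (no floor is applied to
#'   differences).
#' @param names Optional length-2 labels for the operands.
#' @return An `mm_map` of kind `"differential"`.
#' @export
differential_map <- function(a, b, layout, tau = NULL, names = c("a", "b")) {
  stopifnot(inherits(layout, "mm_layout"))
  tau <- tau %||% attr(a, "tau") %||% 1e-5
  va <- check_vector(a, layout)
  vb <- check_vector(b, layout)
  v <- va - vb
  cells <- layout_cells(layout)
  cells$value <- unname(v[cells$taxon_id])
  top <- max(abs(cells$value), na.rm = TRUE)
  cells$intensity <- if (top > 0) cells$value / top else
    ifelse(is.na(cells$value), NA_real_, 0)
  cells$intensity[is.na(cells$intensity)] <- 0
  cells$class <- dplyr::case_when(
    is.na(cells$taxon_id) ~ "gap",
    cells$value == 0 ~ "zero",
    TRUE ~ "assigned"
  )
  new_map(cells, layout, kind = "differential", scale = "diverging",
          tau = tau, extra = list(operands = names))
}

#' Animation frames for a sample series
#'
#' One map per sample on a fixed layout, with a shared global intensity
#' scale (the maximum abundance over all frames) so brightness is
#' comparable across frames — the prerequisite for reading temporal or
#' stage-wise change off the animation.
#'
#' @param series A wide abundance tibble whose row order is the frame
#'   order (time points, disease stages, ...).
#' @param layout An `mm_layout`.
#' @inheritParams intensity_map
#' @return An `mm_map_series`: a list of `mm_map` frames (named by
#'   `sample_id`) with attribute `global_max`.
#' @export
animation_frames <- function(series, layout, scale = c("linear", "log"),
                             tau = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(layout, "mm_layout"))
  if (!is.data.frame(series) || nrow(series) < 2L) {
    rlang::abort("`series` needs at least two samples.",
                 class = "micromaps_input_error")
  }
  tau <- tau %||% attr(series, "tau") %||% 1e-5
  rows <- purrr::map(seq_len(nrow(series)),
                     function(i) check_vector(series[i, ], layout))
  global_max <- max(purrr::map_dbl(rows, function(v) {
    p <- v[!is.na(v) & v >= tau]
    if (length(p)) max(p) else 0
  }))
  ids <- series$sample_id %||% paste0("frame", seq_along(rows))
  frames <- purrr::map2(rows, ids, function(v, id) {
    cells <- layout_cells(layout)
    cells$value <- unname(v[cells$taxon_id])
    cells$intensity <- scale_intensity(cells$value, scale, tau,
                                       max_value = global_max)
    cells$class <- dplyr::case_when(
      is.na(cells$taxon_id) ~ "gap",
      is.na(cells$value) | cells$value < tau ~ "zero",
      TRUE ~ "assigned"
    )
    new_map(cells, layout, kind = "frame", scale = scale, tau = tau,
            extra = list(frame = id, global_max = global_max))
  })
  structure(stats::setNames(frames, ids), global_max = global_max,
            class = "mm_map_series")
}

#' @export
print.mm_map_series <- function(x, ...) {
  cat(sprintf("<mm_map_series> %d frames, shared max %.4g\n", length(x),
              attr(x, "global_max")))
  invisible(x)
}

#' Attach the curve-path overlay to a map
#'
#' Adds the Hilbert curve's polyline (through cell centers, in visiting
#' order) to a map's overlay set, so the 1D taxon order can be followed on
#' the 2D image.  Drawn above cells and below labels by [autoplot.mm_map()].
#'
#' @param map An `mm_map`.
#' @param layout The layout the map was built on (levels must match).
#' @return The map with a `path` attribute (tibble `d`, `x`, `y`).
#' @export
overlay_path <- function(map, layout) {
  stopifnot(inherits(map, "mm_map"), inherits(layout, "mm_layout"))
  if (!identical(attr(map, "level"), attr(layout, "level"))) {
    rlang::abort("map and layout levels differ.",
                 class = "micromaps_input_error")
  }
  attr(map, "path") <- hilbert_path(attr(layout, "level"))
  map
}

#' Attach neighborhood boundaries to a map
#'
#' @param map An `mm_map`.
#' @param layout The layout the map was built on.
#' @param grouping Grouping to outline.
#' @return The map with a `neighborhoods` attribute.
#' @export
overlay_boundaries <- function(map, layout, grouping) {
  stopifnot(inherits(map, "mm_map"))
  attr(map, "neighborhoods") <- neighborhoods(layout, grouping)
  map
}
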