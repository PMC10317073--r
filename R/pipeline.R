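# Batch pipeline: one call that reads inputs, orders taxa, builds the
# layout and writes every requested artifact.  The Rscript front end in
# inst/cli/micromaps.R is a thin flag parser over run_pipeline().

#' Run the full map pipeline non-interactively
#'
#' Reads an abundance matrix and taxonomy, computes the requested taxon
#' ordering, builds the Hilbert layout, and writes one PNG map per sample
#' plus the layout TSV, a run-metadata JSON and a plain-text log of every
#' decision value (level, tau, orientation, child-order rule).  Suitable
#' for batch featurization: identical inputs and options give identical
#' outputs.
#'
#' @param abundance Path to an abundance table, or a wide abundance
#'   tibble.
#' @param taxonomy Path to a lineage table / Newick file, or a record
#'   tibble / `mm_taxonomy`.
#' @param out Output directory (created if needed).
#' @param order `"taxonomic"` (default) or `"labeled"`.
#' @param metadata For labeled ordering: path to a 2-column TSV
#'   (`sample_id`, `condition`) or a tibble.
#' @param conditions For labeled ordering: character vector declaring the
#'   condition order.
#' @param level Optional curve-level override.
#' @param tau Optional noise-threshold override.
#' @param reserve Gap policy flag (see [build_layout()]).
#' @param scale `"linear"` or `"log"` intensity scale.
#' @param child_order Child-order rule for [linearize()].
#' @param show_path,show_boundaries Overlay flags applied to every map.
#' @param boundary_grouping Grouping outlined when `show_boundaries` is
#'   on; defaults to the first grouping of the order.
#' @param average,differential Optional extras: `average = TRUE` also
#'   writes the cohort average map; `differential = c(s1, s2)` writes the
#'   signed difference map of two sample ids.
#' @param animate If `TRUE`, also writes the samples as an animation
#'   frame sequence with a shared intensity scale.
#' @param pixel_size Pixels per grid cell in PNG exports.
#' @return Invisibly, a list with the `layout`, the `order`, the vector of
#'   written `files`, and the run `log` lines.
#' @export
run_pipeline <- function(abundance, taxonomy, out,
                         order = c("taxonomic", "labeled"),
                         metadata = NULL, conditions = NULL,
                         level = NULL, tau = NULL, reserve = FALSE,
                         scale = c("linear", "log"),
                         child_order = "size-desc",
                         show_path = FALSE, show_boundaries = FALSE,
                         boundary_grouping = NULL,
                         average = FALSE, differential = NULL,
                         animate = FALSE, pixel_size = 4L) {
  order <- match.arg(order)
  scale <- match.arg(scale)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ab <- if (is.character(abundance)) read_abundance(abundance) else abundance
  ab <- normalize_abundance(ab, tau = tau)
  tau_used <- attr(ab, "tau")

  tax <- if (is.character(taxonomy)) {
    if (grepl("\\.(nwk|newick|tre|tree)$", taxonomy, ignore.case = TRUE)) {
      read_newick(taxonomy)
    } else {
      build_taxonomy(read_lineage_table(taxonomy))
    }
  } else if (inherits(taxonomy, "mm_taxonomy")) {
    taxonomy
  } else {
    build_taxonomy(taxonomy)
  }

  if (order == "labeled") {
    if (is.null(metadata) || is.null(conditions)) {
      rlang::abort("labeled ordering requires `metadata` and `conditions`.",
                   class = "micromaps_config_error")
    }
    meta <- if (is.character(metadata)) {
      readr::read_tsv(metadata, show_col_types = FALSE, progress = FALSE)
    } else {
      metadata
    }
    ord <- labeled_order(ab, meta, conditions, tax, tau = tau_used,
                         child_order = child_order)
  } else {
    ord <- linearize(tax, child_order = child_order)
  }

  lay <- build_layout(ord, level = level, reserve = reserve)
  grouping <- boundary_grouping %||% attr(lay, "groups")$grouping[1L]

  files <- character()
  layout_path <- file.path(out, "layout.tsv")
  write_layout(lay, layout_path)
  files <- c(files, layout_path)

  decorate <- function(m) {
    if (show_boundaries) m <- overlay_boundaries(m, lay, grouping)
    if (show_path) m <- overlay_path(m, lay)
    m
  }

  for (sid in ab$sample_id) {
    m <- decorate(intensity_map(ab[ab$sample_id == sid, ], lay,
                                scale = scale, tau = tau_used))
    p <- file.path(out, paste0("map_", gsub("[^A-Za-z0-9_.-]", "_", sid), ".png"))
    write_map_png(m, p, pixel_size = pixel_size)
    files <- c(files, p, paste0(p, ".json"))
  }

  if (isTRUE(average)) {
    m <- decorate(average_map(ab, lay, scale = scale, tau = tau_used))
    p <- file.path(out, "map_average.png")
    write_map_png(m, p, pixel_size = pixel_size)
    files <- c(files, p, paste0(p, ".json"))
  }
  if (!is.null(differential)) {
    if (length(differential) != 2L ||
        !all(differential %in% ab$sample_id)) {
      rlang::abort("`differential` must name two sample ids present in the matrix.",
                   class = "micromaps_config_error")
    }
    m <- decorate(differential_map(ab[ab$sample_id == differential[1L], ],
                                   ab[ab$sample_id == differential[2L], ],
                                   lay, tau = tau_used,
                                   names = differential))
    p <- file.path(out, "map_differential.png")
    write_map_png(m, p, pixel_size = pixel_size)
    files <- c(files, p, paste0(p, ".json"))
  }
  if (isTRUE(animate)) {
    fr <- animation_frames(ab, lay, scale = scale, tau = tau_used)
    files <- c(files, write_frames_png(fr, file.path(out, "frames"),
                                       pixel_size = pixel_size))
  }

  log_lines <- c(
    sprintf("level: %d", attr(lay, "level")),
    sprintf("tau: %.17g", tau_used),
    "orientation: x=column, y=row, origin top-left",
    sprintf("ordering: %s", order),
    sprintf("child_order: %s", child_order),
    sprintf("reserve: %s", reserve),
    sprintf("scale: %s", scale),
    sprintf("n_taxa: %d", nrow(lay)),
    sprintf("n_samples: %d", nrow(ab)),
    sprintf("order_hash: %s", rlang::hash(lay$taxon_id))
  )
  log_path <- file.path(out, "run_log.txt")
  writeLines(log_lines, log_path)
  meta_path <- file.path(out, "run_metadata.json")
  jsonlite::write_json(
    list(level = attr(lay, "level"), tau = tau_used, ordering = order,
         child_order = child_order, reserve = reserve, scale = scale,
         orientation = "x=column, y=row, origin top-left",
         n_taxa = nrow(lay), n_samples = nrow(ab),
         order_hash = rlang::hash(lay$taxon_id)),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, log_path, meta_path)

  invisible(list(layout = lay, order = ord, files = files, log = log_lines))
}
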