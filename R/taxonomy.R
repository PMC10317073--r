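# Taxonomy handling: rank-annotated lineage tables, tree construction and
# the deterministic taxonomic linear ordering.
#
# A taxon record table is an ordinary tibble with a `taxon_id` column
# followed by one column per rank, ordered coarse -> fine (e.g. genus,
# species, strain).  The leaf rank is whatever the finest column is: strain
# for shotgun-style collections, species or genus for 16S-style ones.

rank_columns <- function(records) {
  setdiff(names(records), c("taxon_id", "display_name"))
}

validate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    rlang::abort("`records` must be a non-empty data frame.",
                 class = "micromaps_input_error")
  }
  if (!"taxon_id" %in% names(records)) {
    rlang::abort("`records` must have a `taxon_id` column.",
                 class = "micromaps_input_error")
  }
  dup <- records$taxon_id[duplicated(records$taxon_id)]
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("duplicate taxon_id(s): %s", paste(unique(dup), collapse = ", ")),
      class = "micromaps_input_error"
    )
  }
  ranks <- rank_columns(records)
  if (length(ranks) == 0L) {
    rlang::abort("`records` must have at least one rank column.",
                 class = "micromaps_input_error")
  }
  empty <- apply(is.na(records[ranks]) | records[ranks] == "", 1L, all)
  if (any(empty)) {
    rlang::abort(
      sprintf("record(s) with empty lineage: %s",
              paste(records$taxon_id[empty], collapse = ", ")),
      class = "micromaps_input_error"
    )
  }
  tibble::as_tibble(records)
}

#' Build a taxonomy tree from taxon records
#'
#' Assembles the rank lineages of a record table into a rooted tree whose
#' leaves are the records and whose internal nodes are shared lineage
#' prefixes: two strains of the same species hang under one species node,
#' two species of the same genus under one genus node, and so on.  Records
#' missing an intermediate rank are given a synthetic
#' `"<parent>__unranked"` placeholder node so every clade still occupies a
#' contiguous block after linearization.
#'
#' @param records A data frame with a `taxon_id` column followed by one
#'   column per rank, ordered coarse to fine.  An optional `display_name`
#'   column is carried through.
#' @return An object of class `mm_taxonomy`: the validated record tibble
#'   (with placeholders filled in) plus the rank ordering, ready for
#'   [linearize()].
#' @examples
#' records <- simulate_taxonomy(2, 2, 4)
#' build_taxonomy(records)
#' @export
build_taxonomy <- function(records) {
  records <- validate_records(records)
  ranks <- rank_columns(records)
  # fill missing intermediate ranks with "<parent>__unranked" placeholders
  # so that clade contiguity survives linearization
  parent <- rep("root", nrow(records))
  for (r in ranks) {
    v <- records[[r]]
    miss <- is.na(v) | v == ""
    v[miss] <- paste0(parent[miss], "__unranked")
    records[[r]] <- v
    parent <- v
  }
  structure(
    list(records = records, ranks = ranks),
    class = "mm_taxonomy"
  )
}

#' @export
print.mm_taxonomy <- function(x, ...) {
  counts <- vapply(x$ranks, function(r) dplyr::n_distinct(x$records[[r]]),
                   integer(1))
  cat(sprintf("<mm_taxonomy> %d taxa; ranks: %s\n", nrow(x$records),
              paste(sprintf("%s (%d)", x$ranks, counts), collapse = ", ")))
  invisible(x)
}

#' Number of leaves per clade, used by the child-order rule
#' @noRd
clade_sizes <- function(records, rank) {
  dplyr::count(records, .data[[rank]], name = "..n")
}

#' Linearize a taxonomy tree into a 1D taxon order
#'
#' Trees have no natural start or finish, so a deterministic child-order
#' rule is applied at every node and the leaves are read off depth-first,
#' left to right.  The default rule sorts children by descending leaf
#' count (largest clades first), breaking ties lexicographically by name,
#' which keeps big neighborhoods visually coherent and is independent of
#' input row order.  Every clade's leaves end up in one contiguous run.
#'
#' @param taxonomy An `mm_taxonomy` from [build_taxonomy()], or a raw
#'   record data frame (coerced).
#' @param child_order `"size-desc"` (default) or `"lexicographic"`.
#' @return An `mm_order`: a tibble with columns `position` (1-based) and
#'   `taxon_id` plus the rank columns, carrying a `groups` attribute — a
#'   tibble of `(grouping, label, start, end)` contiguous runs for every
#'   rank — and an `ordering` attribute (`"taxonomic"`).
#' @examples
#' ord <- linearize(build_taxonomy(simulate_taxonomy(2, 2, 4)))
#' head(ord)
#' attr(ord, "groups")
#' @export
linearize <- function(taxonomy, child_order = c("size-desc", "lexicographic")) {
  child_order <- match.arg(child_order)
  if (!inherits(taxonomy, "mm_taxonomy")) taxonomy <- build_taxonomy(taxonomy)
  records <- taxonomy$records
  ranks <- taxonomy$ranks

  # sort keys: one per rank level, a (clade size, name) pair computed on
  # the full lineage path so same-named clades under different parents stay
  # distinct; taxon_id last for full determinism
  ord <- records
  keys <- list()
  path <- rep("", nrow(ord))
  for (r in ranks) {
    path <- paste(path, ord[[r]], sep = "\r")  # \r never occurs in names
    if (child_order == "size-desc") {
      n_in_clade <- stats::ave(path, path, FUN = length)
      keys[[length(keys) + 1L]] <- -as.integer(n_in_clade)
    }
    keys[[length(keys) + 1L]] <- ord[[r]]
  }
  keys[[length(keys) + 1L]] <- ord$taxon_id
  perm <- do.call(order, c(keys, list(method = "radix")))
  ord <- ord[perm, , drop = FALSE]

  out <- tibble::tibble(position = seq_len(nrow(ord)),
                        taxon_id = ord$taxon_id)
  out <- dplyr::bind_cols(out, ord[ranks])
  new_order(out, groups = group_runs(out, ranks), ordering = "taxonomic")
}

#' Contiguous runs of each grouping column along an order
#'
#' Runs are delimited on the full lineage path down to the grouping rank,
#' so same-named clades under different parents yield distinct runs; the
#' reported label is the plain rank value.
#' @noRd
group_runs <- function(order_tbl, groupings) {
  path <- rep("", nrow(order_tbl))
  runs <- vector("list", length(groupings))
  for (i in seq_along(groupings)) {
    g <- groupings[[i]]
    if (g %in% names(order_tbl)) path <- paste(path, order_tbl[[g]], sep = "\r")
    key <- if (g %in% names(order_tbl)) path else order_tbl[[g]]
    r <- rle(key)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    runs[[i]] <- tibble::tibble(grouping = g,
                                label = order_tbl[[g]][start],
                                start = start, end = end)
  }
  dplyr::bind_rows(runs)
}

new_order <- function(tbl, groups, ordering) {
  structure(tbl, groups = groups, ordering = ordering,
            class = c("mm_order", class(tibble::as_tibble(tbl))))
}

#' @export
print.mm_order <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<mm_order> %d taxa, %s ordering; groupings: %s\n",
              nrow(x), attr(x, "ordering"),
              paste(unique(g$grouping), collapse = ", ")))
  NextMethod()
}

#' Read a rank-annotated lineage table
#'
#' Expects a TSV or CSV file with a header row naming `taxon_id` plus one
#' column per rank, coarse to fine (e.g. `taxon_id, genus, species,
#' strain`).  Delimiter is inferred from the file extension/content.
#'
#' @param path Path to the table.
#' @return A validated record tibble suitable for [build_taxonomy()].
#' @export
read_lineage_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path),
                 class = "micromaps_input_error")
  }
  tbl <- tryCatch(
    readr::read_delim(path, delim = guess_delim(path),
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE),
    error = function(e) {
      rlang::abort(sprintf("could not parse lineage table %s: %s", path,
                           conditionMessage(e)),
                   class = "micromaps_input_error")
    }
  )
  validate_records(tbl)
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a taxonomy from a Newick tree
#'
#' Parses a Newick file with named leaves and converts each leaf's
#' root-to-tip path of *named* internal nodes into a rank lineage, using a
#' sidecar rank map: `ranks[i]` names the rank of the i-th named level
#' below the root, and the final entry is the leaf rank.  Unnamed internal
#' nodes are skipped.  Depths beyond `length(ranks) - 1` are collapsed
#' into the last internal rank.
#'
#' @param path Path to a Newick file.
#' @param ranks Character vector of rank names, coarse to fine; the last
#'   entry labels the leaves.
#' @return An `mm_taxonomy`.
#' @export
read_newick <- function(path, ranks = c("genus", "species", "strain")) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) {
    rlang::abort(sprintf("could not parse Newick file: %s", path),
                 class = "micromaps_input_error")
  }
  if (any(duplicated(tree$tip.label))) {
    rlang::abort("duplicate leaf labels in Newick tree.",
                 class = "micromaps_input_error")
  }
  n_tip <- length(tree$tip.label)
  node_lab <- if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  inner <- length(ranks) - 1L
  lineages <- purrr::map(seq_len(n_tip), function(tip) {
    path_names <- character()
    node <- parent_of[tip]
    while (node != 0L) {
      lab <- node_lab[node - n_tip]
      if (!is.na(lab) && nzchar(lab)) path_names <- c(lab, path_names)
      node <- parent_of[node]
    }
    if (length(path_names) > inner && inner >= 0L) {
      path_names <- path_names[seq_len(inner)]
    }
    length(path_names) <- inner  # pad with NA; placeholders added downstream
    c(path_names, tree$tip.label[tip])
  })
  records <- tibble::as_tibble(
    stats::setNames(as.data.frame(do.call(rbind, lineages),
                                  stringsAsFactors = FALSE), ranks)
  )
  records <- dplyr::bind_cols(tibble::tibble(taxon_id = tree$tip.label), records)
  build_taxonomy(records)
}
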