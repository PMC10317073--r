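# Abundance matrices and the condition-anchored ("labeled") ordering.
#
# An abundance matrix is a wide tibble: `sample_id` column, then one
# numeric column per taxon.  Attributes track whether rows have been
# normalized to relative abundances, the noise threshold tau, and any
# all-zero samples.

abundance_taxa <- function(abundance) setdiff(names(abundance), "sample_id")

validate_abundance <- function(abundance) {
  if (!is.data.frame(abundance) || !"sample_id" %in% names(abundance)) {
    rlang::abort("abundance table must have a `sample_id` column.",
                 class = "micromaps_input_error")
  }
  if (anyDuplicated(abundance$sample_id)) {
    rlang::abort("duplicated sample_id(s) in abundance table.",
                 class = "micromaps_input_error")
  }
  taxa <- abundance_taxa(abundance)
  if (length(taxa) == 0L) {
    rlang::abort("abundance table has no taxon columns.",
                 class = "micromaps_input_error")
  }
  vals <- as.matrix(abundance[taxa])
  if (!is.numeric(vals) || anyNA(vals)) {
    rlang::abort("abundance values must be numeric and non-missing.",
                 class = "micromaps_input_error")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    rlang::abort(
      sprintf("negative abundance at sample '%s', taxon '%s'.",
              abundance$sample_id[bad[1L]], taxa[bad[2L]]),
      class = "micromaps_input_error"
    )
  }
  tibble::as_tibble(abundance)
}

#' Read an abundance matrix
#'
#' Accepts either a wide table (rows are samples: a `sample_id` column —
#' or unnamed first column — followed by one numeric column per taxon) or
#' a sparse triplet table with columns `sample_id`, `taxon_id`, `value`
#' where omitted pairs are zero.  TSV and CSV are both accepted.  Raw
#' counts are fine; the matrix is marked unnormalized until
#' [normalize_abundance()] is applied.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default: triplet if the header is exactly the
#'   three triplet columns), `"wide"`, or `"triplets"`.
#' @return A wide abundance tibble with attribute `normalized = FALSE`.
#' @export
read_abundance <- function(path, format = c("auto", "wide", "triplets")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path),
                 class = "micromaps_input_error")
  }
  tbl <- tryCatch(
    readr::read_delim(path, delim = guess_delim(path), progress = FALSE,
                      show_col_types = FALSE),
    error = function(e) {
      rlang::abort(sprintf("could not parse abundance file %s: %s", path,
                           conditionMessage(e)),
                   class = "micromaps_input_error")
    }
  )
  if (format == "auto") {
    format <- if (identical(sort(names(tbl)),
                            sort(c("sample_id", "taxon_id", "value")))) {
      "triplets"
    } else {
      "wide"
    }
  }
  if (format == "triplets") {
    need <- c("sample_id", "taxon_id", "value")
    if (!all(need %in% names(tbl))) {
      rlang::abort("triplet file needs columns sample_id, taxon_id, value.",
                   class = "micromaps_input_error")
    }
    if (anyDuplicated(tbl[c("sample_id", "taxon_id")])) {
      rlang::abort("duplicated (sample_id, taxon_id) pair in triplet file.",
                   class = "micromaps_input_error")
    }
    tbl <- tidyr::pivot_wider(tbl, names_from = "taxon_id",
                              values_from = "value", values_fill = 0)
  } else {
    names(tbl)[1L] <- "sample_id"
    if (anyDuplicated(names(tbl))) {
      rlang::abort("duplicated taxon column names in abundance table.",
                   class = "micromaps_input_error")
    }
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  out <- validate_abundance(tbl)
  attr(out, "normalized") <- FALSE
  out
}

#' Normalize an abundance matrix to relative abundances
#'
#' Divides every sample row by its row sum so values become relative
#' abundances summing to 1; idempotent on already-normalized input.
#' All-zero rows are left at zero, flagged in the `zero_samples`
#' attribute, and excluded from ordering computations with a warning.
#'
#' The noise threshold tau — the minimal relative abundance at which a
#' taxon counts as present for anchoring and coloring — is fixed here:
#' when the input looks like raw counts, tau defaults to the reciprocal of
#' the median per-sample depth (one-read resolution); when the input is
#' already relative, to `1e-5`.  Either way it can be overridden.
#'
#' @param abundance A wide abundance tibble.
#' @param tau Optional noise threshold override (`>= 0`).
#' @return The normalized tibble with attributes `normalized = TRUE`,
#'   `tau`, and `zero_samples`.
#' @examples
#' ab <- tibble::tibble(sample_id = "s1", a = 2, b = 2, c = 0, d = 0)
#' normalize_abundance(ab)
#' @export
normalize_abundance <- function(abundance, tau = NULL) {
  abundance <- validate_abundance(abundance)
  taxa <- abundance_taxa(abundance)
  vals <- as.matrix(abundance[taxa])
  sums <- rowSums(vals)
  zero <- sums == 0
  if (any(zero)) {
    rlang::warn(sprintf(
      "all-zero sample(s) excluded from ordering computations: %s",
      paste(abundance$sample_id[zero], collapse = ", ")))
  }
  already <- all(abs(sums[!zero] - 1) <= 1e-9)
  if (is.null(tau)) {
    tau <- if (already || !any(vals[!zero, , drop = FALSE] > 1)) {
      1e-5
    } else {
      1 / stats::median(sums[!zero])
    }
  }
  if (tau < 0) {
    rlang::abort("`tau` must be >= 0.", class = "micromaps_input_error")
  }
  vals[!zero, ] <- vals[!zero, , drop = FALSE] / sums[!zero]
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = abundance$sample_id),
    tibble::as_tibble(as.data.frame(vals))
  )
  attr(out, "normalized") <- TRUE
  attr(out, "tau") <- tau
  attr(out, "zero_samples") <- abundance$sample_id[zero]
  out
}

abundance_tau <- function(abundance, tau = NULL) {
  tau %||% attr(abundance, "tau") %||% 1e-5
}

validate_design <- function(abundance, metadata, conditions) {
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "condition") %in% names(metadata))) {
    rlang::abort("`metadata` must have columns sample_id and condition.",
                 class = "micromaps_input_error")
  }
  if (length(conditions) == 0L || anyDuplicated(conditions)) {
    rlang::abort("`conditions` must be a duplicate-free, non-empty order.",
                 class = "micromaps_input_error")
  }
  missing_meta <- setdiff(abundance$sample_id, metadata$sample_id)
  if (length(missing_meta) > 0L) {
    rlang::abort(sprintf("unlabeled sample(s): %s",
                         paste(missing_meta, collapse = ", ")),
                 class = "micromaps_input_error")
  }
  meta <- metadata[metadata$sample_id %in% abundance$sample_id, ]
  stray <- setdiff(meta$condition, conditions)
  if (length(stray) > 0L) {
    rlang::abort(sprintf(
      "sample condition(s) not in the declared condition order: %s",
      paste(stray, collapse = ", ")), class = "micromaps_input_error")
  }
  zero <- attr(abundance, "zero_samples") %||% character()
  meta <- meta[!meta$sample_id %in% zero, ]
  empty <- setdiff(conditions, meta$condition)
  if (length(empty) > 0L) {
    rlang::abort(sprintf("condition(s) with no usable samples: %s",
                         paste(empty, collapse = ", ")),
                 class = "micromaps_input_error")
  }
  meta
}

#' Per-condition abundance means and condition anchors
#'
#' For every taxon and condition, computes the arithmetic mean relative
#' abundance over that condition's samples, then anchors the taxon to the
#' condition with the highest mean — provided that mean clears the noise
#' threshold tau.  Ties across conditions go to the earliest condition in
#' the declared order; taxa whose means are all below tau are
#' `"unassigned"`.
#'
#' @param abundance A normalized abundance tibble (see
#'   [normalize_abundance()]).
#' @param metadata Tibble with columns `sample_id`, `condition`.
#' @param conditions Character vector: the user-declared condition order.
#' @param tau Noise threshold override; defaults to the matrix's stored
#'   tau.
#' @return A tibble with one row per taxon: `taxon_id`, one mean column
#'   per condition (prefixed `mean_`), `anchor`, and `score` (the
#'   anchoring mean; `NA` when unassigned).
#' @examples
#' sim <- simulate_profiles(simulate_taxonomy(), seed = 1)
#' ab <- normalize_abundance(sim$abundance)
#' condition_means(ab, sim$metadata, sim$conditions)
#' @export
condition_means <- function(abundance, metadata, conditions, tau = NULL) {
  abundance <- validate_abundance(abundance)
  if (!isTRUE(attr(abundance, "normalized"))) {
    rlang::abort("abundance must be normalized first; see normalize_abundance().",
                 class = "micromaps_input_error")
  }
  tau <- abundance_tau(abundance, tau)
  meta <- validate_design(abundance, metadata, conditions)
  taxa <- abundance_taxa(abundance)

  used <- abundance[abundance$sample_id %in% meta$sample_id, ]
  cond_of <- stats::setNames(meta$condition, meta$sample_id)
  vals <- as.matrix(used[taxa])
  cond <- factor(cond_of[used$sample_id], levels = conditions)
  means <- rowsum(vals, cond) / as.vector(table(cond))  # conditions x taxa

  best <- apply(means, 2L, which.max)  # ties -> earliest declared condition
  best_mean <- means[cbind(best, seq_along(taxa))]
  assigned <- best_mean >= tau
  out <- tibble::tibble(taxon_id = taxa)
  mean_cols <- tibble::as_tibble(as.data.frame(t(means)))
  names(mean_cols) <- paste0("mean_", conditions)
  out <- dplyr::bind_cols(out, mean_cols)
  out$anchor <- ifelse(assigned, conditions[best], "unassigned")
  out$score <- ifelse(assigned, best_mean, NA_real_)
  out
}

#' Condition-anchored ("labeled") taxon ordering
#'
#' Orders taxa in blocks by the condition in which their mean relative
#' abundance is highest, following the user-declared condition order, with
#' a trailing `"unassigned"` block for taxa below the noise threshold in
#' every condition.  Within each block taxa follow the taxonomic
#' linearization, so condition neighborhoods keep internal taxonomic
#' structure.
#'
#' @inheritParams condition_means
#' @param taxonomy An `mm_taxonomy` (or record table) covering the
#'   matrix's taxa; supplies the within-block order.
#' @param child_order Child-order rule passed to [linearize()].
#' @return An `mm_order` whose `groups` attribute holds the condition
#'   blocks (grouping `"condition"`) followed by rank runs.
#' @examples
#' sim <- simulate_profiles(simulate_taxonomy(), seed = 1)
#' ab <- normalize_abundance(sim$abundance)
#' labeled_order(ab, sim$metadata, sim$conditions, simulate_taxonomy())
#' @export
labeled_order <- function(abundance, metadata, conditions, taxonomy,
                          tau = NULL, child_order = "size-desc") {
  anchors <- condition_means(abundance, metadata, conditions, tau)
  tax_order <- if (inherits(taxonomy, "mm_order")) {
    taxonomy
  } else {
    linearize(taxonomy, child_order = child_order)
  }
  missing_tax <- setdiff(anchors$taxon_id, tax_order$taxon_id)
  if (length(missing_tax) > 0L) {
    rlang::abort(sprintf("taxa absent from the taxonomy: %s",
                         paste(utils::head(missing_tax, 5L), collapse = ", ")),
                 class = "micromaps_input_error")
  }
  block_levels <- c(conditions, "unassigned")
  tax_order <- tax_order[tax_order$taxon_id %in% anchors$taxon_id, ]
  joined <- dplyr::left_join(
    tibble::as_tibble(tax_order)[setdiff(names(tax_order), "position")],
    anchors[c("taxon_id", "anchor", "score")],
    by = "taxon_id"
  )
  joined <- joined[order(match(joined$anchor, block_levels)), , drop = FALSE]
  joined$position <- seq_len(nrow(joined))
  out <- dplyr::relocate(joined, "position", "taxon_id")
  out <- dplyr::rename(out, condition = "anchor")
  ranks <- intersect(rank_columns(out), names(out))
  ranks <- setdiff(ranks, c("condition", "score", "position"))
  new_order(out, groups = group_runs(out, c("condition", ranks)),
            ordering = "labeled")
}
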