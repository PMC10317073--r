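# Synthetic communities: a balanced toy taxonomy plus log-normal abundance
# profiles with planted condition signatures.  Exists so the whole pipeline
# is exercisable end to end without any external reference collection; the
# generator emits the same tables the file readers consume.

#' Simulate a balanced reference taxonomy
#'
#' Builds a three-rank (genus / species / strain) record table with
#' systematic names: `n_genera` genera, each with `species_per_genus`
#' species, each with `strains_per_species` strains.  The default shape —
#' 2 genera, 2 species each, 4 strains each — is the classic 16-leaf toy
#' collection that fits a level-2 Hilbert grid exactly.
#'
#' @param n_genera,species_per_genus,strains_per_species Positive counts.
#' @return A record tibble with columns `taxon_id`, `genus`, `species`,
#'   `strain`, ready for [build_taxonomy()].
#' @examples
#' simulate_taxonomy(2, 2, 4) # 16 strains
#' @export
simulate_taxonomy <- function(n_genera = 2, species_per_genus = 2,
                              strains_per_species = 4) {
  counts <- c(n_genera, species_per_genus, strains_per_species)
  if (any(!is.finite(counts) | counts < 1 | counts != floor(counts))) {
    rlang::abort("all taxonomy counts must be integers >= 1.",
                 class = "micromaps_input_error")
  }
  grid <- tidyr::expand_grid(
    g = seq_len(n_genera), s = seq_len(species_per_genus),
    t = seq_len(strains_per_species)
  )
  tibble::tibble(
    taxon_id = sprintf("G%02d_S%02d_T%03d", grid$g, grid$s, grid$t),
    genus = sprintf("Genus_%02d", grid$g),
    species = sprintf("Genus_%02d_sp%02d", grid$g, grid$s),
    strain = sprintf("G%02d_S%02d_T%03d", grid$g, grid$s, grid$t)
  )
}

#' Simulate labeled abundance profiles over a taxonomy
#'
#' Draws per-sample abundances from a log-normal background — mimicking
#' the right-skewed distribution of real microbial relative abundances —
#' and plants, for each condition, a disjoint set of signature taxa whose
#' expected abundance is `effect_size` times the background.  Rows are
#' normalized to relative abundances.  The ground-truth signature
#' assignment is returned so ordering methods can be scored against it.
#'
#' @param records A taxon record table (e.g. from [simulate_taxonomy()]).
#' @param conditions Character vector of condition labels, in the order a
#'   user would declare them.
#' @param samples_per_condition Samples drawn per condition (default 3,
#'   a typical small-cohort group size).
#' @param signature_per_condition Number of signature taxa planted per
#'   condition; default one tenth of the collection (at least 1).
#' @param effect_size Multiplier on the background mean for signature taxa
#'   in their own condition; must be `> 1` to plant a signal (exactly 1
#'   yields a pure null community).
#' @param sdlog Log-scale standard deviation of the log-normal noise.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with `abundance` (wide sample-by-taxon tibble of raw
#'   intensities, unnormalized), `metadata` (tibble `sample_id`,
#'   `condition`), `conditions` (the declared order), and `truth` (tibble
#'   `taxon_id`, `condition` of planted signatures).
#' @examples
#' sim <- simulate_profiles(simulate_taxonomy(), seed = 1)
#' sim$truth
#' @export
simulate_profiles <- function(records,
                              conditions = c("C1", "C2", "C3"),
                              samples_per_condition = 3,
                              signature_per_condition = NULL,
                              effect_size = 10,
                              sdlog = 1,
                              seed = 1L) {
  if (!is.data.frame(records) || !"taxon_id" %in% names(records)) {
    rlang::abort("`records` must be a taxon record table.",
                 class = "micromaps_input_error")
  }
  if (length(conditions) < 1L || anyDuplicated(conditions)) {
    rlang::abort("`conditions` must be non-empty and duplicate-free.",
                 class = "micromaps_input_error")
  }
  if (samples_per_condition < 1) {
    rlang::abort("`samples_per_condition` must be >= 1.",
                 class = "micromaps_input_error")
  }
  if (effect_size < 1) {
    rlang::abort("`effect_size` must be >= 1.",
                 class = "micromaps_input_error")
  }
  taxa <- records$taxon_id
  n <- length(taxa)
  n_cond <- length(conditions)
  if (is.null(signature_per_condition)) {
    signature_per_condition <- max(1L, floor(n / 10))
  }
  if (signature_per_condition * n_cond > n) {
    rlang::abort("not enough taxa for disjoint condition signatures.",
                 class = "micromaps_input_error")
  }

  withr::with_seed(as.integer(seed), {
    sig_taxa <- sample(taxa, signature_per_condition * n_cond)
    truth <- tibble::tibble(
      taxon_id = sig_taxa,
      condition = rep(conditions, each = signature_per_condition)
    )
    meta <- tibble::tibble(
      sample_id = sprintf("%s_rep%d", rep(conditions, each = samples_per_condition),
                          rep(seq_len(samples_per_condition), n_cond)),
      condition = rep(conditions, each = samples_per_condition)
    )
    # meanlog per (condition, taxon): background 0, signatures boosted
    boost <- matrix(0, nrow = n_cond, ncol = n,
                    dimnames = list(conditions, taxa))
    boost[cbind(truth$condition, truth$taxon_id)] <- log(effect_size)
    vals <- purrr::map(seq_len(nrow(meta)), function(i) {
      mu <- boost[meta$condition[i], ]
      stats::rlnorm(n, meanlog = mu, sdlog = sdlog)
    })
    abundance <- tibble::as_tibble(
      stats::setNames(as.data.frame(do.call(rbind, vals)), taxa)
    )
    abundance <- dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                                  abundance)
    list(abundance = abundance, metadata = meta,
         conditions = conditions, truth = truth)
  })
}
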