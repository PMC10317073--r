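# Abundance I/O, normalization, condition means and the labeled ordering.

test_that("wide and triplet abundance files read correctly", {
  wide <- abund_tbl(list(s1 = c(a = 1, b = 2, c = 0, d = 3, e = 4),
                         s2 = c(a = 0, b = 0, c = 5, d = 0, e = 1),
                         s3 = c(a = 2, b = 2, c = 2, d = 2, e = 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, path)
  got <- read_abundance(path)
  expect_equal(dim(got), c(3L, 6L))
  expect_false(attr(got, "normalized"))

  trip <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    taxon_id = c("a", "b", "a"),
    value = c(3, 1, 2)
  )
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(trip, path2)
  got2 <- read_abundance(path2)
  expect_equal(sort(names(got2)), c("a", "b", "sample_id"))
  expect_equal(got2$b[got2$sample_id == "s2"], 0)  # missing pair is zero

  bad <- wide
  bad$c[1] <- -1
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path3)
  expect_error(read_abundance(path3), "negative.*s1.*'c'",
               class = "micromaps_input_error")
})

test_that("duplicated ids are rejected", {
  wide <- abund_tbl(list(s1 = c(a = 1, b = 2)))
  dup <- dplyr::bind_rows(wide, wide)
  expect_error(normalize_abundance(dup), "duplicated",
               class = "micromaps_input_error")
})

test_that("normalization divides rows by their sums and is idempotent", {
  ab <- abund_tbl(list(s1 = c(a = 2, b = 2, c = 0, d = 0)))
  norm <- normalize_abundance(ab)
  expect_equal(unlist(norm[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(0.5, 0.5, 0, 0))
  again <- normalize_abundance(norm)
  expect_equal(as.matrix(again[-1]), as.matrix(norm[-1]))
})

test_that("every row of a random matrix normalizes to sum 1", {
  set.seed(42)
  m <- matrix(stats::rlnorm(100 * 20), nrow = 100)
  ab <- tibble::as_tibble(as.data.frame(m))
  names(ab) <- paste0("t", 1:20)
  ab <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", 1:100)), ab)
  norm <- normalize_abundance(ab)
  sums <- rowSums(as.matrix(norm[paste0("t", 1:20)]))
  expect_true(all(abs(sums - 1) <= 1e-9))
})

test_that("all-zero samples are flagged, warned about, and excluded", {
  ab <- abund_tbl(list(s1 = c(a = 1, b = 1), s2 = c(a = 0, b = 0)))
  expect_warning(norm <- normalize_abundance(ab), "s2")
  expect_equal(attr(norm, "zero_samples"), "s2")
  expect_equal(unlist(norm[2, c("a", "b")], use.names = FALSE), c(0, 0))
})

test_that("tau defaults to one-read resolution on counts, 1e-5 on proportions", {
  counts <- abund_tbl(list(s1 = c(a = 80, b = 20), s2 = c(a = 150, b = 50)))
  norm <- normalize_abundance(counts)
  expect_equal(attr(norm, "tau"), 1 / 150)  # median depth (100+200)/2
  rel <- normalize_abundance(norm)
  expect_equal(attr(rel, "tau"), 1e-5)
  over <- normalize_abundance(counts, tau = 0.01)
  expect_equal(attr(over, "tau"), 0.01)
})

# Hand-built 2-condition, 4-sample fixture: means are computed by hand.
#   taxon A: C1 samples (0.30, 0.30) -> mean 0.30; C2 (0.10, 0.10) -> 0.10
#   taxon B: C1 (0.05, 0.05) -> 0.05; C2 (0.40, 0.40) -> 0.40
#   taxon C: fills the rest of each row
hand_fixture <- function() {
  ab <- abund_tbl(list(
    c1a = c(A = 0.30, B = 0.05, C = 0.65),
    c1b = c(A = 0.30, B = 0.05, C = 0.65),
    c2a = c(A = 0.10, B = 0.40, C = 0.50),
    c2b = c(A = 0.10, B = 0.40, C = 0.50)
  ))
  meta <- tibble::tibble(sample_id = c("c1a", "c1b", "c2a", "c2b"),
                         condition = c("C1", "C1", "C2", "C2"))
  list(ab = normalize_abundance(ab, tau = 0.01), meta = meta,
       conds = c("C1", "C2"))
}

test_that("condition means and anchors match hand computation", {
  f <- hand_fixture()
  cm <- condition_means(f$ab, f$meta, f$conds)
  expect_equal(cm$mean_C1[cm$taxon_id == "A"], 0.30)
  expect_equal(cm$mean_C2[cm$taxon_id == "A"], 0.10)
  expect_equal(cm$anchor[cm$taxon_id == "A"], "C1")
  expect_equal(cm$anchor[cm$taxon_id == "B"], "C2")
  expect_equal(cm$score[cm$taxon_id == "B"], 0.40)
})

test_that("cross-condition ties anchor to the first declared condition", {
  ab <- normalize_abundance(abund_tbl(list(
    s1 = c(A = 0.5, B = 0.5), s2 = c(A = 0.5, B = 0.5)
  )), tau = 0.01)
  meta <- tibble::tibble(sample_id = c("s1", "s2"),
                         condition = c("C1", "C2"))
  cm <- condition_means(ab, meta, c("C1", "C2"))
  expect_equal(cm$anchor, c("C1", "C1"))
  # reversing the declared order flips the tie
  cm2 <- condition_means(ab, meta, c("C2", "C1"))
  expect_equal(cm2$anchor, c("C2", "C2"))
})

test_that("taxa below tau in every condition are unassigned and trail", {
  ab <- normalize_abundance(abund_tbl(list(
    s1 = c(A = 0.995, B = 0.005), s2 = c(A = 0.995, B = 0.005)
  )), tau = 0.01)
  meta <- tibble::tibble(sample_id = c("s1", "s2"),
                         condition = c("C1", "C2"))
  cm <- condition_means(ab, meta, c("C1", "C2"))
  expect_equal(cm$anchor[cm$taxon_id == "B"], "unassigned")
  expect_true(is.na(cm$score[cm$taxon_id == "B"]))

  rec <- tibble::tibble(taxon_id = c("A", "B"), genus = "g",
                        species = c("A", "B"), strain = c("A", "B"))
  ord <- labeled_order(ab, meta, c("C1", "C2"), rec)
  expect_equal(ord$taxon_id[nrow(ord)], "B")
  runs <- attr(ord, "groups")
  cond_runs <- runs[runs$grouping == "condition", ]
  expect_equal(cond_runs$label[which.max(cond_runs$start)], "unassigned")
})

test_that("anchors agree with a brute-force loop on a 3-condition fixture", {
  rec <- simulate_taxonomy(2, 2, 4)
  sim <- simulate_profiles(rec, conditions = c("X", "Y", "Z"), seed = 11)
  ab <- normalize_abundance(sim$abundance, tau = 1e-4)
  cm <- condition_means(ab, sim$metadata, sim$conditions)
  taxa <- setdiff(names(ab), "sample_id")
  for (tx in taxa) {
    means <- vapply(sim$conditions, function(cond) {
      rows <- sim$metadata$sample_id[sim$metadata$condition == cond]
      mean(ab[[tx]][match(rows, ab$sample_id)])
    }, numeric(1))
    expect_equal(unlist(cm[cm$taxon_id == tx,
                           paste0("mean_", sim$conditions)],
                        use.names = FALSE),
                 unname(means))
    expected_anchor <- if (max(means) >= 1e-4) {
      sim$conditions[which.max(means)]
    } else {
      "unassigned"
    }
    expect_equal(cm$anchor[cm$taxon_id == tx], expected_anchor)
  }
})

test_that("labeled order blocks follow the declared condition order", {
  f <- hand_fixture()
  rec <- tibble::tibble(taxon_id = c("A", "B", "C"), genus = "g",
                        species = c("A", "B", "C"),
                        strain = c("A", "B", "C"))
  ord <- labeled_order(f$ab, f$meta, f$conds, rec)
  expect_equal(ord$taxon_id[1], "A")  # C1 block first
  runs <- attr(ord, "groups")
  cond_runs <- runs[runs$grouping == "condition", ]
  cond_runs <- cond_runs[order(cond_runs$start), ]
  expect_equal(cond_runs$label, c("C1", "C2"))  # A, C anchor to C1; B to C2
  # every taxon in exactly one block
  expect_equal(sum(cond_runs$end - cond_runs$start + 1L), nrow(ord))
})

test_that("labeled ordering is invariant to sample row order", {
  rec <- simulate_taxonomy(2, 2, 4)
  sim <- simulate_profiles(rec, seed = 3)
  ab <- normalize_abundance(sim$abundance, tau = 1e-4)
  ord1 <- labeled_order(ab, sim$metadata, sim$conditions, rec)
  shuf <- normalize_abundance(sim$abundance[sample.int(nrow(ab)), ],
                              tau = 1e-4)
  ord2 <- labeled_order(shuf, sim$metadata, sim$conditions, rec)
  expect_equal(ord2$taxon_id, ord1$taxon_id)
})

test_that("raising tau only ever moves taxa toward the unassigned block", {
  rec <- simulate_taxonomy(2, 2, 4)
  sim <- simulate_profiles(rec, seed = 5)
  ab <- normalize_abundance(sim$abundance)
  taus <- c(1e-5, 1e-3, 1e-2, 5e-2, 0.2)
  prev_unassigned <- character()
  for (tau in taus) {
    cm <- condition_means(ab, sim$metadata, sim$conditions, tau = tau)
    un <- cm$taxon_id[cm$anchor == "unassigned"]
    expect_true(all(prev_unassigned %in% un))
    prev_unassigned <- un
  }
})

test_that("within each condition block taxa follow the taxonomic order", {
  rec <- simulate_taxonomy(2, 2, 4)
  sim <- simulate_profiles(rec, seed = 9)
  ab <- normalize_abundance(sim$abundance, tau = 1e-4)
  tax_ord <- linearize(build_taxonomy(rec))
  ord <- labeled_order(ab, sim$metadata, sim$conditions, rec)
  runs <- attr(ord, "groups")
  for (i in which(runs$grouping == "condition")) {
    block <- ord$taxon_id[runs$start[i]:runs$end[i]]
    expect_equal(block,
                 tax_ord$taxon_id[tax_ord$taxon_id %in% block])
  }
})

test_that("design errors are caught: unlabeled samples, empty or stray conditions", {
  f <- hand_fixture()
  expect_error(condition_means(f$ab, f$meta[-1, ], f$conds),
               "unlabeled", class = "micromaps_input_error")
  expect_error(condition_means(f$ab, f$meta, c("C1", "C2", "C3")),
               "no usable samples", class = "micromaps_input_error")
  expect_error(condition_means(f$ab, f$meta, "C1"),
               "not in the declared", class = "micromaps_input_error")
  raw <- abund_tbl(list(s1 = c(A = 1, B = 2)))
  expect_error(
    condition_means(raw, tibble::tibble(sample_id = "s1", condition = "C1"),
                    "C1"),
    "normalized", class = "micromaps_input_error")
})
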