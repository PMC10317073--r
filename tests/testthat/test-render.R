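# Map rasters: intensity scaling, reductions, differential identities,
# animation scaling, overlays and deterministic export.

toy_setup <- function(seed = 1) {
  rec <- toy_records()
  lay <- build_layout(linearize(build_taxonomy(rec)))
  sim <- simulate_profiles(rec, seed = seed)
  ab <- normalize_abundance(sim$abundance, tau = 1e-4)
  list(rec = rec, lay = lay, ab = ab)
}

vec_of <- function(lay, ...) {
  v <- stats::setNames(rep(0, nrow(lay)), lay$taxon_id)
  dots <- c(...)
  if (length(dots)) v[names(dots)] <- dots
  v
}

test_that("an all-zero sample renders every assigned cell as zero-class", {
  s <- toy_setup()
  m <- intensity_map(vec_of(s$lay), s$lay, tau = 1e-4)
  expect_true(all(m$class == "zero"))
  expect_true(all(m$intensity == 0))
})

test_that("a single present taxon lights exactly its cells at intensity 1", {
  s <- toy_setup()
  tx <- s$lay$taxon_id[5]
  m <- intensity_map(vec_of(s$lay, stats::setNames(0.7, tx)), s$lay,
                     tau = 1e-4)
  lit <- m[m$class == "assigned", ]
  expect_equal(lit$taxon_id, tx)
  expect_equal(lit$intensity, 1)
  expect_equal(nrow(lit), 1L)
})

test_that("linear max normalization: abundances (0.2, 0.8) give (0.25, 1)", {
  s <- toy_setup()
  v <- vec_of(s$lay, stats::setNames(c(0.2, 0.8), s$lay$taxon_id[1:2]))
  m <- intensity_map(v, s$lay, tau = 1e-4)
  expect_equal(m$intensity[match(s$lay$taxon_id[1:2], m$taxon_id)],
               c(0.25, 1))
})

test_that("log scaling stretches [tau, max] onto [0, 1]", {
  s <- toy_setup()
  v <- vec_of(s$lay, stats::setNames(c(1e-4, 1e-2, 1), s$lay$taxon_id[1:3]))
  m <- intensity_map(v, s$lay, scale = "log", tau = 1e-4)
  got <- m$intensity[match(s$lay$taxon_id[1:3], m$taxon_id)]
  expect_equal(got, c(0, 0.5, 1))
  expect_error(intensity_map(v, s$lay, scale = "log", tau = 0),
               class = "micromaps_input_error")
})

test_that("sub-threshold, gap and assigned cells are distinguishable", {
  ord <- tibble::tibble(taxon_id = c("a", "b", "c"))
  lay <- build_layout(ord, level = 2, reserve = TRUE)
  m <- intensity_map(c(a = 0.9, b = 0.000001, c = 0.1), lay, tau = 1e-4)
  expect_setequal(unique(m$class), c("assigned", "zero", "gap"))
  expect_equal(m$class[match("b", m$taxon_id)], "zero")
  expect_true(all(m$class[is.na(m$taxon_id)] == "gap"))
})

test_that("vector/layout taxon mismatches are reported with the missing ids", {
  s <- toy_setup()
  expect_error(intensity_map(c(bogus = 1), s$lay, tau = 1e-4),
               "missing", class = "micromaps_input_error")
})

test_that("colorless maps carry geometry only, areas proportional to clades", {
  s <- toy_setup()
  m <- colorless_map(s$lay, "genus")
  expect_false("value" %in% names(m))
  expect_equal(sum(is.na(m$label)), 0L)
  expect_equal(unname(table(m$label)), c(8L, 8L), ignore_attr = TRUE)
  nb <- attr(m, "neighborhoods")
  expect_equal(nrow(nb$regions), 2L)

  single_ord <- linearize(build_taxonomy(
    tibble::tibble(taxon_id = "only", genus = "g", species = "s",
                   strain = "only")))
  m1 <- colorless_map(build_layout(single_ord), "genus")
  expect_equal(nrow(attr(m1, "neighborhoods")$regions), 1L)
})

test_that("average of identical samples equals the sample; mean of (0, x) is x/2", {
  s <- toy_setup()
  one <- s$ab[1, ]
  both <- s$ab[c(1, 1), ]
  avg <- average_map(both, s$lay, tau = 1e-4)
  single <- intensity_map(one, s$lay, tau = 1e-4)
  expect_equal(avg$value, single$value)
  expect_equal(avg$intensity, single$intensity)

  taxa <- s$lay$taxon_id
  zero <- vec_of(s$lay)
  x <- stats::setNames(seq_along(taxa) / 100, taxa)
  avg2 <- average_map(list(zero, x), s$lay, tau = 1e-4)
  expect_equal(avg2$value[match(taxa, avg2$taxon_id)], unname(x / 2))
})

test_that("average and aggregate agree with brute-force per-cell reduction", {
  s <- toy_setup(seed = 2)
  five <- s$ab[1:5, ]
  taxa <- s$lay$taxon_id
  mat <- as.matrix(five[taxa])
  avg <- average_map(five, s$lay, tau = 1e-4)
  expect_equal(avg$value[match(taxa, avg$taxon_id)],
               unname(colMeans(mat)))
  agg <- aggregate_map(five, s$lay, reducer = max, tau = 1e-4)
  expect_equal(agg$value[match(taxa, agg$taxon_id)],
               unname(apply(mat, 2, max)))
})

test_that("differential maps: identity zero, antisymmetry, hand example", {
  s <- toy_setup()
  a <- s$ab[1, ]; b <- s$ab[2, ]
  d_aa <- differential_map(a, a, s$lay, tau = 1e-4)
  expect_true(all(d_aa$value == 0))
  expect_true(all(d_aa$intensity == 0))
  expect_equal(unique(d_aa$class), "zero")

  d_ab <- differential_map(a, b, s$lay, tau = 1e-4)
  d_ba <- differential_map(b, a, s$lay, tau = 1e-4)
  expect_equal(d_ab$value, -d_ba$value)
  expect_equal(d_ab$intensity, -d_ba$intensity)
  expect_equal(attr(d_ab, "metadata")$operands, c("a", "b"))

  lay4 <- build_layout(tibble::tibble(taxon_id = c("w", "x", "y", "z")),
                       level = 1)
  dm <- differential_map(c(w = 0.5, x = 0.1, y = 0.2, z = 0.2),
                         c(w = 0.1, x = 0.3, y = 0.2, z = 0.4), lay4)
  expect_equal(dm$value[match(c("w", "x", "y", "z"), dm$taxon_id)],
               c(0.4, -0.2, 0, -0.2))
  expect_equal(max(dm$intensity), 1)  # normalized by the largest |diff|
})

test_that("animation frames share a global scale and preserve count", {
  s <- toy_setup(seed = 4)
  fr <- animation_frames(s$ab[1:3, ], s$lay, tau = 1e-4)
  expect_length(fr, 3L)
  taxa <- s$lay$taxon_id
  global_max <- max(as.matrix(s$ab[1:3, taxa]))
  expect_equal(attr(fr, "global_max"), global_max)
  # the frame containing the global max attains intensity 1; others stay below
  max_int <- vapply(fr, function(f) max(f$intensity), numeric(1))
  expect_equal(max(max_int), 1)
  per_frame_max <- apply(as.matrix(s$ab[1:3, taxa]), 1, max)
  expect_equal(unname(max_int), unname(per_frame_max / global_max))

  const <- s$ab[c(1, 1, 1), ]
  fr2 <- animation_frames(const, s$lay, tau = 1e-4)
  expect_equal(fr2[[1]]$intensity, fr2[[3]]$intensity)
  expect_error(animation_frames(s$ab[1, ], s$lay),
               class = "micromaps_input_error")
})

test_that("curve-path overlay has 4^k vertices, all steps axis-aligned", {
  s <- toy_setup()
  m <- overlay_path(intensity_map(s$ab[1, ], s$lay, tau = 1e-4), s$lay)
  path <- attr(m, "path")
  expect_equal(nrow(path), 16L)
  expect_true(all((diff(path$x) == 0) != (diff(path$y) == 0)))
  # level-1 polyline: 4 vertices, hence 3 segments
  expect_equal(nrow(hilbert_path(1)) - 1L, 3L)
  other <- build_layout(tibble::tibble(taxon_id = paste0("t", 1:60)))
  expect_error(overlay_path(m, other), class = "micromaps_input_error")
})

test_that("PNG export is deterministic and writes sidecar metadata", {
  s <- toy_setup()
  m <- intensity_map(s$ab[1, ], s$lay, tau = 1e-4)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_map_png(m, p1)
  write_map_png(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  meta <- jsonlite::fromJSON(paste0(p1, ".json"))
  expect_equal(meta$level, 2L)
  expect_equal(meta$scale, "linear")
  expect_equal(meta$tau, 1e-4)
  expect_match(meta$orientation, "top-left")
  expect_true(nzchar(meta$order_hash))
})

test_that("autoplot returns a ggplot for every map kind", {
  s <- toy_setup()
  m <- overlay_boundaries(intensity_map(s$ab[1, ], s$lay, tau = 1e-4),
                          s$lay, "genus")
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  expect_s3_class(ggplot2::autoplot(colorless_map(s$lay, "genus")), "ggplot")
  expect_s3_class(
    ggplot2::autoplot(differential_map(s$ab[1, ], s$ab[2, ], s$lay,
                                       tau = 1e-4)),
    "ggplot")
})
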