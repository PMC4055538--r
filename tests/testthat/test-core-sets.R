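toy_counts <- function(mat, datasets = paste0("d", seq_len(ncol(mat)))) {
  rownames(mat) <- sprintf("COG%02d", seq_len(nrow(mat)))
  colnames(mat) <- datasets
  as_count_tbl(mat)
}

toy_zones <- function(n_photic, n_aphotic) {
  setNames(rep(c("photic", "aphotic"), c(n_photic, n_aphotic)),
           paste0("d", seq_len(n_photic + n_aphotic)))
}

test_that("core sets pick up directed group differences and skip degenerates", {
  set.seed(31)
  mat <- matrix(rnorm(50 * 8, mean = 100, sd = 3), nrow = 50)
  mat[1, 1:4] <- mat[1, 1:4] + 60   # photic-enriched
  mat[2, 5:8] <- mat[2, 5:8] + 60   # aphotic-enriched
  mat[3, ] <- 42                    # constant everywhere -> degenerate
  zones <- toy_zones(4, 4)
  core <- derive_core_sets(toy_counts(mat), zones, alpha = 1e-3)
  expect_equal(core$photic_cogs, "COG01")
  expect_equal(core$aphotic_cogs, "COG02")
  expect_true(is.na(tidy(core)$p_value[tidy(core)$cog_id == "COG03"]))
  expect_length(intersect(core$photic_cogs, core$aphotic_cogs), 0L)

  # column order invariance
  perm <- sample(8)
  core_p <- derive_core_sets(toy_counts(mat)[, c(1, perm + 1)], zones[perm],
                             alpha = 1e-3)
  expect_equal(core_p$photic_cogs, core$photic_cogs)
  expect_equal(tidy(core_p)$p_value, tidy(core)$p_value)

  expect_error(derive_core_sets(toy_counts(mat), toy_zones(1, 7)),
               class = "cogdepth_validation_error")
})

test_that("the log2 ratio follows its closed form and antisymmetry", {
  core <- structure(list(photic_cogs = c("P1", "P2"), aphotic_cogs = c("A1")),
                    class = "core_sets")
  v <- c(P1 = 8, P2 = 8, A1 = 2)
  expect_equal(log2_ratio(v, core, pseudocount = 0), 2)
  expect_equal(log2_ratio(c(P1 = 4, P2 = 4, A1 = 4), core, 0), 0)
  swapped <- structure(list(photic_cogs = "A1", aphotic_cogs = c("P1", "P2")),
                       class = "core_sets")
  expect_equal(log2_ratio(v, swapped, 0), -log2_ratio(v, core, 0))

  # monotone: raising a photic COG raises the ratio, an aphotic COG lowers it
  v2 <- v; v2["P1"] <- 10
  expect_gt(log2_ratio(v2, core, 0.5), log2_ratio(v, core, 0.5))
  v3 <- v; v3["A1"] <- 4
  expect_lt(log2_ratio(v3, core, 0.5), log2_ratio(v, core, 0.5))
})

test_that("per-dataset ratios report both linear conventions consistently", {
  core <- structure(list(photic_cogs = "COG01", aphotic_cogs = "COG02"),
                    class = "core_sets")
  counts <- toy_counts(matrix(c(8L, 2L, 2L, 8L), nrow = 2))
  r <- dataset_log2_ratios(normalize_counts(counts), core, pseudocount = 0)
  expect_equal(r$log2_ratio, c(2, -2))
  expect_equal(r$ratio_photic_aphotic * r$ratio_aphotic_photic, c(1, 1))
  expect_equal(r$ratio_aphotic_photic[2], 4)
})

test_that("reference bands are mean +/- two sample SDs, order-invariant", {
  ratios <- tibble::tibble(dataset_id = c("p1", "p2", "p3", "a1", "a2"),
                           log2_ratio = c(2, 2, 2, 1, 3))
  zones <- c(p1 = "photic", p2 = "photic", p3 = "photic",
             a1 = "aphotic", a2 = "aphotic")
  # photic centre exceeds aphotic here only numerically; build valid bands
  bands <- reference_bands(ratios, zones)
  b <- tidy(bands)
  expect_equal(b$halfwidth[b$zone == "photic"], 0)
  expect_equal(b$center[b$zone == "aphotic"], 2)
  expect_equal(b$halfwidth[b$zone == "aphotic"], 2 * sqrt(2))

  bands_r <- reference_bands(ratios[c(4, 2, 5, 1, 3), ], zones)
  expect_equal(tidy(bands_r), tidy(bands))

  expect_error(reference_bands(ratios[c(1, 4, 5), ], zones),
               class = "cogdepth_validation_error")
})

test_that("zone calls follow the band rule, including beyond-band values", {
  bands <- structure(tibble::tibble(zone = c("photic", "aphotic"),
                                    center = c(2, -2),
                                    halfwidth = c(0.5, 0.5), n = c(3L, 3L)),
                     class = c("ratio_bands", "tbl_df", "tbl", "data.frame"))
  expect_equal(classify_zone(2, bands), "photic")
  expect_equal(classify_zone(3.7, bands), "photic")     # above the photic band
  expect_equal(classify_zone(0, bands), "intermediate") # between bands
  expect_equal(classify_zone(-2.4, bands), "aphotic")
  expect_equal(classify_zone(-9, bands), "aphotic")     # below the aphotic band

  overlapping <- bands
  overlapping$halfwidth <- c(3, 3)
  expect_equal(classify_zone(0, overlapping), "intermediate")

  inverted <- bands
  inverted$center <- c(-2, 2)
  expect_error(classify_zone(0, inverted), class = "cogdepth_validation_error")
})
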