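toy_counts <- function(mat, datasets = paste0("d", seq_len(ncol(mat)))) {
  rownames(mat) <- sprintf("COG%02d", seq_len(nrow(mat)))
  colnames(mat) <- datasets
  as_count_tbl(mat)
}

test_that("a column with identical composition yields no depth-related COGs", {
  mat <- matrix(rep(c(10L, 20L, 30L), 4), nrow = 3)
  set <- column_depth_cogs(toy_counts(mat), paste0("d", 1:4))
  expect_length(set$cog_ids, 0L)
  expect_true(all(tidy(set)$p_adj > 0.5))
})

test_that("a strongly depth-shifted COG is detected with a tiny adjusted p", {
  set.seed(77)
  base <- matrix(rpois(2000 * 4, 24L), ncol = 4)
  base[1, ] <- c(500L, 500L, 50L, 50L)
  storage.mode(base) <- "integer"
  counts <- toy_counts(base)
  set <- column_depth_cogs(counts, paste0("d", 1:4), alpha = 0.01)
  expect_true("COG01" %in% set$cog_ids)
  expect_lt(tidy(set)$p_adj[tidy(set)$cog_id == "COG01"], 1e-10)
  # the detected pair is one of the four photic-vs-aphotic contrasts
  expect_match(tidy(set)$pair[tidy(set)$cog_id == "COG01"], "d[12] vs d[34]")
  # permutation of COG order does not change the result set
  perm <- sample(nrow(counts))
  set_p <- column_depth_cogs(counts[perm, ], paste0("d", 1:4), alpha = 0.01)
  expect_equal(set_p$cog_ids, set$cog_ids)
  # binomial flavour agrees on the strong signal
  set_b <- column_depth_cogs(counts, paste0("d", 1:4), test = "binomial")
  expect_true("COG01" %in% set_b$cog_ids)
})

test_that("set intersection and the presence filter behave as set algebra", {
  mk <- function(ids) structure(list(cog_ids = ids, dataset_ids = "d1"),
                                class = "depth_cog_set")
  expect_equal(intersect_depth_cogs(list(mk(c("A", "B")), mk(c("B", "C")),
                                         mk("B"))), "B")
  expect_equal(intersect_depth_cogs(list(mk(c("A", "B")), mk(c("C")))),
               character())
  sets <- list(mk(c("A", "B")), mk(c("A", "B", "C")))
  expect_true(all(intersect_depth_cogs(sets) %in% sets[[1]]$cog_ids))
  expect_error(intersect_depth_cogs(list(mk("A"))),
               class = "cogdepth_validation_error")
})

test_that("clustering recovers a planted two-group structure with high support", {
  set.seed(15)
  centro <- cbind(matrix(3, 40, 5), matrix(-3, 40, 5))
  mat <- centro + matrix(rnorm(400, sd = 0.3), 40, 10)
  z <- zscore_rows(toy_counts(mat, datasets = paste0("s", 1:10)))
  dendro <- cluster_datasets(z, n_boot = 100, seed = 5)
  split <- top_split(dendro)
  expect_true(any(vapply(split, function(s) setequal(s, paste0("s", 1:5)),
                         logical(1))))
  expect_gte(top_split_support(dendro), 95)
  # newick export carries supports as internal node labels
  nwk <- to_newick(dendro)
  expect_match(nwk, "\\)100\\.0:")
})

test_that("duplicate datasets merge first and dataset order is immaterial", {
  set.seed(16)
  mat <- matrix(rnorm(60), 20, 3)
  mat <- cbind(mat, mat[, 3])  # d4 duplicates d3
  z <- toy_counts(mat)
  dendro <- cluster_datasets(z, n_boot = 10, seed = 1)
  first <- sort(strsplit(dendro$support$members[1], ",")[[1]])
  expect_equal(first, c("d3", "d4"))

  perm <- c(3, 1, 4, 2)
  z_p <- z[, c(1, perm + 1)]
  dendro_p <- cluster_datasets(z_p, n_boot = 10, seed = 1)
  expect_setequal(dendro$support$members, dendro_p$support$members)
})

test_that("the photic rule uses the 1% PAR boundary", {
  expect_equal(photic_label(1000, 1000), "photic")
  expect_equal(photic_label(1000, 9), "aphotic")
  # with k = 0.046 the boundary depth is ln(100)/0.046 = 100.1 m
  meta <- tibble::tibble(dataset_id = c("shallow", "boundary", "deep"),
                         site = "X", depth_m = c(50, 100.0, 100.3),
                         do_umol_kg = 100, par_surface = 1000,
                         par_at_depth = NA_real_, attenuation_k = 0.046,
                         zone_label = "unset")
  zones <- assign_zones(meta)
  expect_equal(zones$zone_label, c("photic", "photic", "aphotic"))

  meta$attenuation_k <- NA_real_
  expect_error(assign_zones(meta), class = "cogdepth_validation_error")
})
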