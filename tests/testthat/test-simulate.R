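test_that("light decays exponentially and the 1% boundary is ln(100)/k", {
  expect_equal(par_at_depth(1000, 0.5, 0), 1000)
  expect_equal(par_at_depth(1000, 0.046, 100.113), 10.0, tolerance = 1e-3)
  expect_equal(par_at_depth(500, 0.1, 46.052), 5.0, tolerance = 1e-3)
  z <- par_at_depth(800, 0.05, c(0, 10, 50, 200))
  expect_true(all(diff(z) < 0))
  expect_error(par_at_depth(100, -0.1, 5), class = "cogdepth_validation_error")
})

test_that("the reference design has 24 datasets split 12/12 by the PAR rule", {
  d <- reference_design()
  expect_equal(nrow(d), 24L)
  expect_equal(anyDuplicated(d$dataset_id), 0L)
  photic <- par_at_depth(d$par_surface, d$attenuation_k, d$depth_m) >=
    0.01 * d$par_surface
  expect_equal(sum(photic), 12L)
  # the low-oxygen standard: exactly three datasets below 20 µmol/kg
  expect_equal(sum(d$do_umol_kg < 20), 3L)
})

test_that("simulation is seed-deterministic and respects library sizes", {
  cfg <- sim_config(n_background_cogs = 200, n_photic_markers = 8,
                    n_aphotic_markers = 6, n_o2_markers = 4,
                    library_size_range = c(4000, 5000))
  a <- simulate_cog_data(cfg, seed = 33, reads = TRUE)
  b <- simulate_cog_data(cfg, seed = 33, reads = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)

  libs <- library_sizes(a$counts)
  expect_true(all(libs >= 4000 & libs <= 5000))
  # reads expand counts exactly: row count per dataset = library size
  expect_equal(unname(table(a$reads$dataset_id)[names(libs)]),
               unname(as.integer(libs)), ignore_attr = TRUE)
  # marker lists are pairwise disjoint
  tr <- a$truth
  all_ids <- c(tr$photic_marker_ids, tr$aphotic_marker_ids, tr$o2_marker_ids)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("a lambda=1 mixture reduces to the pure photic composition", {
  cfg <- sim_config(n_background_cogs = 50, n_photic_markers = 5,
                    n_aphotic_markers = 4, n_o2_markers = 2)
  class <- factor(rep(c("background", "photic", "aphotic", "o2"),
                      c(50, 5, 4, 2)),
                  levels = c("background", "photic", "aphotic", "o2"))
  p0 <- rep(1 / 61, 61)
  pure <- cogdepth:::dataset_composition(p0, class, lambda = 1,
                                         o2_on = FALSE, cfg)
  mixed_at_one <- cogdepth:::dataset_composition(p0, class, lambda = 1,
                                                 o2_on = FALSE, cfg)
  expect_equal(mixed_at_one, pure)
  # and the photic markers are boosted by the fold change relative to background
  expect_equal(pure[class == "photic"][1] / pure[class == "background"][1],
               cfg$marker_fold_change)
  # a lambda=0.5 mixture lies between the two pure compositions
  ap <- cogdepth:::dataset_composition(p0, class, 0, FALSE, cfg)
  mid <- cogdepth:::dataset_composition(p0, class, 0.5, FALSE, cfg)
  expect_true(all(mid >= pmin(pure, ap) - 1e-12 & mid <= pmax(pure, ap) + 1e-12))
})

test_that("planted fold change is recovered from large libraries", {
  # law-of-large-numbers check on the on/off relative abundance ratio
  cfg <- sim_config(n_background_cogs = 400, n_photic_markers = 20,
                    n_aphotic_markers = 10, n_o2_markers = 5,
                    library_size_range = c(1e6, 1e6),
                    dirichlet_concentration = 1e9,
                    design = reference_design()[
                      reference_design()$site %in% c("ATII", "GOS1", "PRT"), ])
  sim <- simulate_cog_data(cfg, seed = 21, reads = FALSE)
  mat <- as_count_matrix(sim$counts)
  rel <- sweep(mat, 2, colSums(mat), "/")
  tr <- sim$truth
  on_ds <- names(tr$zone)[tr$zone == "photic" & tr$lambda == 1]
  off_ds <- names(tr$zone)[tr$zone == "aphotic" & tr$lambda == 0]
  # effect_scale is 1 for GOS1 (on) and PRT/ATII_700+1500 (off, scale!=1 ok:
  # compare against per-dataset scaled folds by averaging markers)
  ratio <- mean(rel[tr$photic_marker_ids, "GOS1_2m"]) /
    mean(rel[tr$photic_marker_ids, "PRT_6000m"])
  # composition renormalization shifts the observable ratio slightly below
  # the planted fold; 10% tolerance covers it at this library size
  expect_equal(ratio, cfg$marker_fold_change, tolerance = 0.1)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(marker_fold_change = 0.5),
               class = "cogdepth_validation_error")
  expect_error(sim_config(library_size_range = c(100, 50)),
               class = "cogdepth_validation_error")
  expect_error(sim_config(eukarya_fraction = 0.9, unidentified_fraction = 0.2),
               class = "cogdepth_validation_error")
  d <- reference_design(); d$lambda[1] <- 1.5
  expect_error(sim_config(design = d), class = "cogdepth_validation_error")
})
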