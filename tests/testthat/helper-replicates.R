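# Shared simulation replicates for the end-to-end recovery tests. Each
# replicate runs the full pipeline on freshly simulated reference data and
# keeps only small summary metrics, so several test files can reuse the
# same replicates without recomputation or large residency.

.cogdepth_test_cache <- new.env(parent = emptyenv())

reference_replicate_metrics <- function(i) {
  key <- sprintf("ref%03d", i)
  if (!is.null(.cogdepth_test_cache[[key]])) {
    return(.cogdepth_test_cache[[key]])
  }
  seed <- 1000L + i
  sim <- simulate_cog_data(sim_config(), seed = seed, reads = TRUE)
  res <- run_cog_pipeline(sim$counts, sim$metadata, reads = sim$reads,
                          config = pipeline_config(n_boot = 100), seed = seed)
  tr <- sim$truth
  core <- res$core_sets
  planted <- c(tr$photic_marker_ids, tr$aphotic_marker_ids)
  discovered <- c(core$photic_cogs, core$aphotic_cogs)

  split <- top_split(res$dendrogram)
  truth_photic <- sort(names(tr$zone)[tr$zone == "photic"])
  split_ok <- any(vapply(split, function(s) identical(sort(s), truth_photic),
                         logical(1)))

  calls <- setNames(res$ratios$zone_call, res$ratios$dataset_id)
  lam <- tr$lambda
  pure_photic <- names(lam)[lam == 1]
  pure_aphotic <- names(lam)[lam == 0]
  mixed_mid <- names(lam)[lam >= 0.3 & lam <= 0.7]

  n_gt1 <- function(tab) sum(phylum_share(tab)$share > 0.01)

  metrics <- list(
    recovery_photic = mean(tr$photic_marker_ids %in% core$photic_cogs),
    recovery_aphotic = mean(tr$aphotic_marker_ids %in% core$aphotic_cogs),
    fdp_core = if (length(discovered)) mean(!discovered %in% planted) else 0,
    n_core = length(discovered),
    top_split_ok = split_ok,
    top_split_support = top_split_support(res$dendrogram),
    calls_pure_photic_ok = all(calls[pure_photic] == "photic"),
    calls_pure_aphotic_ok = all(calls[pure_aphotic] == "aphotic"),
    calls_mixed_ok = all(calls[mixed_mid] == "intermediate"),
    omz_recovery = mean(tr$o2_marker_ids %in% res$omz$set$cog_ids),
    threshold = res$omz$threshold$threshold_o2,
    threshold_confident = res$omz$threshold$confident,
    n_phyla_gt1_photic = n_gt1(res$taxonomy$photic),
    n_phyla_gt1_aphotic = n_gt1(res$taxonomy$aphotic))
  .cogdepth_test_cache[[key]] <- metrics
  metrics
}

reference_metrics <- function(n = 20) {
  lapply(seq_len(n), reference_replicate_metrics)
}

# Null replicates: both zone fold changes and the oxygen fold change at 1
# and no compositional overdispersion (the sampling model under which the
# stage tests' null holds exactly), so every discovery is a false positive.
null_replicate_metrics <- function(i) {
  key <- sprintf("null%03d", i)
  if (!is.null(.cogdepth_test_cache[[key]])) {
    return(.cogdepth_test_cache[[key]])
  }
  seed <- 5000L + i
  cfg <- sim_config(marker_fold_change = 1, o2_fold_change = 1,
                    dirichlet_concentration = Inf)
  sim <- simulate_cog_data(cfg, seed = seed, reads = FALSE)
  sub <- subsample_counts(sim$counts, seed = seed)
  norm <- normalize_counts(sub)
  meta <- sim$metadata

  col_ids <- function(site) {
    m <- meta[meta$site == site, ]
    m$dataset_id[order(m$depth_m)]
  }
  depth_fp <- vapply(c("ATII", "ALOHA", "BATS"), function(s) {
    length(column_depth_cogs(sub, col_ids(s), alpha = 0.01)$cog_ids)
  }, numeric(1))

  zones <- assign_zones(meta)
  core <- derive_core_sets(norm, zones, alpha = 1e-4)
  core_fp <- length(core$photic_cogs) + length(core$aphotic_cogs)

  low <- low_o2_datasets(meta, cutoff = 20)
  omz <- omz_cogs(norm, norm$cog_id, low, alpha = 0.05)
  omz_fp <- length(omz$cog_ids)

  metrics <- list(depth_fp = depth_fp, core_fp = core_fp, omz_fp = omz_fp)
  .cogdepth_test_cache[[key]] <- metrics
  metrics
}

null_metrics <- function(n = 20) {
  lapply(seq_len(n), null_replicate_metrics)
}
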