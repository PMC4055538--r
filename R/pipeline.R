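#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis; the defaults are the
#' levels the method prescribes (per-column screen at adjusted p <= 0.01,
#' core sets at 1e-4, OMZ stage at 0.05, dissolved-oxygen cutoff 20
#' µmol/kg, photic PAR fraction 1%).
#'
#' @param reference_sites Site names of the reference water columns.
#' @param omz_site Site name of the OMZ column.
#' @param alpha_depth,alpha_core,alpha_omz Stage significance levels.
#' @param test `"fisher"` or `"binomial"` count test for the column screens.
#' @param n_boot Bootstrap replicates for dataset clustering.
#' @param subsample_target Common depth for rarefaction (`NULL` = smallest
#'   library).
#' @param pseudocount Pseudocount of the ratio diagnostic.
#' @param low_o2_cutoff Dissolved-oxygen cutoff (µmol/kg) defining the
#'   low-oxygen group.
#' @param par_fraction Photic-zone PAR fraction.
#' @param require_presence Apply the presence rule when intersecting the
#'   per-column depth-related sets?
#' @param top_n_phyla Phyla reported per taxonomy table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference_sites = c("ATII", "ALOHA", "BATS"),
                            omz_site = "Iquique",
                            alpha_depth = 0.01,
                            alpha_core = 1e-4,
                            alpha_omz = 0.05,
                            test = c("fisher", "binomial"),
                            n_boot = 1000,
                            subsample_target = NULL,
                            pseudocount = 0.5,
                            low_o2_cutoff = 20,
                            par_fraction = 0.01,
                            require_presence = FALSE,
                            top_n_phyla = 10) {
  test <- match.arg(test)
  for (a in c(alpha_depth, alpha_core, alpha_omz)) {
    if (a <= 0 || a >= 1) stop_validation("alpha values must lie in (0, 1)")
  }
  if (par_fraction <= 0 || par_fraction >= 1) {
    stop_validation("par_fraction must lie in (0, 1)")
  }
  structure(list(reference_sites = reference_sites, omz_site = omz_site,
                 alpha_depth = alpha_depth, alpha_core = alpha_core,
                 alpha_omz = alpha_omz, test = test, n_boot = n_boot,
                 subsample_target = subsample_target,
                 pseudocount = pseudocount, low_o2_cutoff = low_o2_cutoff,
                 par_fraction = par_fraction,
                 require_presence = require_presence,
                 top_n_phyla = top_n_phyla),
            class = "pipeline_config")
}

#' Run the full depth-profiling analysis
#'
#' Executes, in order: rarefaction to a common depth; the per-column
#' depth-related COG screens for each reference site and their
#' intersection; bootstrap-supported clustering of all datasets on the
#' intersected set; PAR-based zone labels and derivation of the
#' photic/aphotic core sets; the per-dataset ratio diagnostic with
#' reference bands and zone calls; the OMZ stage (candidate screen, core
#' exclusion, rank-sum test, group partition, oxygen-threshold estimate);
#' and, when reads are supplied, the phylum-level taxonomy summaries of
#' both core sets. Identical inputs, config and seed give identical
#' results.
#'
#' @param counts Count tibble (all 24 datasets in the reference design).
#' @param metadata Metadata tibble.
#' @param reads Optional read-assignment tibble for the taxonomy stage.
#' @param config A [pipeline_config()].
#' @param seed Integer seed; stage seeds are derived from it.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV, the dendrogram as newick, and a machine-readable
#'   `summary.json`.
#' @return A `cog_pipeline_result` list with elements `subsampled`,
#'   `depth_sets`, `intersected_cogs`, `dendrogram`, `zones`, `core_sets`,
#'   `ratios` (with zone calls), `bands`, `omz` (candidates, set, group-I
#'   profile, threshold), `taxonomy` (or `NULL`) and `summary` (the list
#'   serialised to JSON).
#' @export
run_cog_pipeline <- function(counts, metadata, reads = NULL,
                             config = pipeline_config(), seed = 1,
                             out_dir = NULL) {
  cfg <- config
  known_sites <- unique(metadata$site)
  bad <- setdiff(c(cfg$reference_sites, cfg$omz_site), known_sites)
  if (length(bad)) {
    stop_validation("[stage config] unknown site(s): %s", paste(bad, collapse = ", "))
  }

  sub <- subsample_counts(counts, target = cfg$subsample_target, seed = seed)
  norm <- normalize_counts(sub)

  col_ids <- function(site) {
    m <- metadata |> filter(.data$site == !!site) |> arrange(.data$depth_m)
    m$dataset_id
  }
  depth_sets <- lapply(cfg$reference_sites, function(s) {
    column_depth_cogs(sub, col_ids(s), alpha = cfg$alpha_depth,
                      test = cfg$test, site = s)
  })
  names(depth_sets) <- cfg$reference_sites
  intersected <- intersect_depth_cogs(depth_sets, counts = sub,
                                      require_presence = cfg$require_presence)
  if (length(intersected) < 2L) {
    stop_validation("[stage intersect] fewer than 2 shared depth-related COGs")
  }

  z <- zscore_rows(norm |> filter(.data$cog_id %in% intersected))
  dendro <- cluster_datasets(z, n_boot = cfg$n_boot, seed = seed + 1L)

  zones <- assign_zones(metadata, par_fraction = cfg$par_fraction)
  core <- derive_core_sets(norm |> filter(.data$cog_id %in% intersected),
                           zones, alpha = cfg$alpha_core)
  if (!length(core$photic_cogs) || !length(core$aphotic_cogs)) {
    stop_validation("[stage core-sets] an empty core set; cannot form the ratio diagnostic")
  }

  ratios <- dataset_log2_ratios(norm, core, pseudocount = cfg$pseudocount)
  ref_ids <- zones$dataset_id[zones$site %in% cfg$reference_sites]
  bands <- reference_bands(ratios |> filter(.data$dataset_id %in% ref_ids),
                           zones)
  ratios <- classify_zones(ratios, bands)

  omz_cand <- omz_candidates(sub, col_ids(cfg$omz_site),
                             alpha = cfg$alpha_depth, test = cfg$test,
                             site = cfg$omz_site)
  omz_ids <- exclude_core(omz_cand, core)
  low_ids <- low_o2_datasets(metadata, cutoff = cfg$low_o2_cutoff)
  omz <- omz_cogs(norm, omz_ids, low_ids, alpha = cfg$alpha_omz)
  profile <- NULL; threshold <- NULL
  if (any(!is.na(omz$table$group) & omz$table$group == "I")) {
    profile <- group_i_profile(norm, omz, metadata)
    threshold <- oxygen_threshold(profile)
  }

  taxonomy <- NULL
  if (!is.null(reads)) {
    photic_tab <- summarize_phyla(reads, core$photic_cogs)
    aphotic_tab <- summarize_phyla(reads, core$aphotic_cogs)
    taxonomy <- list(
      photic = photic_tab, aphotic = aphotic_tab,
      top_photic = top_phyla(photic_tab, cfg$top_n_phyla),
      top_aphotic = top_phyla(aphotic_tab, cfg$top_n_phyla),
      share_photic = phylum_share(photic_tab),
      share_aphotic = phylum_share(aphotic_tab))
  }

  summary <- list(
    seed = seed,
    subsample_target = min(library_sizes(sub)),
    n_depth_cogs = lapply(depth_sets, function(s) length(s$cog_ids)),
    n_intersected = length(intersected),
    n_core_photic = length(core$photic_cogs),
    n_core_aphotic = length(core$aphotic_cogs),
    top_split_support = top_split_support(dendro),
    bands = as.data.frame(tidy(bands)),
    zone_calls = setNames(ratios$zone_call, ratios$dataset_id),
    n_omz_candidates = length(omz_ids),
    n_omz_cogs = length(omz$cog_ids),
    o2_threshold = if (!is.null(threshold)) threshold$threshold_o2 else NA,
    config = unclass(cfg)[setdiff(names(unclass(cfg)), "subsample_target")])

  result <- structure(list(subsampled = sub, depth_sets = depth_sets,
                           intersected_cogs = intersected, dendrogram = dendro,
                           zones = zones, core_sets = core, ratios = ratios,
                           bands = bands,
                           omz = list(candidates = omz_cand, set = omz,
                                      group_i_profile = profile,
                                      threshold = threshold),
                           taxonomy = taxonomy, summary = summary),
                      class = "cog_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (s in names(result$depth_sets)) {
    write_result_table(tidy(result$depth_sets[[s]]),
                       p(sprintf("depth_cogs_%s.tsv", s)))
  }
  write_result_table(tibble(cog_id = result$intersected_cogs),
                     p("intersected_cogs.tsv"))
  to_newick(result$dendrogram, p("dendrogram.nwk"))
  write_result_table(tidy(result$core_sets), p("core_sets.tsv"))
  write_result_table(result$ratios, p("ratios.tsv"))
  write_result_table(tidy(result$omz$set), p("omz_cogs.tsv"))
  if (!is.null(result$omz$group_i_profile)) {
    write_result_table(result$omz$group_i_profile, p("group_i_profile.tsv"))
  }
  if (!is.null(result$taxonomy)) {
    write_result_table(result$taxonomy$photic, p("phylum_counts_photic.tsv"))
    write_result_table(result$taxonomy$aphotic, p("phylum_counts_aphotic.tsv"))
  }
  jsonlite::write_json(result$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(result)
}

#' @export
print.cog_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Depth-profiling pipeline result\n")
  cat("  depth-related COGs per column:",
      paste(names(s$n_depth_cogs), unlist(s$n_depth_cogs), sep = "=",
            collapse = ", "), "\n")
  cat("  shared set:", s$n_intersected,
      "| core sets:", s$n_core_photic, "photic /", s$n_core_aphotic,
      "aphotic\n")
  cat("  top-split bootstrap support:", round(s$top_split_support, 1), "\n")
  cat("  OMZ COGs:", s$n_omz_cogs, "| oxygen threshold estimate:",
      signif(s$o2_threshold, 4), "µmol/kg\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cog_pipeline_result <- function(x, ...) {
  s <- x$summary
  tibble(n_intersected = s$n_intersected, n_core_photic = s$n_core_photic,
         n_core_aphotic = s$n_core_aphotic, n_omz_cogs = s$n_omz_cogs,
         top_split_support = s$top_split_support,
         o2_threshold = s$o2_threshold)
}
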