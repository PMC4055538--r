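#' Derive the photic/aphotic global-core COG sets
#'
#' Per COG, Welch's unequal-variance t-test compares normalized abundance
#' between the photic and aphotic dataset groups; p-values are
#' Benjamini-Hochberg adjusted and COGs with adjusted p <= `alpha`
#' (default 1e-4) are retained, assigned photic or aphotic by the larger
#' group mean. COGs with zero variance in both groups are degenerate and
#' excluded from testing.
#'
#' @param norm Normalized abundance tibble (`cog_id` + dataset columns),
#'   typically restricted to an intersected depth-related set.
#' @param zones Zone labels: a metadata tibble with `dataset_id` and
#'   `zone_label`, or a named character vector (`photic` / `aphotic`).
#'   Each group needs >= 2 datasets.
#' @param alpha Significance level on the adjusted p (default 1e-4; the
#'   companion Methods-style level 0.05 is available by argument).
#' @return A `core_sets` object: the full test table (via [tidy()]) plus
#'   `photic_cogs` and `aphotic_cogs`, the two disjoint marker lists.
#' @export
derive_core_sets <- function(norm, zones, alpha = 1e-4) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")
  zl <- zone_vector(zones)
  mat <- as_count_matrix(norm)
  zl <- zl[intersect(names(zl), colnames(mat))]
  photic_ids <- names(zl)[zl == "photic"]
  aphotic_ids <- names(zl)[zl == "aphotic"]
  if (length(photic_ids) < 2L || length(aphotic_ids) < 2L) {
    stop_validation("each zone group needs >= 2 datasets (got %d photic, %d aphotic)",
                    length(photic_ids), length(aphotic_ids))
  }
  w <- welch_rows(mat, photic_ids, aphotic_ids)
  tab <- tibble(cog_id = rownames(mat)) |>
    bind_cols(w) |>
    rename(mean_photic = "mean1", mean_aphotic = "mean2") |>
    mutate(p_adj = bh_fdr(.data$p_value),
           direction = if_else(.data$mean_photic > .data$mean_aphotic,
                               "photic", "aphotic"),
           significant = !is.na(.data$p_adj) & .data$p_adj <= alpha) |>
    arrange(.data$cog_id)
  structure(list(table = tab, alpha = alpha,
                 photic_cogs = sort(tab$cog_id[tab$significant &
                                                 tab$direction == "photic"]),
                 aphotic_cogs = sort(tab$cog_id[tab$significant &
                                                  tab$direction == "aphotic"]),
                 photic_datasets = photic_ids, aphotic_datasets = aphotic_ids),
            class = "core_sets")
}

zone_vector <- function(zones) {
  if (is.data.frame(zones)) {
    zl <- setNames(zones$zone_label, zones$dataset_id)
  } else {
    zl <- zones
  }
  zl <- zl[zl %in% c("photic", "aphotic")]
  if (!length(zl)) stop_validation("no photic/aphotic labels supplied")
  zl
}

#' @export
print.core_sets <- function(x, ...) {
  cat("Photic/aphotic core COG sets (Welch, BH-adjusted p <=", x$alpha, ")\n")
  cat("  ", length(x$photic_cogs), "photic,", length(x$aphotic_cogs),
      "aphotic of", nrow(x$table), "tested\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.core_sets <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.core_sets <- function(x, ...) {
  tibble(n_tested = nrow(x$table), n_photic = length(x$photic_cogs),
         n_aphotic = length(x$aphotic_cogs), alpha = x$alpha)
}

#' Log2 photic:aphotic abundance ratio of one dataset
#'
#' `log2((mean over the photic core set + pseudocount) /
#' (mean over the aphotic core set + pseudocount))`. The pseudocount
#' (default 0.5 normalized-abundance units) guards empty aphotic means on
#' very small inputs.
#'
#' @param values Named numeric vector of one dataset's normalized
#'   abundances (names = COG ids).
#' @param core A `core_sets` object with both sets nonempty.
#' @param pseudocount Non-negative pseudocount (default 0.5).
#' @return The log2 ratio (a scalar).
#' @export
log2_ratio <- function(values, core, pseudocount = 0.5) {
  if (!length(core$photic_cogs) || !length(core$aphotic_cogs)) {
    stop_validation("both core sets must be nonempty")
  }
  mp <- mean(values[core$photic_cogs])
  ma <- mean(values[core$aphotic_cogs])
  log2((mp + pseudocount) / (ma + pseudocount))
}

#' Per-dataset photic:aphotic ratio diagnostic
#'
#' Computes, for every dataset, the mean normalized abundance over the
#' photic and aphotic core sets and the log2 photic:aphotic ratio; both
#' linear ratio conventions are reported explicitly since the field quotes
#' either direction.
#'
#' @param norm Normalized abundance tibble covering the core COGs.
#' @param core A `core_sets` object.
#' @param pseudocount See [log2_ratio()].
#' @return Tibble with columns `dataset_id`, `mean_photic_set`,
#'   `mean_aphotic_set`, `log2_ratio`, `ratio_photic_aphotic`,
#'   `ratio_aphotic_photic`.
#' @export
dataset_log2_ratios <- function(norm, core, pseudocount = 0.5) {
  if (!length(core$photic_cogs) || !length(core$aphotic_cogs)) {
    stop_validation("both core sets must be nonempty")
  }
  mat <- as_count_matrix(norm)
  missing <- setdiff(c(core$photic_cogs, core$aphotic_cogs), rownames(mat))
  if (length(missing)) {
    stop_validation("core COG(s) absent from abundance table: %s",
                    paste(head(missing, 3), collapse = ", "))
  }
  mp <- unname(colMeans(mat[core$photic_cogs, , drop = FALSE])) + pseudocount
  ma <- unname(colMeans(mat[core$aphotic_cogs, , drop = FALSE])) + pseudocount
  tibble(dataset_id = colnames(mat),
         mean_photic_set = mp - pseudocount,
         mean_aphotic_set = ma - pseudocount,
         log2_ratio = log2(mp / ma),
         ratio_photic_aphotic = mp / ma,
         ratio_aphotic_photic = ma / mp)
}

#' Reference photic/aphotic ratio bands
#'
#' From the log2 ratios of the reference-column datasets, per zone label:
#' centre = mean, halfwidth = 2 x sample SD. Values within (or beyond, on
#' the enriched side of) a band indicate photic or aphotic functional
#' enrichment.
#'
#' @param ratios Ratio tibble from [dataset_log2_ratios()], restricted to
#'   the reference datasets.
#' @param zones Zone labels (tibble or named vector), >= 2 reference
#'   datasets per label.
#' @return A `ratio_bands` object (tibble of zone, center, halfwidth, n).
#' @export
reference_bands <- function(ratios, zones) {
  zl <- zone_vector(zones)
  r <- ratios |> filter(.data$dataset_id %in% names(zl)) |>
    mutate(zone = unname(zl[.data$dataset_id]))
  bands <- r |>
    group_by(.data$zone) |>
    summarise(center = mean(.data$log2_ratio),
              halfwidth = 2 * sd(.data$log2_ratio),
              n = n(), .groups = "drop")
  if (!all(c("photic", "aphotic") %in% bands$zone) || any(bands$n < 2L)) {
    stop_validation("need >= 2 reference datasets per zone label")
  }
  structure(bands, class = c("ratio_bands", class(bands)))
}

#' @exportS3Method generics::tidy
tidy.ratio_bands <- function(x, ...) as_tibble(unclass(x))

band_params <- function(bands, zone) {
  i <- which(bands$zone == zone)
  list(center = bands$center[i], halfwidth = bands$halfwidth[i])
}

#' Classify datasets by their ratio diagnostic
#'
#' A value within the photic band or above it is called photic; within the
#' aphotic band or below it, aphotic; anything between the bands — the
#' signature of mixed-layer ("facultatively photic") communities — is
#' intermediate. A value covered by both (overlapping) bands is also
#' intermediate.
#'
#' @param value Numeric vector of log2 ratios.
#' @param bands A `ratio_bands` object whose photic centre exceeds the
#'   aphotic centre.
#' @return Character vector of calls (`photic`/`aphotic`/`intermediate`).
#' @export
classify_zone <- function(value, bands) {
  ph <- band_params(bands, "photic")
  ap <- band_params(bands, "aphotic")
  if (!length(ph$center) || !length(ap$center)) {
    stop_validation("bands must contain both zones")
  }
  if (ph$center <= ap$center) {
    stop_validation("photic band centre must exceed the aphotic centre")
  }
  is_ph <- value >= ph$center - ph$halfwidth
  is_ap <- value <= ap$center + ap$halfwidth
  case_when(is_ph & is_ap ~ "intermediate",
            is_ph ~ "photic",
            is_ap ~ "aphotic",
            TRUE ~ "intermediate")
}

#' @rdname classify_zone
#' @param ratios Ratio tibble from [dataset_log2_ratios()].
#' @return `classify_zones()`: the ratio tibble with a `zone_call` column.
#' @export
classify_zones <- function(ratios, bands) {
  ratios |> mutate(zone_call = classify_zone(.data$log2_ratio, bands))
}
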