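#' Phylum-level summary of core-COG reads
#'
#' Counts reads assigned to the given core COGs per (phylum, COG, dataset),
#' after discarding Eukarya and unidentified reads (missing phylum or
#' superkingdom, or either labelled unidentified). Counts are raw, not
#' normalized.
#'
#' @param reads Read-assignment tibble (see [read_read_assignments()]).
#' @param core_cogs Character vector of COG ids to keep.
#' @param datasets Optional dataset ids to keep (default: all).
#' @return A `phylum_counts` tibble (`phylum`, `cog_id`, `dataset_id`, `n`)
#'   with attributes `retained_total` (reads kept) and `discarded_total`
#'   (Eukarya/unidentified reads among the selected COGs and datasets).
#' @export
summarize_phyla <- function(reads, core_cogs, datasets = NULL) {
  sel <- reads |> filter(.data$cog_id %in% core_cogs)
  if (!is.null(datasets)) sel <- sel |> filter(.data$dataset_id %in% datasets)
  drop <- is.na(sel$phylum) | is.na(sel$superkingdom) |
    sel$superkingdom %in% c("Eukarya", "unidentified") |
    sel$phylum %in% c("", "unidentified", "Eukarya_phylum")
  kept <- sel[!drop, ]
  out <- kept |>
    count(.data$phylum, .data$cog_id, .data$dataset_id) |>
    arrange(.data$phylum, .data$cog_id, .data$dataset_id)
  attr(out, "retained_total") <- nrow(kept)
  attr(out, "discarded_total") <- sum(drop)
  class(out) <- c("phylum_counts", class(out))
  out
}

#' Top phyla by mean per-dataset read count
#'
#' Phyla ranked by their mean total count per dataset (mean over the
#' datasets present in the table), descending, ties broken
#' lexicographically.
#'
#' @param table A `phylum_counts` tibble.
#' @param n Number of phyla to return (default 10).
#' @return Character vector of at most `n` phylum names.
#' @export
top_phyla <- function(table, n = 10) {
  if (n < 1) stop_validation("n must be >= 1")
  if (!nrow(table)) return(character())
  n_ds <- length(unique(table$dataset_id))
  ranked <- table |>
    group_by(.data$phylum) |>
    summarise(mean_count = sum(.data$n) / n_ds, .groups = "drop") |>
    arrange(desc(.data$mean_count), .data$phylum)
  head(ranked$phylum, n)
}

#' Phylum share of retained reads
#'
#' Fraction of the retained (identified, prokaryotic, core-COG) reads
#' contributed by each phylum; fractions sum to one.
#'
#' @param table A `phylum_counts` tibble with a positive total.
#' @return Tibble with `phylum` and `share`, sorted by decreasing share.
#' @export
phylum_share <- function(table) {
  total <- sum(table$n)
  if (!total) stop_validation("phylum table has zero total count")
  table |>
    group_by(.data$phylum) |>
    summarise(share = sum(.data$n) / total, .groups = "drop") |>
    arrange(desc(.data$share), .data$phylum)
}
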