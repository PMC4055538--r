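#' Read a COG count table
#'
#' Reads read-per-COG-per-dataset counts from one of two tab-separated
#' layouts: a wide count matrix (first column COG identifiers, one further
#' column per dataset) or a long per-read assignment table with columns
#' `read_id`, `dataset_id`, `cog_id`, `superkingdom`, `phylum`, which is
#' aggregated to counts. Cells absent from an assignment table are zero
#' counts, the usual shotgun-counting semantics.
#'
#' COG identifiers are opaque strings matched case-sensitively; any
#' orthologous-group vocabulary (COG, NOG, ...) is accepted.
#'
#' @param path Path to a TSV file.
#' @param format `"matrix"` for the wide layout, `"reads"` for the per-read
#'   assignment layout.
#' @return A count tibble: column `cog_id` plus one integer column per
#'   dataset. Column sums are the per-dataset library sizes (total assigned
#'   reads).
#' @seealso [read_read_assignments()], [read_metadata()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("cog_id\tds1\tds2", "COG0001\t5\t2", "COG0002\t0\t7"), tf)
#' read_cog_counts(tf)
read_cog_counts <- function(path, format = c("matrix", "reads")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  if (format == "reads") {
    reads <- read_read_assignments(path)
    return(aggregate_read_counts(reads))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tbl) < 2L) {
    stop_format("count matrix needs a COG id column plus at least one dataset column")
  }
  names(tbl)[1] <- "cog_id"
  counts <- tbl
  for (nm in names(counts)[-1]) {
    v <- suppressWarnings(as.numeric(counts[[nm]]))
    if (anyNA(v)) stop_validation("non-numeric count in column '%s'", nm)
    if (any(v < 0)) stop_validation("negative count in column '%s'", nm)
    if (any(v != round(v))) stop_validation("non-integer count in column '%s'", nm)
    counts[[nm]] <- as.integer(round(v))
  }
  validate_cog_counts(counts)
  counts
}

#' Read a per-read COG/taxonomy assignment table
#'
#' The table is the tabular stand-in for a best-hit functional and taxonomic
#' assignment of each shotgun read: columns `read_id`, `dataset_id`,
#' `cog_id`, `superkingdom`, `phylum` (tab-separated, header row).
#'
#' @param path Path to a TSV file.
#' @return A tibble with the five columns above.
#' @export
read_read_assignments <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("read_id", "dataset_id", "cog_id", "superkingdom", "phylum")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_format("read assignment table lacks column(s): %s",
                paste(missing, collapse = ", "))
  }
  dup <- tbl |> count(.data$dataset_id, .data$read_id) |> filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_validation("duplicated read_id within dataset (e.g. %s / %s)",
                    dup$dataset_id[1], dup$read_id[1])
  }
  tbl[need]
}

#' Aggregate a read-assignment table to a count tibble
#'
#' @param reads A tibble as returned by [read_read_assignments()].
#' @return A count tibble (see [read_cog_counts()]); the column sum per
#'   dataset equals that dataset's number of assigned reads.
#' @export
aggregate_read_counts <- function(reads) {
  counts <- reads |>
    count(.data$cog_id, .data$dataset_id) |>
    tidyr::pivot_wider(names_from = "dataset_id", values_from = "n",
                       values_fill = 0L) |>
    arrange(.data$cog_id)
  validate_cog_counts(counts)
  counts
}

#' Read dataset metadata
#'
#' Required columns: `dataset_id`, `site`, `depth_m`, `do_umol_kg`
#' (dissolved oxygen). Optional: `par_surface`, `par_at_depth`
#' (photosynthetically active radiation, same units at both depths),
#' `attenuation_k` (diffuse light attenuation, 1/m, used to derive
#' at-depth PAR when it was not measured) and `zone_label`.
#'
#' @param path Path to a TSV file.
#' @return A metadata tibble, one row per dataset; `zone_label` is
#'   `"unset"` unless provided.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  need <- c("dataset_id", "site", "depth_m", "do_umol_kg")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_format("metadata lacks required column(s): %s", paste(missing, collapse = ", "))
  }
  for (nm in c("par_surface", "par_at_depth", "attenuation_k")) {
    if (!nm %in% names(tbl)) tbl[[nm]] <- NA_real_
    tbl[[nm]] <- as.numeric(tbl[[nm]])
  }
  if (!"zone_label" %in% names(tbl)) tbl$zone_label <- "unset"
  tbl$zone_label[is.na(tbl$zone_label)] <- "unset"
  validate_metadata(tbl)
  tbl[c(need, "par_surface", "par_at_depth", "attenuation_k", "zone_label")]
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$dataset_id)) {
    stop_validation("duplicated dataset_id in metadata")
  }
  if (any(is.na(meta$depth_m)) || any(meta$depth_m < 0)) {
    stop_validation("depth_m must be non-negative")
  }
  if (any(!is.na(meta$do_umol_kg) & meta$do_umol_kg < 0)) {
    stop_validation("do_umol_kg must be non-negative")
  }
  bad <- !meta$zone_label %in% c("photic", "aphotic", "unset")
  if (any(bad)) stop_validation("zone_label must be photic/aphotic/unset")
  invisible(meta)
}

validate_cog_counts <- function(counts) {
  if (!"cog_id" %in% names(counts) || ncol(counts) < 2L) {
    stop_format("count table must have a cog_id column plus dataset columns")
  }
  if (anyDuplicated(counts$cog_id)) stop_validation("duplicated cog_id in count table")
  mat <- as.matrix(counts[-1])
  if (!is.numeric(mat)) stop_validation("counts must be numeric")
  if (any(mat < 0)) stop_validation("counts must be non-negative")
  if (any(mat != round(mat))) stop_validation("counts must be integral")
  invisible(counts)
}

#' Convert a count/abundance tibble to a plain matrix
#'
#' @param counts Tibble with `cog_id` plus per-dataset columns.
#' @return Numeric matrix, rows named by COG id, columns by dataset id.
#' @export
as_count_matrix <- function(counts) {
  mat <- as.matrix(counts[-1])
  rownames(mat) <- counts$cog_id
  mat
}

#' Convert a matrix back to the count tibble layout
#'
#' @param mat Matrix with COG rownames and dataset colnames.
#' @return Tibble with `cog_id` first.
#' @export
as_count_tbl <- function(mat) {
  bind_cols(tibble(cog_id = rownames(mat)), as_tibble(mat))
}

#' Per-dataset library sizes
#'
#' @param counts A count tibble.
#' @return Named integer vector of column sums (assigned reads per dataset).
#' @export
library_sizes <- function(counts) {
  colSums(as_count_matrix(counts))
}

#' Write / read a result table
#'
#' Result tables are plain TSV (header row, "." decimal separator, UTF-8,
#' no quoting); numbers round-trip to at least 12 significant digits.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `write_result_table()` returns `table` invisibly;
#'   `read_result_table()` returns a tibble.
#' @export
write_result_table <- function(table, path) {
  out <- as_tibble(table)
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(table)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                  progress = FALSE)
}
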