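#' Screen one water column for depth-related COGs
#'
#' For every COG and every pair of depths within a water column, tests
#' whether the COG's relative abundance differs between the two equal-depth
#' libraries (Fisher's exact test on the 2x2 table of COG vs remaining
#' reads, or the conditional binomial alternative). All (COG, pair)
#' p-values of the column are Benjamini-Hochberg adjusted jointly; a COG is
#' depth-related when any pair reaches adjusted p <= `alpha`.
#'
#' @param counts Equal-depth count tibble (see [subsample_counts()]).
#' @param dataset_ids Datasets forming the column, ordered by depth
#'   (>= 2 required).
#' @param alpha Significance level on the adjusted p (default 0.01).
#' @param test `"fisher"` (default) or `"binomial"`.
#' @param site Optional site name carried into the result.
#' @return A `depth_cog_set`: the per-COG best pair with its adjusted p
#'   (via [tidy()]), and `cog_ids`, the sorted significant COGs.
#' @export
column_depth_cogs <- function(counts, dataset_ids, alpha = 0.01,
                              test = c("fisher", "binomial"), site = NULL) {
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")
  if (length(dataset_ids) < 2L) stop_validation("a column needs >= 2 datasets")
  mat <- as_count_matrix(counts)
  missing <- setdiff(dataset_ids, colnames(mat))
  if (length(missing)) {
    stop_validation("dataset(s) absent from counts: %s",
                    paste(missing, collapse = ", "))
  }
  mat <- mat[, dataset_ids, drop = FALSE]
  libs <- colSums(mat)
  pairs <- combn(dataset_ids, 2L)
  res <- map(seq_len(ncol(pairs)), function(i) {
    d1 <- pairs[1, i]; d2 <- pairs[2, i]
    p <- if (test == "fisher") {
      fisher_p_vec(mat[, d1], libs[[d1]], mat[, d2], libs[[d2]])
    } else {
      mapply(binom_p_one, mat[, d1], mat[, d1] + mat[, d2],
             libs[[d1]] / (libs[[d1]] + libs[[d2]]), USE.NAMES = FALSE)
    }
    tibble(cog_id = rownames(mat), pair = paste(d1, d2, sep = " vs "),
           p_value = p)
  }) |> bind_rows()
  res$p_adj <- bh_fdr(res$p_value)
  best <- res |>
    group_by(.data$cog_id) |>
    slice_min(.data$p_adj, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    mutate(significant = .data$p_adj <= alpha) |>
    arrange(.data$cog_id)
  structure(list(site = site %||% NA_character_, alpha = alpha, test = test,
                 dataset_ids = dataset_ids, table = best,
                 cog_ids = sort(best$cog_id[best$significant])),
            class = "depth_cog_set")
}

#' @export
print.depth_cog_set <- function(x, ...) {
  cat("Depth-related COG screen",
      if (!is.na(x$site)) paste0("(", x$site, ")"), "\n")
  cat("  ", length(x$dataset_ids), "depths,", nrow(x$table), "COGs tested,",
      length(x$cog_ids), "significant at adjusted p <=", x$alpha, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.depth_cog_set <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.depth_cog_set <- function(x, ...) {
  tibble(site = x$site, n_tested = nrow(x$table),
         n_significant = length(x$cog_ids), alpha = x$alpha, test = x$test)
}

#' Intersect depth-related COG sets across water columns
#'
#' COGs significant in every column; optionally also required to have a
#' nonzero count in at least one dataset of each column (the presence
#' rule).
#'
#' @param sets List of `depth_cog_set` objects (>= 2).
#' @param counts Count tibble; required when `require_presence = TRUE`.
#' @param require_presence Apply the presence filter?
#' @return Sorted character vector of COG ids.
#' @export
intersect_depth_cogs <- function(sets, counts = NULL, require_presence = FALSE) {
  if (length(sets) < 2L) stop_validation("need >= 2 sets to intersect")
  ids <- Reduce(intersect, lapply(sets, function(s) s$cog_ids))
  if (require_presence) {
    if (is.null(counts)) stop_validation("presence filter needs the count table")
    mat <- as_count_matrix(counts)
    for (s in sets) {
      present <- rowSums(mat[, s$dataset_ids, drop = FALSE] > 0) > 0
      ids <- ids[ids %in% rownames(mat)[present]]
    }
  }
  sort(ids)
}

leafset_key <- function(labels) paste(sort(labels), collapse = "\r")

# All internal-node leaf sets of an hclust tree, by merge order.
hclust_leafsets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    sets[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) hc$labels[-k] else sets[[k]]
    }))
  }
  sets
}

#' Cluster datasets with bootstrap node support
#'
#' Agglomerative (average linkage) clustering of datasets on the Euclidean
#' distance over COG dimensions of a Z-scored abundance matrix. Node
#' support is the percentage of `n_boot` replicate trees — each built from
#' a with-replacement resample of the COGs — that contain the same leaf
#' set under some node.
#'
#' @param z Z-scored abundance tibble (`cog_id` + dataset columns,
#'   >= 2 non-constant COGs, >= 3 datasets).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `boot_dendro`: the `hclust` tree, a support table (one row per
#'   internal node: member datasets, size, support %) and `n_boot`.
#' @export
cluster_datasets <- function(z, n_boot = 1000, seed = 1) {
  mat <- as_count_matrix(z)
  if (ncol(mat) < 3L) stop_validation("clustering needs >= 3 datasets")
  nonconst <- apply(mat, 1L, function(v) sd(v) > 0)
  if (sum(nonconst) < 2L) stop_validation("clustering needs >= 2 non-constant COGs")
  mat <- mat[nonconst, , drop = FALSE]
  hc <- hclust(dist(t(mat)), method = "average")
  sets <- hclust_leafsets(hc)
  keys <- vapply(sets, leafset_key, character(1))
  hits <- setNames(numeric(length(keys)), keys)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(mat), replace = TRUE)
      hb <- hclust(dist(t(mat[idx, , drop = FALSE])), method = "average")
      bk <- unique(vapply(hclust_leafsets(hb), leafset_key, character(1)))
      present <- keys %in% bk
      hits[present] <- hits[present] + 1
    }
  })
  support <- tibble(
    node = seq_along(sets),
    members = map_chr(sets, ~ paste(sort(.x), collapse = ",")),
    size = lengths(sets),
    support = 100 * unname(hits) / n_boot)
  structure(list(hclust = hc, support = support, n_boot = n_boot),
            class = "boot_dendro")
}

#' @export
print.boot_dendro <- function(x, ...) {
  cat("Bootstrap-supported dendrogram over", length(x$hclust$labels),
      "datasets (", x$n_boot, "replicates)\n")
  top <- x$support |> filter(.data$size == length(x$hclust$labels) - 1 |
                               .data$node == nrow(x$support))
  cat("  root-level support:",
      paste(sprintf("%.0f", top$support), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.boot_dendro <- function(x, ...) x$support

#' @exportS3Method generics::glance
glance.boot_dendro <- function(x, ...) {
  tibble(n_datasets = length(x$hclust$labels), n_boot = x$n_boot,
         min_support = min(x$support$support),
         top_split_support = top_split_support(x))
}

#' Bootstrap support of the root bipartition
#'
#' The two root children carry the same dataset bipartition; their recorded
#' supports can differ slightly (a child set may recur nested inside a
#' replicate tree without its complement), so the conservative minimum of
#' the two is reported. A singleton child is trivially present in every
#' replicate and counts as 100.
#'
#' @param dendro A `boot_dendro`.
#' @return Support percentage in \[0, 100\].
#' @export
top_split_support <- function(dendro) {
  n <- nrow(dendro$support)
  kids <- dendro$hclust$merge[n, ]
  sup <- map_dbl(kids, function(k) {
    if (k < 0) 100 else dendro$support$support[k]
  })
  min(sup)
}

#' The leaf sets of the two branches under the root
#'
#' @param dendro A `boot_dendro`.
#' @return List of two character vectors partitioning the datasets.
#' @export
top_split <- function(dendro) {
  hc <- dendro$hclust
  sets <- hclust_leafsets(hc)
  kids <- hc$merge[nrow(hc$merge), ]
  lapply(kids, function(k) if (k < 0) hc$labels[-k] else sort(sets[[k]]))
}

#' Export a bootstrap dendrogram as newick
#'
#' Internal nodes are labelled with their bootstrap support (percent,
#' rounded to one decimal).
#'
#' @param dendro A `boot_dendro`.
#' @param path Optional output file; when `NULL` the newick string is
#'   returned.
#' @return The newick string, invisibly when written to `path`.
#' @export
to_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(dendro$hclust)
  parts <- ape::prop.part(phy)
  keys <- vapply(parts, function(i) leafset_key(phy$tip.label[i]), character(1))
  lookup <- setNames(dendro$support$support,
                     vapply(strsplit(dendro$support$members, ","), leafset_key,
                            character(1)))
  phy$node.label <- ifelse(keys %in% names(lookup),
                           sprintf("%.1f", lookup[keys]), "")
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Label datasets photic or aphotic from light metadata
#'
#' A dataset is photic when its at-depth PAR is at least `par_fraction`
#' (default 1%) of the surface PAR. At-depth PAR is taken from
#' `par_at_depth` or, when absent, derived from `par_surface` and
#' `attenuation_k` via [par_at_depth()].
#'
#' @param metadata Metadata tibble (see [read_metadata()]).
#' @param par_fraction Photic-zone PAR fraction (default 0.01).
#' @return The metadata with `zone_label` filled in.
#' @export
assign_zones <- function(metadata, par_fraction = 0.01) {
  if (par_fraction <= 0 || par_fraction >= 1) {
    stop_validation("par_fraction must lie in (0, 1)")
  }
  pad <- metadata$par_at_depth
  derive <- is.na(pad)
  if (any(derive)) {
    ok <- !is.na(metadata$par_surface) & !is.na(metadata$attenuation_k)
    if (any(derive & !ok)) {
      stop_validation("PAR underivable for dataset(s): %s",
                      paste(metadata$dataset_id[derive & !ok], collapse = ", "))
    }
    pad[derive] <- par_at_depth(metadata$par_surface[derive],
                                metadata$attenuation_k[derive],
                                metadata$depth_m[derive])
  }
  if (any(is.na(metadata$par_surface))) {
    stop_validation("par_surface required for the photic rule")
  }
  metadata$zone_label <- ifelse(pad >= par_fraction * metadata$par_surface,
                                "photic", "aphotic")
  metadata
}

#' @rdname assign_zones
#' @param par_surface,par_at_depth Scalar PAR values.
#' @export
photic_label <- function(par_surface, par_at_depth, par_fraction = 0.01) {
  if (is.na(par_surface) || is.na(par_at_depth)) {
    stop_validation("PAR values required")
  }
  if (par_at_depth >= par_fraction * par_surface) "photic" else "aphotic"
}
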