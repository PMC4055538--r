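#' Depth-related candidates in the OMZ water column
#'
#' Applies the same per-column pairwise exact-test screen as
#' [column_depth_cogs()] to the oxygen-minimum-zone column (default
#' alpha 0.01).
#'
#' @inheritParams column_depth_cogs
#' @return A `depth_cog_set` for the OMZ column.
#' @export
omz_candidates <- function(counts, dataset_ids, alpha = 0.01,
                           test = c("fisher", "binomial"), site = NULL) {
  column_depth_cogs(counts, dataset_ids, alpha = alpha, test = test,
                    site = site)
}

#' Remove the photic/aphotic core from a candidate list
#'
#' Light-driven abundance changes are excluded before testing for oxygen
#' effects: the photic and aphotic core COGs are dropped from the
#' candidate list.
#'
#' @param candidates Character vector of COG ids, or a `depth_cog_set`.
#' @param core A `core_sets` object.
#' @return Sorted character vector of the remaining COG ids.
#' @export
exclude_core <- function(candidates, core) {
  ids <- if (inherits(candidates, "depth_cog_set")) candidates$cog_ids else candidates
  sort(setdiff(ids, c(core$photic_cogs, core$aphotic_cogs)))
}

#' Datasets below a dissolved-oxygen cutoff
#'
#' @param metadata Metadata tibble.
#' @param cutoff Dissolved oxygen cutoff in µmol/kg (default 20; datasets
#'   strictly below it form the low-oxygen group).
#' @return Character vector of dataset ids.
#' @export
low_o2_datasets <- function(metadata, cutoff = 20) {
  metadata$dataset_id[metadata$do_umol_kg < cutoff]
}

#' OMZ-associated COGs
#'
#' Each candidate COG's normalized abundances in the low-oxygen datasets
#' are compared with all remaining datasets by the exact Wilcoxon rank-sum
#' test; p-values are Benjamini-Hochberg adjusted across candidates and
#' COGs with adjusted p <= `alpha` (default 0.05) are retained. The
#' retained COGs are partitioned into two abundance-profile groups by
#' cutting their average-linkage tree (Euclidean distance on Z-scored
#' profiles) at k = 2; group I is the group with the higher mean abundance
#' in the low-oxygen datasets.
#'
#' @param norm Normalized abundance tibble.
#' @param candidates COG ids to test (already core-excluded), or a
#'   `depth_cog_set`.
#' @param low_o2_ids Dataset ids of the low-oxygen group (>= 1; at least
#'   one dataset must remain in the comparison group).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return An `omz_set`: test table (via [tidy()]), `cog_ids`, per-COG
#'   `group` (I/II) and the low-oxygen dataset ids.
#' @export
omz_cogs <- function(norm, candidates, low_o2_ids, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")
  ids <- if (inherits(candidates, "depth_cog_set")) candidates$cog_ids else candidates
  mat <- as_count_matrix(norm)
  ids <- intersect(ids, rownames(mat))
  if (!length(ids)) {
    return(structure(list(table = tibble(cog_id = character(),
                                         statistic = numeric(),
                                         p_value = numeric(),
                                         p_adj = numeric(),
                                         significant = logical(),
                                         group = character()),
                          cog_ids = character(),
                          low_o2_dataset_ids = low_o2_ids, alpha = alpha),
                     class = "omz_set"))
  }
  low_idx <- match(low_o2_ids, colnames(mat))
  if (anyNA(low_idx)) stop_validation("low-oxygen dataset absent from abundance table")
  if (!length(low_idx) || length(low_idx) == ncol(mat)) {
    stop_validation("both oxygen groups must be nonempty")
  }
  sub <- mat[ids, , drop = FALSE]
  p <- unname(ranksum_rows(sub, low_idx))
  tab <- tibble(cog_id = ids,
                statistic = unname(apply(sub, 1L,
                                         function(v) sum(rank(v)[low_idx]))),
                p_value = p,
                p_adj = bh_fdr(p)) |>
    mutate(significant = .data$p_adj <= alpha)
  sig <- tab$cog_id[tab$significant]
  tab$group <- NA_character_
  if (length(sig) >= 2L) {
    zsub <- as_count_matrix(zscore_rows(as_count_tbl(sub[sig, , drop = FALSE])))
    grp <- if (nrow(zsub) >= 2L) {
      cutree(hclust(dist(zsub), method = "average"), k = 2L)
    } else {
      setNames(rep(1L, length(sig)), sig)
    }
    low_mean <- vapply(split(names(grp), grp), function(g) {
      mean(sub[g, low_idx, drop = FALSE])
    }, numeric(1))
    roman <- if (length(low_mean) == 1L || low_mean[["1"]] >= low_mean[["2"]]) {
      c("1" = "I", "2" = "II")
    } else {
      c("1" = "II", "2" = "I")
    }
    tab$group[match(names(grp), tab$cog_id)] <- roman[as.character(grp)]
  } else if (length(sig) == 1L) {
    tab$group[tab$cog_id == sig] <- "I"
  }
  structure(list(table = arrange(tab, .data$cog_id), cog_ids = sort(sig),
                 low_o2_dataset_ids = low_o2_ids, alpha = alpha),
            class = "omz_set")
}

#' @export
print.omz_set <- function(x, ...) {
  cat("OMZ-associated COGs (exact rank-sum, BH-adjusted p <=", x$alpha, ")\n")
  cat("  ", length(x$cog_ids), "of", nrow(x$table), "candidates; groups:",
      paste(names(table(x$table$group)), table(x$table$group),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.omz_set <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.omz_set <- function(x, ...) {
  tibble(n_candidates = nrow(x$table), n_significant = length(x$cog_ids),
         n_group_I = sum(x$table$group == "I", na.rm = TRUE),
         n_group_II = sum(x$table$group == "II", na.rm = TRUE),
         alpha = x$alpha)
}

#' Per-dataset mean abundance of the group-I OMZ COGs
#'
#' The dose-response table behind the oxygen-threshold estimate: mean
#' normalized abundance of the group-I COGs in each dataset against that
#' dataset's dissolved oxygen.
#'
#' @param norm Normalized abundance tibble.
#' @param omz An `omz_set` with a nonempty group I.
#' @param metadata Metadata tibble (for `do_umol_kg`).
#' @return Tibble with `dataset_id`, `do_umol_kg`, `group_i_mean`.
#' @export
group_i_profile <- function(norm, omz, metadata) {
  gi <- omz$table$cog_id[!is.na(omz$table$group) & omz$table$group == "I"]
  if (!length(gi)) stop_validation("group I is empty")
  mat <- as_count_matrix(norm)
  tibble(dataset_id = colnames(mat),
         do_umol_kg = metadata$do_umol_kg[match(colnames(mat),
                                                metadata$dataset_id)],
         group_i_mean = colMeans(mat[gi, , drop = FALSE]))
}

#' Estimate the dissolved-oxygen threshold of the group-I response
#'
#' Orders datasets by dissolved oxygen and, over every split between
#' distinct oxygen values, computes the standardized mean difference
#' (pooled-SD units) of the group-I mean abundance between the low and
#' high side. The threshold estimate is the midpoint of the oxygen gap at
#' the best split; the separation statistic is reported, and flagged as
#' unconfident below `min_separation` (a gradual response without a step
#' produces a small statistic).
#'
#' @param profile Tibble from [group_i_profile()] (columns `do_umol_kg`,
#'   `group_i_mean`; >= 4 distinct oxygen values required).
#' @param min_separation Pooled-SD units below which the estimate is
#'   flagged unconfident (default 2).
#' @return A `threshold_estimate`: `threshold_o2`, `statistic`,
#'   `confident`, and the two oxygen values bracketing the split.
#' @export
oxygen_threshold <- function(profile, min_separation = 2) {
  o2 <- profile$do_umol_kg
  y <- profile$group_i_mean
  if (length(unique(o2)) < 4L) {
    stop_validation("need >= 4 distinct oxygen values")
  }
  if (sd(y) == 0) stop_degenerate("group-I mean abundance is constant; no threshold")
  ord <- order(o2)
  o2 <- o2[ord]; y <- y[ord]
  cuts <- unique(o2)
  cuts <- cuts[-length(cuts)]  # split after each distinct value but the last
  stat <- vapply(cuts, function(cc) {
    lo <- y[o2 <= cc]; hi <- y[o2 > cc]
    if (length(lo) < 1L || length(hi) < 1L) return(NA_real_)
    s2 <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
      (length(lo) + length(hi) - 2)
    d <- mean(lo) - mean(hi)
    if (s2 == 0) {
      if (d == 0) 0 else Inf * sign(d)
    } else {
      d / sqrt(s2)
    }
  }, numeric(1))
  best <- which.max(stat)
  gap_lo <- cuts[best]
  gap_hi <- min(o2[o2 > gap_lo])
  structure(list(threshold_o2 = (gap_lo + gap_hi) / 2,
                 statistic = stat[best],
                 confident = is.infinite(stat[best]) || stat[best] >= min_separation,
                 gap = c(gap_lo, gap_hi),
                 splits = tibble(cut_o2 = cuts, statistic = stat)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Oxygen threshold estimate: %.3g µmol/kg (gap %.3g-%.3g), separation %.2f%s\n",
              x$threshold_o2, x$gap[1], x$gap[2], x$statistic,
              if (x$confident) "" else " [low confidence]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_estimate <- function(x, ...) x$splits

#' @exportS3Method generics::glance
glance.threshold_estimate <- function(x, ...) {
  tibble(threshold_o2 = x$threshold_o2, statistic = x$statistic,
         confident = x$confident, gap_low = x$gap[1], gap_high = x$gap[2])
}
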