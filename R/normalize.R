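#' Rarefaction: subsample every dataset to a common read depth
#'
#' Draws `target` reads without replacement from each dataset's assigned
#' reads (a multivariate hypergeometric draw per column), so that all
#' column sums equal `target` and counts are directly comparable across
#' datasets. This equal-depth subsample is the "normalized abundance"
#' scale used by all downstream screens.
#'
#' @param counts A count tibble (`cog_id` + integer dataset columns).
#' @param target Common depth; `NULL` (default) uses the smallest library
#'   size. Must not exceed any library size.
#' @param seed Integer seed for reproducibility.
#' @return A count tibble with every column summing to `target`.
#' @export
subsample_counts <- function(counts, target = NULL, seed = 1) {
  validate_cog_counts(counts)
  mat <- as_count_matrix(counts)
  libs <- colSums(mat)
  target <- target %||% min(libs)
  if (target <= 0 || target != round(target)) {
    stop_validation("target must be a positive integer")
  }
  if (any(libs < target)) {
    stop_validation("target %d exceeds the library size of dataset %s",
                    target, names(libs)[which(libs < target)[1]])
  }
  withr::with_seed(seed, {
    out <- apply(mat, 2L, rarefy_column, target = target)
  })
  dimnames(out) <- dimnames(mat)
  as_count_tbl(out)
}

# Sequential conditional hypergeometric sampling: category i receives a
# Hypergeometric(x_i, remaining_total - x_i, remaining_draws) count.
rarefy_column <- function(x, target) {
  out <- integer(length(x))
  rem_total <- sum(x)
  rem_draw <- as.integer(target)
  for (i in seq_along(x)) {
    if (rem_draw == 0L) break
    if (rem_total == rem_draw) {  # must take everything left
      out[i:length(x)] <- x[i:length(x)]
      return(out)
    }
    k <- rhyper(1, x[i], rem_total - x[i], rem_draw)
    out[i] <- k
    rem_total <- rem_total - x[i]
    rem_draw <- rem_draw - k
  }
  out
}

#' Normalized abundances
#'
#' With `per_10k = FALSE` (the default) the values are the counts of the
#' already equal-depth matrix — rarefaction, not scaling, is the primary
#' normalization. With `per_10k = TRUE` each column is rescaled to sum to
#' 10^4, for inputs whose depths were not equalized.
#'
#' @param counts A count tibble.
#' @param per_10k Rescale columns to a common sum of 10^4?
#' @return A tibble of non-negative abundances (doubles).
#' @export
normalize_counts <- function(counts, per_10k = FALSE) {
  validate_cog_counts(counts)
  mat <- as_count_matrix(counts) * 1.0
  if (per_10k) {
    cs <- colSums(mat)
    if (any(cs == 0)) {
      stop_validation("cannot rescale a dataset with zero total count")
    }
    mat <- sweep(mat, 2L, cs / 1e4, "/")
  }
  as_count_tbl(mat)
}

#' Row-wise Z scores of a normalized abundance table
#'
#' Centres and scales each COG's abundance profile across datasets to mean
#' 0 and sample (n-1) standard deviation 1 — the scale used for heatmap
#' colouring and for clustering datasets.
#'
#' @param norm A normalized abundance tibble (`cog_id` + dataset columns).
#' @param drop_constant Drop COGs with zero variance (otherwise a constant
#'   row is a degenerate-input error).
#' @return A tibble of Z scores, possibly with fewer rows.
#' @export
zscore_rows <- function(norm, drop_constant = TRUE) {
  mat <- as_count_matrix(norm)
  if (ncol(mat) < 2L) stop_validation("Z scores need at least two datasets")
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  const <- s == 0
  if (any(const)) {
    if (!drop_constant) {
      stop_degenerate("constant row(s) have no Z score: %s",
                      paste(head(rownames(mat)[const], 3), collapse = ", "))
    }
    mat <- mat[!const, , drop = FALSE]
    mu <- mu[!const]; s <- s[!const]
  }
  as_count_tbl((mat - mu) / s)
}
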