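#' Remove constant feature columns
#'
#' Drops every feature column that takes a single value across all
#' peptides (such columns carry no information and break z-scoring).
#'
#' @param features A feature tibble (meta columns `id`, `family`,
#'   `is_target` are preserved).
#' @return The filtered tibble; attribute `removed` names the dropped
#'   feature columns, and the `descriptors` attribute (if present) is
#'   subset to match.
#' @export
filter_constant <- function(features) {
  fp <- feature_parts(features)
  if (nrow(fp$mat) < 2) abort("constant-feature filtering needs >= 2 rows")
  n_distinct <- apply(fp$mat, 2, function(x) length(unique(x)))
  keep <- n_distinct >= 2
  if (!any(keep)) abort("all feature columns are constant")
  out <- dplyr::bind_cols(fp$meta, as_tibble(fp$mat[, keep, drop = FALSE]))
  desc <- attr(features, "descriptors")
  if (!is.null(desc)) {
    attr(out, "descriptors") <- desc[desc$feature %in% fp$feat_cols[keep], ]
  }
  attr(out, "removed") <- fp$feat_cols[!keep]
  attr(out, "d_n") <- attr(features, "d_n", exact = TRUE)
  attr(out, "d_c") <- attr(features, "d_c", exact = TRUE)
  out
}

#' Z-score normalize feature columns
#'
#' Transforms each feature to `(x - mean) / sd`, with mean and standard
#' deviation computed across all peptides in the matrix (target and
#' non-target alike). The sample standard deviation (n - 1 denominator)
#' is used by default. Constant columns must be removed first (see
#' [filter_constant()]).
#'
#' @inheritParams filter_constant
#' @param ddof Denominator degrees-of-freedom correction: 1 (default,
#'   sample sd) or 0 (population sd).
#' @return The normalized tibble; attribute `norm_params` is a tibble of
#'   per-feature `mean` and `sd`, so held-out peptides can be projected
#'   with the same statistics.
#' @export
normalize_features <- function(features, ddof = 1) {
  fp <- feature_parts(features)
  mu <- colMeans(fp$mat)
  n <- nrow(fp$mat)
  ss <- colSums(sweep(fp$mat, 2, mu)^2)
  sigma <- sqrt(ss / (n - ddof))
  if (any(sigma == 0)) {
    abort(sprintf("zero-variance feature(s); run filter_constant() first: %s",
                  paste(fp$feat_cols[sigma == 0], collapse = ", ")))
  }
  mat <- sweep(sweep(fp$mat, 2, mu), 2, sigma, "/")
  out <- dplyr::bind_cols(fp$meta, as_tibble(mat))
  attr(out, "descriptors") <- attr(features, "descriptors")
  attr(out, "norm_params") <- tibble(feature = fp$feat_cols, mean = mu, sd = sigma)
  attr(out, "d_n") <- attr(features, "d_n", exact = TRUE)
  attr(out, "d_c") <- attr(features, "d_c", exact = TRUE)
  out
}
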