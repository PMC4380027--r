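#' Class-mean centroid initialization
#'
#' Initializes k-means centroids from the class structure instead of a
#' random draw: centroid 1 is the mean of the target rows; for `k = 2`
#' centroid 2 is the mean of the non-target rows; for `k > 2` the
#' non-target rows are pre-split by a seeded k-means++ draw of `k - 1`
#' centers among them and the resulting group means are used. This
#' removes the run-to-run variance of random centroid seeding while
#' staying reproducible by `seed`.
#'
#' @param features A labeled, normalized feature tibble (with
#'   `is_target`).
#' @param k Number of clusters (2 <= k <= number of rows).
#' @param seed Seed for the k-means++ pre-split (only used when k > 2).
#' @return A numeric matrix of `k` centroids (rows) in feature space.
#' @export
init_centroids <- function(features, k, seed = 1L) {
  fp <- feature_parts(features)
  if (!"is_target" %in% names(features)) abort("`features` must carry `is_target`")
  lab <- features$is_target
  if (k < 2 || k > nrow(fp$mat)) abort("k must be in [2, number of rows]")
  if (!any(lab) || all(lab)) abort("both target and non-target rows required")
  tgt_mean <- colMeans(fp$mat[lab, , drop = FALSE])
  neg <- fp$mat[!lab, , drop = FALSE]
  if (k == 2) {
    cents <- rbind(tgt_mean, colMeans(neg))
  } else {
    groups <- with_seed(seed, kmeanspp_assign(neg, k - 1L))
    means <- lapply(seq_len(k - 1L), function(g) {
      if (!any(groups == g)) return(NULL)
      colMeans(neg[groups == g, , drop = FALSE])
    })
    means <- means[!vapply(means, is.null, logical(1))]
    cents <- do.call(rbind, c(list(tgt_mean), means))
    ## if the pre-split left empty groups, pad with the farthest points
    while (nrow(cents) < k) {
      d <- rowSums((neg - matrix(cents[nearest_centroid(neg, cents), ],
                                 nrow = nrow(neg)))^2)
      cents <- rbind(cents, neg[which.max(d), ])
    }
  }
  dimnames(cents) <- NULL
  cents
}

## Seeded k-means++ style assignment of rows to m groups: draw m centers
## (first uniform, then proportional to squared distance to the nearest
## chosen center), assign each row to its nearest center.
kmeanspp_assign <- function(mat, m) {
  n <- nrow(mat)
  if (m >= n) return(seq_len(n))
  centers <- sample.int(n, 1)
  while (length(centers) < m) {
    d2 <- apply(mat, 1, function(x) {
      min(colSums((t(mat[centers, , drop = FALSE]) - x)^2))
    })
    if (sum(d2) == 0) {
      centers <- c(centers, sample(setdiff(seq_len(n), centers), 1))
    } else {
      centers <- c(centers, sample.int(n, 1, prob = d2))
    }
  }
  nearest_centroid(mat, mat[centers, , drop = FALSE])
}

## Index of nearest centroid per row (squared Euclidean, ties -> lowest).
nearest_centroid <- function(mat, centroids) {
  ## ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per row
  cross <- mat %*% t(centroids)
  c2 <- rowSums(centroids^2)
  scores <- sweep(-2 * cross, 2, c2, "+")
  max.col(-scores, ties.method = "first")
}

#' Lloyd k-means from given centroids
#'
#' Runs Lloyd iterations (squared-Euclidean assignment, mean update)
#' from a fixed set of starting centroids until the assignment stabilizes
#' or `max_iter` is reached. Assignment ties go to the lowest cluster
#' index; a cluster left empty is reseeded to the point farthest from its
#' current centroid. Fully deterministic given inputs.
#'
#' @param features A labeled feature tibble.
#' @param centroids Starting centroid matrix (e.g. from
#'   [init_centroids()]), one row per cluster.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @return An object of class `amp_clustering`: a list with `assignment`
#'   (tibble of `id`, `cluster`, and labels if present), `centroids`,
#'   `k`, `iterations`, `tot_withinss`, and `target_cluster` (when
#'   `is_target` is present; the cluster holding the most target rows,
#'   ties to the lowest index).
#' @export
cluster_kmeans <- function(features, centroids, max_iter = 300L) {
  fp <- feature_parts(features)
  mat <- fp$mat
  if (!all(is.finite(mat))) abort("feature matrix contains non-finite values")
  if (!all(is.finite(centroids))) abort("centroids must be finite")
  k <- nrow(centroids)
  assign_old <- rep(0L, nrow(mat))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    assign_new <- nearest_centroid(mat, centroids)
    ## reseed empty clusters to the globally farthest point
    empty <- setdiff(seq_len(k), unique(assign_new))
    for (e in empty) {
      d <- rowSums((mat - centroids[assign_new, , drop = FALSE])^2)
      far <- which.max(d)
      centroids[e, ] <- mat[far, ]
      assign_new <- nearest_centroid(mat, centroids)
    }
    if (identical(assign_new, assign_old) || iter >= max_iter) {
      assign_old <- assign_new
      break
    }
    assign_old <- assign_new
    for (j in seq_len(k)) {
      rows <- assign_new == j
      if (any(rows)) centroids[j, ] <- colMeans(mat[rows, , drop = FALSE])
    }
  }
  wss <- sum((mat - centroids[assign_old, , drop = FALSE])^2)
  assignment <- dplyr::bind_cols(
    as_tibble(fp$meta),
    tibble(cluster = assign_old)
  )
  target_cluster <- NA_integer_
  if ("is_target" %in% names(features)) {
    counts <- vapply(seq_len(k),
                     function(j) sum(features$is_target & assign_old == j),
                     numeric(1))
    target_cluster <- which.max(counts) # ties -> lowest index
  }
  structure(
    list(assignment = assignment, centroids = centroids, k = k,
         iterations = iter, tot_withinss = wss,
         target_cluster = target_cluster),
    class = "amp_clustering"
  )
}

#' @export
print.amp_clustering <- function(x, ...) {
  cat(sprintf("k-means clustering: k = %d, %d points, %d iteration(s)\n",
              x$k, nrow(x$assignment), x$iterations))
  cat(sprintf("total within-cluster SS: %.4f\n", x$tot_withinss))
  if (!is.na(x$target_cluster)) {
    cat(sprintf("target cluster: %d\n", x$target_cluster))
  }
  invisible(x)
}

#' Evaluate a clustering against binary family labels
#'
#' Applies the target-cluster rule (the cluster with the most
#' target-class points, ties to the lowest index) and derives the
#' confusion counts: TP = targets in the target cluster, FP = non-targets
#' there, FN = targets elsewhere, TN = the rest. Reports accuracy,
#' sensitivity, specificity, precision, F-measure
#' (2TP / (2TP + FN + FP)), Jaccard index (TP / (TP + FP + FN)), plus the
#' external criteria entropy (cluster-size-weighted class entropy, in
#' bits) and purity (fraction of points in their cluster's dominant
#' class).
#'
#' @param clustering An `amp_clustering` object whose assignment carries
#'   `is_target`, or any such object plus an explicit `labels` vector.
#' @param labels Optional logical vector of target labels, overriding the
#'   assignment's `is_target` column.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f_measure`, `jaccard`,
#'   `entropy`, `purity`.
#' @export
evaluate_clustering <- function(clustering, labels = NULL) {
  assign <- clustering$assignment$cluster
  if (is.null(labels)) {
    if (!"is_target" %in% names(clustering$assignment)) {
      abort("no `is_target` labels available")
    }
    labels <- clustering$assignment$is_target
  }
  if (!any(labels)) abort("no target-labeled rows")
  if (all(labels)) abort("no non-target rows")
  k <- clustering$k
  counts <- vapply(seq_len(k), function(j) sum(labels & assign == j), numeric(1))
  target_cluster <- which.max(counts)
  n <- length(labels)
  tp <- sum(labels & assign == target_cluster)
  fp <- sum(!labels & assign == target_cluster)
  fn <- sum(labels & assign != target_cluster)
  tn <- n - tp - fp - fn
  entropy <- 0
  purity_count <- 0L
  for (j in seq_len(k)) {
    in_j <- assign == j
    nj <- sum(in_j)
    if (nj == 0) next
    p <- c(sum(labels[in_j]), sum(!labels[in_j])) / nj
    p <- p[p > 0]
    entropy <- entropy + (nj / n) * sum(-p * log2(p))
    purity_count <- purity_count + max(sum(labels[in_j]), sum(!labels[in_j]))
  }
  purity <- purity_count / n
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    f_measure = 2 * tp / (2 * tp + fn + fp),
    jaccard = tp / (tp + fp + fn),
    entropy = entropy,
    purity = purity
  )
}
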