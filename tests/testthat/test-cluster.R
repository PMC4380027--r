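labeled_matrix <- function(points, is_target) {
  dplyr::bind_cols(
    tibble::tibble(id = sprintf("p%d", seq_len(nrow(points))),
                   is_target = is_target),
    tibble::as_tibble(as.data.frame(points))
  )
}

test_that("class-mean initialization reproduces the class means", {
  m <- labeled_matrix(rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2)),
                      c(TRUE, TRUE, FALSE, FALSE))
  cents <- init_centroids(m, 2)
  expect_equal(cents, rbind(c(0, 1), c(10, 1)))

  one_each <- labeled_matrix(rbind(c(1, 1), c(5, 5)), c(TRUE, FALSE))
  expect_equal(init_centroids(one_each, 2), rbind(c(1, 1), c(5, 5)))
})

test_that("k > 2 initialization keeps the target mean first and splits the rest", {
  withr::with_seed(2, {
    pts <- rbind(matrix(rnorm(10, 0), ncol = 2),
                 matrix(rnorm(10, 8), ncol = 2),
                 matrix(rnorm(10, -8), ncol = 2))
  })
  m <- labeled_matrix(pts, rep(c(TRUE, FALSE, FALSE), each = 5))
  cents <- init_centroids(m, 3, seed = 7)
  expect_equal(nrow(cents), 3)
  expect_equal(cents[1, ], colMeans(pts[1:5, ]))
  expect_equal(init_centroids(m, 3, seed = 7), cents) # seeded determinism
})

test_that("init_centroids validates k and class presence", {
  m <- labeled_matrix(rbind(c(0, 0), c(1, 1)), c(TRUE, FALSE))
  expect_error(init_centroids(m, 5), "k must be")
  bad <- labeled_matrix(rbind(c(0, 0), c(1, 1)), c(TRUE, TRUE))
  expect_error(init_centroids(bad, 2), "non-target")
})

test_that("well-separated clouds converge to the planted split in <= 2 iterations", {
  withr::with_seed(14, {
    pts <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
                 matrix(rnorm(20, 10, 0.1), ncol = 2))
  })
  m <- labeled_matrix(pts, rep(c(TRUE, FALSE), each = 10))
  cl <- cluster_kmeans(m, init_centroids(m, 2))
  expect_lte(cl$iterations, 2)
  expect_equal(cl$assignment$cluster, rep(c(1L, 2L), each = 10))
  expect_equal(cl$target_cluster, 1L)
})

test_that("k equal to the number of rows gives singleton clusters", {
  pts <- cbind(c(0, 3, 9, 27), 0)
  m <- labeled_matrix(pts, c(TRUE, FALSE, FALSE, FALSE))
  cl <- cluster_kmeans(m, pts)
  expect_equal(sort(cl$assignment$cluster), 1:4)
  expect_equal(cl$tot_withinss, 0)
})

test_that("final within-cluster SS matches exhaustive enumeration", {
  withr::with_seed(77, {
    for (rep in 1:4) {
      ## two separated groups so Lloyd from class means reaches the optimum
      n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
      pts <- rbind(matrix(rnorm(2 * n1, 0, 0.5), ncol = 2),
                   matrix(rnorm(2 * n2, 6, 0.5), ncol = 2))
      m <- labeled_matrix(pts, rep(c(TRUE, FALSE), c(n1, n2)))
      cl <- cluster_kmeans(m, init_centroids(m, 2))
      expect_equal(cl$tot_withinss, brute_force_wss(pts, 2), tolerance = 1e-9)
    }
  })
})

test_that("our Lloyd agrees with stats::kmeans from the same start", {
  withr::with_seed(99, {
    pts <- rbind(matrix(rnorm(30, 0), ncol = 3),
                 matrix(rnorm(30, 4), ncol = 3))
  })
  m <- labeled_matrix(pts, rep(c(TRUE, FALSE), each = 10))
  cents <- init_centroids(m, 2)
  ours <- cluster_kmeans(m, cents)
  ref <- stats::kmeans(pts, centers = cents, algorithm = "Lloyd", iter.max = 100)
  expect_equal(ours$tot_withinss, ref$tot.withinss, tolerance = 1e-9)
  expect_equal(ours$assignment$cluster, unname(ref$cluster))
})

test_that("empty clusters are reseeded rather than dropped", {
  pts <- cbind(c(0, 0.1, 0.2, 10), 0)
  m <- labeled_matrix(pts, c(TRUE, TRUE, TRUE, FALSE))
  ## third centroid far away from every point -> empty on first assignment
  cents <- rbind(c(0, 0), c(10, 0), c(500, 0))
  cl <- cluster_kmeans(m, cents)
  expect_equal(sort(unique(cl$assignment$cluster)), 1:3)
})

test_that("perfect clustering scores 1 on every metric, entropy 0", {
  m <- labeled_matrix(rbind(c(0, 0), c(0, 1), c(9, 0), c(9, 1)),
                      c(TRUE, TRUE, FALSE, FALSE))
  cl <- cluster_kmeans(m, init_centroids(m, 2))
  met <- evaluate_clustering(cl)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$specificity, 1)
  expect_equal(met$precision, 1)
  expect_equal(met$f_measure, 1)
  expect_equal(met$jaccard, 1)
  expect_equal(met$entropy, 0)
  expect_equal(met$purity, 1)
})

test_that("metrics match hand-computed confusion counts", {
  ## n = 10: TP = 3, FP = 1, FN = 1, TN = 5 via a fixed assignment
  asg <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  fake <- structure(list(assignment = tibble::tibble(
    id = sprintf("p%d", 1:10), is_target = labels, cluster = asg),
    k = 2L), class = "amp_clustering")
  met <- evaluate_clustering(fake)
  expect_equal(met$tp, 3); expect_equal(met$fp, 1)
  expect_equal(met$fn, 1); expect_equal(met$tn, 5)
  expect_equal(met$sensitivity, 0.75)
  expect_equal(met$specificity, 5 / 6)
  expect_equal(met$precision, 0.75)
  expect_equal(met$f_measure, 0.75)
  expect_equal(met$jaccard, 0.6)
  expect_equal(met$accuracy, 0.8)
})

test_that("evaluation is invariant to cluster index permutation", {
  labels <- rep(c(TRUE, FALSE), c(4, 8))
  asg <- c(2, 2, 2, 1, 1, 1, 1, 3, 3, 3, 1, 2)
  mk <- function(a) structure(list(assignment = tibble::tibble(
    id = sprintf("p%d", seq_along(a)), is_target = labels, cluster = a),
    k = 3L), class = "amp_clustering")
  perm <- c(3L, 1L, 2L)
  met1 <- evaluate_clustering(mk(asg))
  met2 <- evaluate_clustering(mk(perm[asg]))
  expect_equal(met1, met2)
})

test_that("tidiers summarize clusterings", {
  m <- labeled_matrix(rbind(c(0, 0), c(0, 1), c(9, 0), c(9, 1)),
                      c(TRUE, TRUE, FALSE, FALSE))
  cl <- cluster_kmeans(m, init_centroids(m, 2))
  td <- tidy(cl)
  expect_equal(nrow(td), 2)
  expect_equal(td$size, c(2L, 2L))
  expect_true(td$is_target_cluster[1])
  gl <- glance(cl)
  expect_equal(gl$f_measure, 1)
  expect_s3_class(autoplot(cl), "ggplot")
})
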