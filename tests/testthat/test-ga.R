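## small labeled matrix with `n_signal` perfectly separating columns and
## `n_noise` standard-normal noise columns
signal_matrix <- function(n_target = 6, n_background = 12,
                          n_signal = 3, n_noise = 7, seed = 1,
                          sep = 6) {
  withr::with_seed(seed, {
    n <- n_target + n_background
    lab <- rep(c(TRUE, FALSE), c(n_target, n_background))
    sig <- sapply(seq_len(n_signal), function(i) {
      ifelse(lab, sep, 0) + rnorm(n, sd = 0.3)
    })
    noise <- matrix(rnorm(n * n_noise), nrow = n)
    mat <- cbind(sig, noise)
    colnames(mat) <- sprintf("synthetic:FULL:f%02d", seq_len(ncol(mat)))
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("p%02d", seq_len(n)), is_target = lab),
      tibble::as_tibble(mat)
    )
  })
}

test_that("fitness is 1 - F + m/N with the documented conventions", {
  m <- normalize_features(signal_matrix(seed = 3))
  n_feat <- 10
  ## selecting only signal features separates perfectly: F = 1
  mask <- rep(FALSE, n_feat); mask[1:3] <- TRUE
  expect_equal(ga_fitness(mask, m, k = 2), 3 / 10, tolerance = 1e-12)
  ## all features selected, perfect separation -> fitness 1
  sep_all <- normalize_features(signal_matrix(seed = 3, n_noise = 0, n_signal = 4))
  expect_equal(ga_fitness(rep(TRUE, 4), sep_all, k = 2), 1)
  ## empty chromosome -> worst fitness by convention
  expect_equal(ga_fitness(rep(FALSE, n_feat), m, k = 2), 2)
})

test_that("fitness is weakly regularization-monotone for assignment-neutral drops", {
  m <- normalize_features(signal_matrix(seed = 4))
  full_sig <- c(rep(TRUE, 3), rep(FALSE, 7))
  two_sig <- c(TRUE, TRUE, FALSE, rep(FALSE, 7))
  expect_lte(ga_fitness(two_sig, m, k = 2), ga_fitness(full_sig, m, k = 2))
})

test_that("GA runs are reproducible and best-ever fitness never increases", {
  m <- normalize_features(signal_matrix(seed = 5))
  cfg <- ga_config(population_size = 20, generations = 15, seed = 42)
  a <- run_ga(m, k = 2, config = cfg)
  b <- run_ga(m, k = 2, config = cfg)
  expect_identical(a$chromosome, b$chromosome)
  expect_identical(a$fitness, b$fitness)
  expect_identical(a$trace, b$trace)
  expect_true(all(diff(a$trace$best_ever) <= 0))
})

test_that("GA recovers a planted separating subset", {
  m <- normalize_features(signal_matrix(n_signal = 3, n_noise = 17, seed = 6))
  res <- run_ga(m, k = 2, config = ga_config(population_size = 40,
                                             generations = 30, seed = 9))
  expect_lte(res$fitness, 0.5)
  expect_equal(res$metrics$f_measure, 1)
  sel <- tidy(res)
  expect_s3_class(sel, "tbl_df")
  expect_equal(sum(sel$selected), length(res$features))
})

test_that("single-feature candidate set returns that feature", {
  m <- normalize_features(signal_matrix(n_signal = 1, n_noise = 0, seed = 7))
  res <- run_ga(m, k = 2, config = ga_config(population_size = 6,
                                             generations = 3, seed = 1))
  expect_equal(length(res$features), 1)
  expect_equal(res$fitness, 1 - res$metrics$f_measure + 1)
})

test_that("GA attains the exhaustive-enumeration optimum on small candidate sets", {
  for (seed in c(11, 12)) {
    m <- normalize_features(signal_matrix(n_target = 5, n_background = 9,
                                          n_signal = 2, n_noise = 6,
                                          seed = seed, sep = 4))
    oracle <- brute_force_best_subset(m, k = 2, seed = 1)
    res <- run_ga(m, k = 2, config = ga_config(population_size = 60,
                                               generations = 40, seed = 1))
    expect_equal(res$fitness, oracle$fitness, tolerance = 1e-12)
  }
})

test_that("autoplot draws the fitness trace", {
  m <- normalize_features(signal_matrix(seed = 8))
  res <- run_ga(m, k = 2, config = ga_config(population_size = 10,
                                             generations = 5, seed = 2))
  expect_s3_class(autoplot(res), "ggplot")
  expect_equal(nrow(res$trace), 6)
})

test_that("grid selection finds the planted cell and reports the winner", {
  peps <- planted_dataset(n_target = 8, n_background = 16, seed = 13)
  props <- synth_property_fixture(4, 0, seed = 13)
  sel <- select_family_features(
    peps, "fam01", props,
    d_n_grid = 10, d_c_grid = 10, k_grid = 2,
    config = ga_config(population_size = 30, generations = 20, seed = 3),
    min_family_size = 3
  )
  expect_equal(sel$k, 2)
  expect_equal(sel$d_n, 10)
  expect_gte(sel$metrics$f_measure, 0.9)
  expect_equal(nrow(sel$grid), 1)
  gl <- glance(sel)
  expect_equal(gl$n_selected, length(sel$features))

  ## determinism of the full grid path
  sel2 <- select_family_features(
    peps, "fam01", props,
    d_n_grid = 10, d_c_grid = 10, k_grid = 2,
    config = ga_config(population_size = 30, generations = 20, seed = 3),
    min_family_size = 3
  )
  expect_identical(sel$chromosome, sel2$chromosome)
  expect_identical(glance(sel), glance(sel2))
})

test_that("grid selection enforces the minimum family size unless relaxed", {
  peps <- planted_dataset(n_target = 5, n_background = 10, seed = 14)
  props <- synth_property_fixture(3, 0, seed = 14)
  expect_error(
    select_family_features(peps, "fam01", props, d_n_grid = 10,
                           d_c_grid = 10, k_grid = 2),
    "minimum"
  )
  expect_error(
    select_family_features(peps, "fam01", props, d_n_grid = integer(0),
                           d_c_grid = 10, k_grid = 2, min_family_size = 3),
    "empty"
  )
})
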