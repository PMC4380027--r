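#' Genetic-algorithm configuration
#'
#' Bundles the GA hyperparameters. The defaults are the full-scale
#' settings (population 1000, 1000 generations, crossover rate 0.8,
#' per-bit mutation rate 0.01); examples, tests and the CLI's default
#' runs use openly scaled-down populations and generation counts.
#'
#' @param population_size Number of chromosomes per generation.
#' @param generations Number of generations.
#' @param crossover_rate Probability a mating pair undergoes uniform
#'   crossover (otherwise the parents are copied).
#' @param mutation_rate Per-bit flip probability.
#' @param elitism Number of best chromosomes copied unchanged into the
#'   next generation.
#' @param tournament_size Tournament size for parent selection.
#' @param seed RNG seed for the whole GA run.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 1000L, generations = 1000L,
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      elitism = 1L, tournament_size = 2L, seed = 1L) {
  stopifnot(population_size >= 1, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0, tournament_size >= 1)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         elitism = as.integer(elitism),
         tournament_size = as.integer(tournament_size),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Fitness of a feature subset
#'
#' Projects the labeled feature matrix onto the selected columns, runs
#' class-mean-initialized k-means, and returns
#' `1 - F-measure + m / N`, where `m` is the number of selected features
#' and `N` the number of candidates. Lower is better; a perfectly
#' separating subset of m features scores `m / N`. An empty chromosome
#' scores the worst possible value, 2.
#'
#' @param chromosome Logical (or 0/1) vector over candidate features.
#' @param features Labeled, normalized feature tibble.
#' @param k Number of clusters.
#' @param seed Seed forwarded to [init_centroids()] (used for k > 2).
#' @return The scalar fitness (to be minimized).
#' @export
ga_fitness <- function(chromosome, features, k = 2L, seed = 1L) {
  chromosome <- as.logical(chromosome)
  n_total <- length(chromosome)
  if (!any(chromosome)) return(2)
  fp <- feature_parts(features)
  if (n_total != length(fp$feat_cols)) {
    abort("chromosome length must equal the number of candidate features")
  }
  sub <- dplyr::bind_cols(fp$meta,
                          as_tibble(fp$mat[, chromosome, drop = FALSE]))
  cents <- init_centroids(sub, k, seed)
  cl <- cluster_kmeans(sub, cents)
  metrics <- evaluate_clustering(cl)
  1 - metrics$f_measure + sum(chromosome) / n_total
}

## Full evaluation of a chromosome: fitness + clustering metrics.
chromosome_metrics <- function(chromosome, features, k, seed) {
  fp <- feature_parts(features)
  sub <- dplyr::bind_cols(fp$meta,
                          as_tibble(fp$mat[, as.logical(chromosome), drop = FALSE]))
  cents <- init_centroids(sub, k, seed)
  cl <- cluster_kmeans(sub, cents)
  list(clustering = cl, metrics = evaluate_clustering(cl))
}

#' Genetic-algorithm feature-subset selection
#'
#' Generational GA over binary chromosomes (1 = feature selected)
#' minimizing the clustering fitness of [ga_fitness()]: seeded random
#' initial population (each bit set with probability 0.5), tournament
#' selection, uniform crossover, per-bit mutation, and elitism. The
#' best-ever chromosome is tracked across generations and returned with
#' its clustering metrics and the per-generation fitness trace.
#' Re-running with the same inputs and seed reproduces the result
#' exactly.
#'
#' @param features Labeled, normalized feature tibble (run
#'   [filter_constant()] and [normalize_features()] first).
#' @param k Number of clusters.
#' @param config A [ga_config()].
#' @return An object of class `amp_selection`: list with `chromosome`
#'   (logical vector named by feature), `features` (selected feature
#'   names), `fitness`, `k`, `metrics` (one-row tibble), `clustering`,
#'   `trace` (tibble of generation, best and mean population fitness,
#'   best-ever fitness), `n_candidates`, and `config`.
#' @export
run_ga <- function(features, k = 2L, config = ga_config()) {
  fp <- feature_parts(features)
  n_feat <- length(fp$feat_cols)
  if (n_feat == 0) abort("no candidate features")
  pop_size <- config$population_size
  cache <- new.env(parent = emptyenv())
  eval_fitness <- function(bits) {
    key <- paste(packBits(c(bits, rep(FALSE, (-length(bits)) %% 8)), "raw"),
                 collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- ga_fitness(bits, features, k, config$seed)
    cache[[key]] <- val
    val
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(pop_size), function(i) {
      bits <- runif(n_feat) < 0.5
      if (!any(bits)) bits[sample.int(n_feat, 1)] <- TRUE
      bits
    })
    fit <- vapply(pop, eval_fitness, numeric(1))
    best_bits <- pop[[which.min(fit)]]
    best_fit <- min(fit)
    trace <- vector("list", config$generations + 1L)
    trace[[1]] <- tibble(generation = 0L, best = min(fit), mean = mean(fit),
                         best_ever = best_fit)
    for (gen in seq_len(config$generations)) {
      elite_idx <- order(fit)[seq_len(min(config$elitism, pop_size))]
      new_pop <- pop[elite_idx]
      while (length(new_pop) < pop_size) {
        parents <- lapply(1:2, function(i) {
          cand <- sample.int(pop_size, config$tournament_size, replace = TRUE)
          pop[[cand[which.min(fit[cand])]]]
        })
        if (runif(1) < config$crossover_rate) {
          mask <- runif(n_feat) < 0.5
          c1 <- ifelse(mask, parents[[1]], parents[[2]])
          c2 <- ifelse(mask, parents[[2]], parents[[1]])
        } else {
          c1 <- parents[[1]]; c2 <- parents[[2]]
        }
        for (child in list(c1, c2)) {
          if (length(new_pop) >= pop_size) break
          flip <- runif(n_feat) < config$mutation_rate
          child <- xor(child, flip)
          new_pop[[length(new_pop) + 1L]] <- child
        }
      }
      pop <- new_pop
      fit <- vapply(pop, eval_fitness, numeric(1))
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_bits <- pop[[which.min(fit)]]
      }
      trace[[gen + 1L]] <- tibble(generation = gen, best = min(fit),
                                  mean = mean(fit), best_ever = best_fit)
    }
    final <- if (any(best_bits)) {
      chromosome_metrics(best_bits, features, k, config$seed)
    } else {
      list(clustering = NULL, metrics = tibble())
    }
    structure(
      list(
        chromosome = setNames(best_bits, fp$feat_cols),
        features = fp$feat_cols[best_bits],
        fitness = best_fit,
        k = k,
        metrics = final$metrics,
        clustering = final$clustering,
        trace = dplyr::bind_rows(trace),
        n_candidates = n_feat,
        config = config,
        d_n = attr(features, "d_n", exact = TRUE),
        d_c = attr(features, "d_c", exact = TRUE)
      ),
      class = "amp_selection"
    )
  })
}

#' @export
print.amp_selection <- function(x, ...) {
  cat(sprintf("GA feature selection: %d of %d features, k = %d\n",
              length(x$features), x$n_candidates, x$k))
  cat(sprintf("fitness = %.4f (1 - F + m/N); F-measure = %.4f\n",
              x$fitness, x$metrics$f_measure))
  invisible(x)
}

#' Grid search over region lengths and cluster counts for one family
#'
#' The full selection protocol for one target family: for every
#' `(d_n, d_c)` cell, encode all peptides in the family's feature space
#' (basic + mined restrictive features), filter constants, z-score, and
#' run the GA at every `k` in the grid; the winner is the run with the
#' highest clustering F-measure (ties broken by fewer selected features,
#' then smaller k, then smaller d_n, then smaller d_c).
#'
#' @param peptides Peptide tibble with `family` labels.
#' @param target_family Family to profile.
#' @param properties Property tibble (after pruning, typically).
#' @param d_n_grid,d_c_grid,k_grid Parameter grids. Defaults are the
#'   full study grids (`d_n` 10/12/14/16, `d_c` 8/10, `k` 2..15); pass
#'   single values for a quick run.
#' @param config A [ga_config()].
#' @param mode Feature-space mode passed to [build_family_features()].
#' @param coverage Restrictive-mining coverage threshold.
#' @param min_family_size Minimum target-family size (default 10,
#'   relaxable).
#' @return The winning `amp_selection`, with an extra `grid` element: a
#'   tibble of one row per (d_n, d_c, k) cell with its best fitness,
#'   F-measure and selected-feature count.
#' @export
select_family_features <- function(peptides, target_family, properties = NULL,
                                   d_n_grid = c(10, 12, 14, 16),
                                   d_c_grid = c(8, 10),
                                   k_grid = 2:15,
                                   config = ga_config(),
                                   mode = "mined", coverage = 0.9,
                                   min_family_size = 10L) {
  check_peptides(peptides, require_family = TRUE)
  fam_n <- sum(peptides$family == target_family)
  if (fam_n < min_family_size) {
    abort(sprintf("family %s has %d peptides; minimum is %d (set min_family_size to relax)",
                  target_family, fam_n, min_family_size))
  }
  if (length(d_n_grid) == 0 || length(d_c_grid) == 0 || length(k_grid) == 0) {
    abort("empty parameter grid")
  }
  grid_rows <- list()
  best <- NULL
  for (d_n in sort(d_n_grid)) {
    for (d_c in sort(d_c_grid)) {
      space <- build_family_features(peptides, target_family, properties,
                                     d_n = d_n, d_c = d_c, mode = mode,
                                     coverage = coverage)
      space <- normalize_features(filter_constant(space))
      for (k in sort(k_grid)) {
        res <- run_ga(space, k = k, config = config)
        grid_rows[[length(grid_rows) + 1L]] <- tibble(
          d_n = d_n, d_c = d_c, k = k,
          n_candidates = res$n_candidates,
          n_selected = length(res$features),
          fitness = res$fitness,
          f_measure = res$metrics$f_measure
        )
        better <- is.null(best) ||
          res$metrics$f_measure > best$metrics$f_measure ||
          (res$metrics$f_measure == best$metrics$f_measure &&
             (length(res$features) < length(best$features) ||
                (length(res$features) == length(best$features) &&
                   (k < best$k ||
                      (k == best$k && (d_n < best$d_n ||
                                         (d_n == best$d_n && d_c < best$d_c)))))))
        if (better) {
          res$d_n <- d_n
          res$d_c <- d_c
          best <- res
        }
      }
    }
  }
  best$grid <- dplyr::bind_rows(grid_rows)
  best$target_family <- target_family
  best
}
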