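## Shared fixtures and independent brute-force oracles.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## random canonical peptide tibble
random_peptides <- function(n, len_range = c(20, 60), seed = 1, prefix = "p") {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("%s%03d", prefix, seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(AAS, sample(len_range[1]:len_range[2], 1), replace = TRUE),
              collapse = "")
      }, character(1))
    )
  })
}

## small labeled dataset with a planted, perfectly separating signal:
## targets are arginine-rich in n1, background is uniform
planted_dataset <- function(n_target = 8, n_background = 16, seed = 1) {
  spec <- synth_spec(
    n_families = 1, peptides_per_family = n_target,
    n_background = n_background, length_range = c(40, 60),
    enrichments = tibble::tibble(family = 1L, region = "n1",
                                 residue = "R", weight = 50),
    seed = seed
  )
  generate_peptides(spec)
}

## brute-force minimum within-cluster SS over all assignments of n points
## into k non-empty clusters (centroid = cluster mean)
brute_force_wss <- function(mat, k) {
  n <- nrow(mat)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    if (length(unique(asg)) < k) next
    wss <- sum(vapply(seq_len(k), function(j) {
      pts <- mat[asg == j, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    best <- min(best, wss)
  }
  best
}

## brute-force leave-one-out restrictive-property evaluation; returns a
## data frame of (accession, region, coverage) for all pairs, computed
## independently of mine_restrictive()
brute_force_restrictive <- function(family_peptides, properties, d_n, d_c) {
  regions <- c("n1", "n2", "n3", "n4", "M", "C")
  pm <- as.matrix(properties[, AAS])
  rownames(pm) <- properties$accession
  res <- list()
  n <- nrow(family_peptides)
  for (a in properties$accession) {
    for (r in regions) {
      vals <- lapply(family_peptides$sequence, function(s) {
        part <- partition_regions(nchar(s), d_n, d_c)
        ch <- strsplit(region_residues(s, part, r), "")[[1]]
        unname(pm[a, ch])
      })
      if (all(lengths(vals) == 0)) next
      pass <- 0
      for (i in seq_len(n)) {
        others <- unlist(vals[-i])
        mine <- vals[[i]]
        ok <- if (length(mine) == 0) TRUE
        else if (length(others) == 0) FALSE
        else all(mine >= min(others) & mine <= max(others))
        pass <- pass + ok
      }
      res[[length(res) + 1]] <- data.frame(accession = a, region = r,
                                           coverage = pass / n)
    }
  }
  do.call(rbind, res)
}

## exhaustive best GA fitness over all non-empty feature subsets
brute_force_best_subset <- function(features, k = 2, seed = 1) {
  feat_cols <- setdiff(names(features), c("id", "family", "is_target"))
  n <- length(feat_cols)
  best <- Inf
  best_mask <- NULL
  for (code in 1:(2^n - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    f <- ga_fitness(mask, features, k, seed)
    if (f < best) {
      best <- f
      best_mask <- mask
    }
  }
  list(fitness = best, mask = best_mask)
}

## brute-force global alignment score by enumeration over all gapped
## alignments of two short sequences (affine gap scoring)
brute_force_align_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  score_alignment <- function(ga, gb) {
    s <- 0
    run_a <- 0; run_b <- 0
    for (k in seq_along(ga)) {
      if (ga[k] == "-") {
        run_a <- run_a + 1
        run_b <- 0
        s <- s + gap_extend + if (run_a == 1) gap_open else 0
      } else if (gb[k] == "-") {
        run_b <- run_b + 1
        run_a <- 0
        s <- s + gap_extend + if (run_b == 1) gap_open else 0
      } else {
        run_a <- 0; run_b <- 0
        s <- s + S[ga[k], gb[k]]
      }
    }
    s
  }
  ## enumerate monotone alignments recursively
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_alignment(ga, gb))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, c(ga, ca[i]), c(gb, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1, j, c(ga, ca[i]), c(gb, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(ga, "-"), c(gb, cb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}
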