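test_that("identical and linearly related scales collapse to one", {
  props <- synth_property_fixture(1, 0, seed = 4)
  dup <- props
  dup$accession <- "COPY0001"
  both <- dplyr::bind_rows(props, dup)
  pruned <- prune_correlated(both, seed = 1)
  expect_equal(nrow(pruned), 1)

  lin <- props
  lin$accession <- "LIN00001"
  lin[, AAS] <- 2 * props[, AAS] + 3
  pruned <- prune_correlated(dplyr::bind_rows(props, lin), seed = 1)
  expect_equal(nrow(pruned), 1)
})

test_that("pruning keeps one scale per correlation component", {
  ## 5 scales: {1,2,3} mutually |r| >= 0.9 via linear relations (3 is
  ## anticorrelated), {4,5} independent
  base <- synth_property_fixture(5, 0, seed = 8)
  base[2, AAS] <- base[1, AAS] * 1.5 + 0.2
  base[3, AAS] <- -2 * base[1, AAS]
  pruned <- prune_correlated(base, seed = 3)
  expect_equal(nrow(pruned), 3)
  expect_equal(sum(pruned$accession %in% base$accession[1:3]), 1)
  expect_true(all(base$accession[4:5] %in% pruned$accession))
  groups <- attr(pruned, "groups")
  expect_equal(length(groups), 1)
  expect_setequal(groups[[1]], base$accession[1:3])

  ## no retained pair correlates above threshold
  r <- abs(cor(t(as.matrix(pruned[, AAS]))))
  expect_true(all(r[upper.tri(r)] < 0.9))
})

test_that("threshold 1 with distinct scales is the identity", {
  props <- synth_property_fixture(6, 0, seed = 10)
  pruned <- prune_correlated(props, threshold = 1, seed = 1)
  expect_equal(pruned$accession, props$accession)
})

test_that("zero-variance scales are kept as singletons with a warning", {
  props <- synth_property_fixture(2, 0, seed = 12)
  props[2, AAS] <- 1
  expect_warning(pruned <- prune_correlated(props, seed = 1), "zero-variance")
  expect_equal(nrow(pruned), 2)
})

test_that("identical family sequences make every property restrictive", {
  fam <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = rep(strrep("ARNDKLYSTWG", 5), 3))
  props <- synth_property_fixture(4, 0, seed = 2)
  mr <- mine_restrictive(fam, props, d_n = 10, d_c = 10)
  expect_equal(nrow(mr), 4 * 6)
  expect_true(all(mr$coverage == 1))
  expect_true(all(mr$envelope_min <= mr$envelope_max))
})

test_that("out-of-envelope residues push coverage below threshold", {
  ## 10 peptides; 8 share an all-A n1, one starts with W and one with Y.
  ## The property is extreme (and opposite) on W and Y, so leaving out
  ## either of those two puts its n1 residue outside the others'
  ## envelope: exactly 2 fail -> coverage 0.8 < 0.9.
  seqs <- c(rep(paste0(strrep("A", 10), strrep("K", 30)), 8),
            paste0("W", strrep("A", 9), strrep("K", 30)),
            paste0("Y", strrep("A", 9), strrep("K", 30)))
  fam <- tibble::tibble(id = sprintf("p%02d", 1:10), sequence = seqs)
  props <- synth_property_fixture(1, 0, seed = 6)
  props[1, "W"] <- 99
  props[1, "Y"] <- -99
  mr <- mine_restrictive(fam, props, d_n = 2, d_c = 5, coverage = 0.9)
  expect_false(any(mr$region == "n1"))
  mr_loose <- mine_restrictive(fam, props, d_n = 2, d_c = 5, coverage = 0.8)
  expect_true(any(mr_loose$region == "n1"))
  expect_equal(mr_loose$coverage[mr_loose$region == "n1"], 0.8)
})

test_that("miner matches the brute-force leave-one-out oracle", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      fam <- random_peptides(sample(3:5, 1), len_range = c(12, 40),
                             seed = 100 + rep)
      props <- synth_property_fixture(sample(5:10, 1), 0, seed = 200 + rep)
      oracle <- brute_force_restrictive(fam, props, d_n = 3, d_c = 3)
      for (cov in c(0.9, 0.6, 1.0)) {
        mr <- mine_restrictive(fam, props, d_n = 3, d_c = 3, coverage = cov)
        expected <- oracle[oracle$coverage >= cov, ]
        got <- paste(mr$accession, mr$region)
        want <- paste(expected$accession, expected$region)
        expect_setequal(got, want)
      }
    }
  })
})

test_that("mining is invariant to peptide order and monotone in coverage", {
  fam <- random_peptides(6, len_range = c(20, 50), seed = 33)
  props <- synth_property_fixture(6, 0, seed = 34)
  a <- mine_restrictive(fam, props)
  b <- mine_restrictive(fam[6:1, ], props)
  expect_equal(a, b)
  strict <- mine_restrictive(fam, props, coverage = 1)
  loose <- mine_restrictive(fam, props, coverage = 0.5)
  expect_true(all(paste(strict$accession, strict$region) %in%
                    paste(loose$accession, loose$region)))
})

test_that("mining requires at least three peptides", {
  fam <- random_peptides(2, seed = 1)
  props <- synth_property_fixture(2, 0, seed = 1)
  expect_error(mine_restrictive(fam, props), "at least 3")
})

test_that("median features follow the even-count convention and empty-region zero", {
  props <- synth_property_fixture(1, 0, seed = 40)
  props[1, AAS] <- 0
  props[1, "A"] <- 1.8
  props[1, "R"] <- -4.5
  ## one peptide whose n1 = "AR" under d_n = 2
  pep <- tibble::tibble(id = "p1", sequence = paste0("AR", strrep("G", 20)))
  restrictive <- tibble::tibble(accession = "SYN0001", region = "n1")
  f <- physchem_features(pep, restrictive, props, d_n = 2, d_c = 5)
  expect_equal(unname(unlist(f[1, "physchem:n1:SYN0001"])), (1.8 - 4.5) / 2)

  ## empty M region -> 0 (L = 13 with d_n = 2, d_c = 5 fills N + C)
  pep2 <- tibble::tibble(id = "p2", sequence = strrep("A", 13))
  r2 <- tibble::tibble(accession = "SYN0001", region = "M")
  f2 <- physchem_features(pep2, r2, props, d_n = 2, d_c = 5)
  expect_equal(unname(unlist(f2[1, "physchem:M:SYN0001"])), 0)
})

test_that("family feature space has 184 + mined columns; 'all' mode is 184 + 6p", {
  peps <- planted_dataset(6, 10, seed = 3)
  props <- synth_property_fixture(5, 0, seed = 3)
  mined <- build_family_features(peps, "fam01", props)
  n_restr <- nrow(attr(mined, "restrictive"))
  expect_equal(nrow(attr(mined, "descriptors")), 184 + n_restr)
  expect_equal(ncol(mined), 3 + 184 + n_restr) # id, family, is_target

  basic <- build_family_features(peps, "fam01", mode = "basic")
  expect_equal(nrow(attr(basic, "descriptors")), 184)

  all_mode <- build_family_features(peps, "fam01", props, mode = "all")
  expect_equal(nrow(attr(all_mode, "descriptors")), 184 + 6 * 5)
  expect_equal(sum(all_mode$is_target), 6)
})
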