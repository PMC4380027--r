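#' Specification for a synthetic peptide benchmark
#'
#' Describes a dataset with planted family structure: each family draws
#' peptide lengths from a range, samples residues per region from a
#' background distribution reweighted by planted per-region residue
#' enrichments, and (optionally) restricts a region's residues to those
#' whose value under a planted property scale falls inside a planted
#' interval. A pool of unbiased background peptides is added. The planted
#' (region, residue) and (region, property) signals form the ground
#' truth against which recovery is measured.
#'
#' @param n_families Number of families.
#' @param peptides_per_family Peptides per family (families of 10-50 are
#'   typical of curated AMP collections).
#' @param n_background Unrelated background peptides.
#' @param length_range Min/max peptide length in residues.
#' @param d_n,d_c Region layout used when planting per-region signals.
#' @param background_freq Residue sampling distribution (default uniform
#'   over the 20 residues); named numeric vector, normalized internally.
#' @param enrichments Tibble of planted compositional biases: columns
#'   `family` (1-based index), `region`, `residue`, `weight` (> 0;
#'   multiplies the background probability of that residue in that
#'   region).
#' @param restrictions Tibble of planted property restrictions: columns
#'   `family`, `region`, `accession`, `min`, `max` (only residues whose
#'   value under that property scale lies in `[min, max]` may appear in
#'   that region).
#' @param properties Property tibble supplying the scales referenced by
#'   `restrictions`.
#' @param seed RNG seed; generation is fully reproducible.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_families = 3L, peptides_per_family = 20L,
                       n_background = 40L, length_range = c(30L, 90L),
                       d_n = 10L, d_c = 10L,
                       background_freq = NULL,
                       enrichments = NULL, restrictions = NULL,
                       properties = NULL, seed = 1L) {
  if (is.null(background_freq)) {
    background_freq <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  background_freq <- background_freq[AA_ALPHABET] / sum(background_freq[AA_ALPHABET])
  if (!is.null(enrichments) && any(enrichments$weight <= 0)) {
    abort("enrichment weights must be positive")
  }
  if (!is.null(restrictions) && is.null(properties)) {
    abort("`properties` required when restrictions are planted")
  }
  structure(
    list(n_families = n_families, peptides_per_family = peptides_per_family,
         n_background = n_background, length_range = length_range,
         d_n = d_n, d_c = d_c, background_freq = background_freq,
         enrichments = enrichments, restrictions = restrictions,
         properties = properties, seed = seed),
    class = "synth_spec"
  )
}

#' Generate a synthetic peptide dataset with planted family signals
#'
#' Samples the dataset described by a [synth_spec()]: per family,
#' peptide lengths are uniform over `length_range`, each sequence is
#' partitioned with the spec's `d_n`/`d_c`, and each region's residues
#' are drawn from the background distribution reweighted by that
#' family's planted enrichments and truncated to residues satisfying the
#' planted property restrictions. Background peptides are drawn without
#' any bias. Identical spec and seed give byte-identical output.
#'
#' @param spec A [synth_spec()].
#' @return A peptide tibble (`id`, `sequence`, `family`; background rows
#'   carry family `"background"`), with attribute `truth`: a tibble of
#'   every planted signal (`family` label, `region`, `type` =
#'   `"residue"` or `"property"`, `name`, and the planted
#'   weight/interval).
#' @export
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    rows <- list()
    truth <- list()
    pmat <- if (!is.null(spec$properties)) property_matrix(spec$properties) else NULL
    sample_region <- function(n, freq) {
      if (n == 0) return("")
      paste(sample(AA_ALPHABET, n, replace = TRUE, prob = freq), collapse = "")
    }
    for (f in seq_len(spec$n_families)) {
      fam_label <- sprintf("fam%02d", f)
      enr <- if (!is.null(spec$enrichments)) {
        spec$enrichments[spec$enrichments$family == f, , drop = FALSE]
      } else NULL
      res <- if (!is.null(spec$restrictions)) {
        spec$restrictions[spec$restrictions$family == f, , drop = FALSE]
      } else NULL
      ## per-region sampling distributions for this family
      region_freq <- lapply(setNames(REGION_NAMES, REGION_NAMES), function(r) {
        freq <- spec$background_freq
        if (!is.null(enr)) {
          here <- enr[enr$region == r, , drop = FALSE]
          for (k in seq_len(nrow(here))) {
            freq[here$residue[k]] <- freq[here$residue[k]] * here$weight[k]
          }
        }
        if (!is.null(res)) {
          here <- res[res$region == r, , drop = FALSE]
          for (k in seq_len(nrow(here))) {
            vals <- pmat[here$accession[k], ]
            ok <- vals >= here$min[k] & vals <= here$max[k]
            if (!any(ok)) {
              abort(sprintf("infeasible restriction: no residue of %s in [%g, %g]",
                            here$accession[k], here$min[k], here$max[k]))
            }
            freq[!ok] <- 0
          }
        }
        freq / sum(freq)
      })
      for (p in seq_len(spec$peptides_per_family)) {
        L <- sample(spec$length_range[1]:spec$length_range[2], 1)
        part <- partition_regions(L, spec$d_n, spec$d_c)
        seqs <- vapply(seq_len(nrow(part)), function(i) {
          sample_region(part$end[i] - part$start[i],
                        region_freq[[part$region[i]]])
        }, character(1))
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("%s_p%03d", fam_label, p),
          sequence = paste(seqs, collapse = ""),
          family = fam_label
        )
      }
      if (!is.null(enr)) {
        for (k in seq_len(nrow(enr))) {
          truth[[length(truth) + 1L]] <- tibble(
            family = fam_label, region = enr$region[k], type = "residue",
            name = enr$residue[k], weight = enr$weight[k],
            min = NA_real_, max = NA_real_
          )
        }
      }
      if (!is.null(res)) {
        for (k in seq_len(nrow(res))) {
          truth[[length(truth) + 1L]] <- tibble(
            family = fam_label, region = res$region[k], type = "property",
            name = res$accession[k], weight = NA_real_,
            min = res$min[k], max = res$max[k]
          )
        }
      }
    }
    for (p in seq_len(spec$n_background)) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1)
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("bg_p%03d", p),
        sequence = sample_region(L, spec$background_freq),
        family = "background"
      )
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- if (length(truth) > 0) {
      dplyr::bind_rows(truth)
    } else {
      tibble(family = character(), region = character(), type = character(),
             name = character(), weight = numeric(), min = numeric(),
             max = numeric())
    }
    out
  })
}

#' Synthetic amino-acid property fixture
#'
#' Builds a table of `n_properties` random property scales (standard
#' normal values per residue) in which `n_correlated_pairs` disjoint
#' pairs are constructed to be perfectly linearly related (so
#' `|r| >= 0.9` pruning must collapse each pair to one scale). Useful
#' for exercising [prune_correlated()] and, written out with
#' [write_aaindex()], the AAIndex1 parser.
#'
#' @param n_properties Total number of scales (>= 1).
#' @param n_correlated_pairs Number of planted correlated pairs
#'   (`2 * n_correlated_pairs <= n_properties`).
#' @param seed RNG seed.
#' @return A property tibble (accessions `SYN0001`, ...); attribute
#'   `planted_pairs` lists the accession pairs constructed as
#'   redundant.
#' @export
synth_property_fixture <- function(n_properties, n_correlated_pairs = 0L,
                                   seed = 1L) {
  stopifnot(n_properties >= 1, 2 * n_correlated_pairs <= n_properties)
  with_seed(seed, {
    vals <- matrix(round(rnorm(20 * n_properties), 3), nrow = n_properties)
    pairs <- list()
    for (k in seq_len(n_correlated_pairs)) {
      i <- 2 * k - 1; j <- 2 * k
      slope <- sample(c(-2, -1, 1, 2), 1)
      vals[j, ] <- slope * vals[i, ] + round(runif(1, -1, 1), 3)
      pairs[[k]] <- sprintf("SYN%04d", c(i, j))
    }
    out <- dplyr::bind_cols(
      tibble(accession = sprintf("SYN%04d", seq_len(n_properties)),
             description = sprintf("synthetic property scale %d",
                                   seq_len(n_properties))),
      as_tibble(setNames(as.data.frame(vals), AA_ALPHABET))
    )
    attr(out, "planted_pairs") <- pairs
    out
  })
}
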