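## Property tibble -> matrix (accession x 20 residues).
property_matrix <- function(properties) {
  mat <- as.matrix(properties[, AA_ALPHABET, drop = FALSE])
  rownames(mat) <- properties$accession
  storage.mode(mat) <- "double"
  mat
}

#' Collapse highly correlated amino-acid property scales
#'
#' Builds a graph over property scales with an edge wherever the absolute
#' Pearson correlation of the two scales' 20 residue values reaches
#' `threshold`, then keeps exactly one scale per connected component,
#' chosen uniformly at random under `seed`. Anticorrelated scales
#' (r <= -threshold) are treated as redundant too, since they carry the
#' same information up to sign. Zero-variance scales (correlation
#' undefined) are kept as singleton components with a warning.
#'
#' @param properties A property tibble from [parse_aaindex()] or
#'   [synth_property_fixture()].
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @param seed Seed for the random representative draw.
#' @return The pruned property tibble; attribute `groups` lists the
#'   accession sets of each multi-member component.
#' @export
prune_correlated <- function(properties, threshold = 0.9, seed = 1L) {
  n <- nrow(properties)
  if (n == 0) return(properties)
  mat <- property_matrix(properties)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("zero-variance property scale(s): %s",
                 paste(rownames(mat)[sds == 0], collapse = ", ")))
  }
  r <- matrix(0, n, n)
  ok <- sds > 0
  if (sum(ok) >= 2) {
    r[ok, ok] <- suppressWarnings(cor(t(mat[ok, , drop = FALSE])))
  }
  adj <- abs(r) >= threshold
  diag(adj) <- TRUE
  ## connected components by label propagation
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  keep <- with_seed(seed, {
    vapply(split(seq_len(n), comp), function(members) {
      if (length(members) == 1) members else members[sample.int(length(members), 1)]
    }, numeric(1))
  })
  keep <- sort(keep)
  groups <- Filter(function(g) length(g) > 1,
                   unname(split(properties$accession, comp)))
  out <- properties[keep, , drop = FALSE]
  attr(out, "groups") <- groups
  attr(out, "threshold") <- threshold
  out
}

#' Mine family-specific restrictive physicochemical properties
#'
#' For each (property scale, region) pair, runs a leave-one-out envelope
#' test over the peptides of one family: peptide i passes if every residue
#' of its region has a property value within the min/max envelope of the
#' values taken by that region's residues across the other family
#' members. Pairs whose pass fraction reaches `coverage` (default: at
#' least 90% of family peptides) are "restrictive" for the family; the
#' reported envelope is recomputed over the whole family.
#'
#' A peptide whose region is empty passes vacuously; if the region is
#' empty in every other peptide (no envelope) a non-empty excluded region
#' fails. Pairs whose region is empty in every family peptide are
#' skipped.
#'
#' @param family_peptides Peptide tibble of one family (>= 3 rows).
#' @param properties A property tibble (typically after
#'   [prune_correlated()]).
#' @param d_n,d_c Region-length parameters.
#' @param coverage Minimum pass fraction for retention (inclusive).
#' @param alignment Optional [progressive_align()] result; when supplied,
#'   region spans are taken on alignment columns and gaps are ignored
#'   inside regions (the alignment-based mining mode).
#' @return A tibble with columns `accession`, `region`, `coverage`,
#'   `envelope_min`, `envelope_max`, ordered by accession then region.
#' @export
mine_restrictive <- function(family_peptides, properties, d_n = 10, d_c = 10,
                             coverage = 0.9, alignment = NULL) {
  check_peptides(family_peptides)
  n_pep <- nrow(family_peptides)
  if (n_pep < 3) abort("restrictive mining needs at least 3 family peptides")
  seqs <- family_peptides$sequence
  if (!is.null(alignment)) {
    rows <- alignment$rows[family_peptides$id]
    if (anyNA(names(rows)) || any(!family_peptides$id %in% names(alignment$rows))) {
      abort("alignment does not cover all family peptides")
    }
    width <- nchar(rows[[1]])
    part <- partition_regions(width, d_n, d_c)
    region_res <- lapply(rows, function(g) {
      lapply(setNames(REGION_NAMES, REGION_NAMES), function(r) {
        gsub("-", "", region_residues(g, part, r), fixed = TRUE)
      })
    })
  } else {
    region_res <- lapply(seqs, function(s) {
      part <- partition_regions(nchar(s), d_n, d_c)
      lapply(setNames(REGION_NAMES, REGION_NAMES),
             function(r) region_residues(s, part, r))
    })
  }
  pmat <- property_matrix(properties)
  accs <- rownames(pmat)
  out <- list()
  for (r in REGION_NAMES) {
    ## residue index lists per peptide for this region
    idx <- lapply(region_res, function(rr) match(seq_chars(rr[[r]]), AA_ALPHABET))
    if (all(lengths(idx) == 0)) next
    for (a in accs) {
      vals <- lapply(idx, function(ii) pmat[a, ii])
      pass <- vapply(seq_len(n_pep), function(i) {
        others <- unlist(vals[-i])
        mine <- vals[[i]]
        if (length(mine) == 0) return(TRUE)
        if (length(others) == 0) return(FALSE)
        all(mine >= min(others) & mine <= max(others))
      }, logical(1))
      cov <- mean(pass)
      if (cov >= coverage) {
        fam_vals <- unlist(vals)
        out[[length(out) + 1L]] <- tibble(
          accession = a, region = r, coverage = cov,
          envelope_min = min(fam_vals), envelope_max = max(fam_vals)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(accession = character(), region = character(),
                  coverage = numeric(), envelope_min = numeric(),
                  envelope_max = numeric()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$accession, match(.data$region, REGION_NAMES))
}

#' Median-value physicochemical features
#'
#' One feature per restrictive (property, region) pair: the median of the
#' property's values over the peptide's residues in that region (an even
#' residue count takes the mean of the two central values). Empty regions
#' contribute 0. The same encoding is applied to family and non-family
#' peptides alike.
#'
#' @param peptides Peptide tibble.
#' @param restrictive Output of [mine_restrictive()], or any tibble with
#'   `accession` and `region` columns.
#' @param properties The property tibble supplying residue values.
#' @inheritParams encode_basic
#' @return A tibble of `id` (and `family` if present) plus one
#'   `physchem:<region>:<accession>` column per restrictive pair.
#' @export
physchem_features <- function(peptides, restrictive, properties,
                              d_n = 10, d_c = 10) {
  check_peptides(peptides)
  pmat <- property_matrix(properties)
  missing <- setdiff(restrictive$accession, rownames(pmat))
  if (length(missing) > 0) {
    abort(sprintf("restrictive accessions absent from property table: %s",
                  paste(unique(missing), collapse = ", ")))
  }
  feat_names <- paste("physchem", restrictive$region, restrictive$accession, sep = ":")
  rows <- lapply(peptides$sequence, function(s) {
    part <- partition_regions(nchar(s), d_n, d_c)
    res_by_region <- lapply(setNames(REGION_NAMES, REGION_NAMES),
                            function(r) match(seq_chars(region_residues(s, part, r)),
                                              AA_ALPHABET))
    vapply(seq_len(nrow(restrictive)), function(k) {
      ii <- res_by_region[[restrictive$region[k]]]
      if (length(ii) == 0) return(0)
      median(pmat[restrictive$accession[k], ii])
    }, numeric(1))
  })
  mat <- if (length(rows) == 0) {
    matrix(numeric(0), nrow = 0, ncol = nrow(restrictive))
  } else if (nrow(restrictive) == 0) {
    matrix(numeric(0), nrow = length(rows), ncol = 0)
  } else {
    do.call(rbind, rows)
  }
  colnames(mat) <- feat_names
  meta <- peptides[, intersect(c("id", "family"), names(peptides)), drop = FALSE]
  out <- dplyr::bind_cols(as_tibble(meta), as_tibble(mat))
  attr(out, "descriptors") <- tibble(
    feature = feat_names, category = "physchem",
    region = restrictive$region, name = restrictive$accession
  )
  out
}

#' Build the full feature space for one target family
#'
#' Encodes all peptides in the representation specific to one target
#' family: the 184 compositional features plus one median-value feature
#' per restrictive (property, region) pair mined from the target family.
#' Two baseline modes are available: `"basic"` (compositional features
#' only) and `"all"` (no mining --- every property in every region, i.e.
#' `184 + 6 * nrow(properties)` columns).
#'
#' @param peptides Peptide tibble with a `family` column, covering the
#'   target family and the background.
#' @param target_family Family label of the target class.
#' @param properties Property tibble (required unless `mode = "basic"`).
#' @inheritParams encode_basic
#' @param mode `"mined"` (default), `"basic"`, or `"all"`.
#' @param coverage Coverage threshold for [mine_restrictive()].
#' @param alignment Optional alignment forwarded to [mine_restrictive()].
#' @return A labeled feature tibble: `id`, `family`, logical `is_target`,
#'   then feature columns; attributes `descriptors` and (for mined mode)
#'   `restrictive`.
#' @export
build_family_features <- function(peptides, target_family, properties = NULL,
                                  d_n = 10, d_c = 10,
                                  mode = c("mined", "basic", "all"),
                                  coverage = 0.9, alignment = NULL) {
  mode <- match.arg(mode)
  check_peptides(peptides, require_family = TRUE)
  if (!target_family %in% peptides$family) {
    abort(sprintf("target family %s not present", target_family))
  }
  basic <- encode_basic(peptides, d_n, d_c)
  desc <- attr(basic, "descriptors")
  restrictive <- NULL
  if (mode == "basic") {
    out <- basic
  } else {
    if (is.null(properties)) abort("`properties` required unless mode = \"basic\"")
    restrictive <- if (mode == "all") {
      tidyr::expand_grid(accession = properties$accession, region = REGION_NAMES)
    } else {
      fam <- peptides[peptides$family == target_family, , drop = FALSE]
      mine_restrictive(fam, properties, d_n, d_c, coverage, alignment)
    }
    phys <- physchem_features(peptides, restrictive, properties, d_n, d_c)
    feat_only <- phys[, setdiff(names(phys), c("id", "family")), drop = FALSE]
    out <- dplyr::bind_cols(basic, feat_only)
    desc <- dplyr::bind_rows(desc, attr(phys, "descriptors"))
  }
  out <- dplyr::mutate(out, is_target = .data$family == target_family,
                       .after = "family")
  attr(out, "descriptors") <- desc
  attr(out, "restrictive") <- restrictive
  attr(out, "d_n") <- d_n
  attr(out, "d_c") <- d_c
  out
}
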