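#' Amino-acid composition of a residue string
#'
#' Fraction of each of the 20 canonical residues in the string. An empty
#' string yields all zeros (the convention for empty regions of short
#' peptides); a non-empty string's fractions sum to 1.
#'
#' @param residues A residue string (possibly empty).
#' @return A named numeric vector of length 20, alphabetical residue
#'   order.
#' @export
#' @examples
#' aa_composition("ARAR")[c("A", "R")]
aa_composition <- function(residues) {
  assert_canonical(residues)
  n <- nchar(residues)
  counts <- setNames(numeric(20), AA_ALPHABET)
  if (n == 0) return(counts)
  tab <- table(factor(seq_chars(residues), levels = AA_ALPHABET))
  counts[] <- as.numeric(tab) / n
  counts
}

#' Twin amino-acid composition
#'
#' For each residue X, the number of adjacent positions (i, i+1) where
#' both residues equal X, divided by `length - 1` (the number of adjacent
#' pairs). Runs count overlapping pairs, so `"AAA"` contributes 2 A-twins.
#' Strings of length <= 1 yield all zeros.
#'
#' @inheritParams aa_composition
#' @return A named numeric vector of length 20.
#' @export
#' @examples
#' twin_composition("AALLA") # A and L each 1/4
twin_composition <- function(residues) {
  assert_canonical(residues)
  n <- nchar(residues)
  out <- setNames(numeric(20), AA_ALPHABET)
  if (n <= 1) return(out)
  ch <- seq_chars(residues)
  twin <- ch[-n][ch[-n] == ch[-1]]
  tab <- table(factor(twin, levels = AA_ALPHABET))
  out[] <- as.numeric(tab) / (n - 1)
  out
}

#' Gaps between successive residues of a class
#'
#' Position differences between consecutive occurrences of residues in a
#' class (basic, hydrophobic, or other). Adjacent class members have gap
#' 1. Fewer than two occurrences give an empty vector.
#'
#' @inheritParams aa_composition
#' @param class One of `"basic"` (R, K, H), `"hydrophobic"`
#'   (I, V, L, F, M, A, G, W, P), or `"other"` (the remaining residues).
#' @return An integer vector of gaps, in sequence order.
#' @export
#' @examples
#' residue_class_gaps("ARMRAASKAALLMAHKNAK", "basic") # 2 4 7 1 3
residue_class_gaps <- function(residues, class = c("basic", "hydrophobic", "other")) {
  class <- match.arg(class)
  assert_canonical(residues)
  pos <- which(seq_chars(residues) %in% RESIDUE_CLASSES[[class]])
  if (length(pos) < 2) return(integer(0))
  diff(pos)
}

#' Distance frequencies of a residue class
#'
#' Histogram of the gaps between successive occurrences of a residue
#' class over six bins: H = 1, 1 < H <= 6, 6 < H <= 11, 11 < H <= 16,
#' 16 < H <= 21, H > 21. Counts are raw (not normalized).
#'
#' @inheritParams residue_class_gaps
#' @return A tibble with columns `bin` and `count` (six rows).
#' @export
#' @examples
#' distance_frequencies("ARMRAASKAALLMAHKNAK", "basic") # counts 1,3,1,0,0,0
distance_frequencies <- function(residues, class = c("basic", "hydrophobic", "other")) {
  gaps <- residue_class_gaps(residues, class)
  idx <- findInterval(gaps, DISTANCE_BIN_BREAKS + 1) + 1L # bin 1 iff H == 1
  counts <- tabulate(idx, nbins = 6L)
  tibble(bin = DISTANCE_BIN_LABELS, count = counts)
}

## Descriptor list of the 184-feature basic encoding, in canonical order.
basic_descriptors <- function() {
  comp <- tidyr::expand_grid(
    category = "composition",
    region = c(REGION_NAMES, "FULL"),
    name = AA_ALPHABET
  )
  twin <- tibble(category = "twin", region = "M", name = AA_ALPHABET)
  dist <- dplyr::bind_rows(
    tibble(category = "distance_basic", region = "N", name = DISTANCE_BIN_LABELS),
    tibble(category = "distance_basic", region = "M", name = DISTANCE_BIN_LABELS),
    tibble(category = "distance_hydrophobic", region = "M", name = DISTANCE_BIN_LABELS),
    tibble(category = "distance_other", region = "M", name = DISTANCE_BIN_LABELS)
  )
  out <- dplyr::bind_rows(comp, twin, dist)
  out$feature <- paste(out$category, out$region, out$name, sep = ":")
  out[, c("feature", "category", "region", "name")]
}

## 184-vector for one sequence given its partition.
encode_basic_one <- function(sequence, partition) {
  spans <- lapply(setNames(c(REGION_NAMES, "FULL"), c(REGION_NAMES, "FULL")),
                  function(r) region_residues(sequence, partition, r))
  comp <- unlist(lapply(spans, aa_composition), use.names = FALSE)
  twin <- unname(twin_composition(spans$M))
  nblock <- region_residues(sequence, partition, "N")
  dist <- c(
    distance_frequencies(nblock, "basic")$count,
    distance_frequencies(spans$M, "basic")$count,
    distance_frequencies(spans$M, "hydrophobic")$count,
    distance_frequencies(spans$M, "other")$count
  )
  c(comp, twin, dist)
}

#' Encode peptides with the 184-feature compositional representation
#'
#' Builds, for every peptide, the region-partitioned compositional feature
#' vector: amino-acid composition over n1, n2, n3, n4, M, C and the full
#' sequence (7 x 20 = 140), twin composition in M (20), and six-bin
#' distance frequencies of basic residues in the N block and in M, and of
#' hydrophobic and other residues in M (4 x 6 = 24) --- 184 features in a
#' fixed, documented order. Gaps for the N-block distance feature are
#' never computed across the N/M boundary.
#'
#' @param peptides A peptide tibble (columns `id`, `sequence`, optionally
#'   `family`).
#' @param d_n,d_c Region-length parameters passed to
#'   [partition_regions()].
#' @return A tibble with `id` (and `family` if present) followed by 184
#'   numeric feature columns named `category:region:name`; the descriptor
#'   table is attached as attribute `descriptors`.
#' @export
#' @examples
#' p <- tibble::tibble(id = "p1", sequence = strrep("ARMRAASKAA", 4))
#' dim(encode_basic(p))
encode_basic <- function(peptides, d_n = 10, d_c = 10) {
  check_peptides(peptides)
  desc <- basic_descriptors()
  rows <- lapply(peptides$sequence, function(s) {
    assert_canonical(s)
    part <- partition_regions(nchar(s), d_n, d_c)
    encode_basic_one(s, part)
  })
  mat <- if (length(rows) == 0) {
    matrix(numeric(0), nrow = 0, ncol = nrow(desc))
  } else {
    do.call(rbind, rows)
  }
  colnames(mat) <- desc$feature
  meta <- peptides[, intersect(c("id", "family"), names(peptides)), drop = FALSE]
  out <- dplyr::bind_cols(as_tibble(meta), as_tibble(mat))
  attr(out, "descriptors") <- desc
  attr(out, "d_n") <- d_n
  attr(out, "d_c") <- d_c
  out
}

## Helper: split a feature tibble into meta columns and numeric matrix.
feature_parts <- function(features) {
  meta_cols <- intersect(c("id", "family", "is_target"), names(features))
  feat_cols <- setdiff(names(features), meta_cols)
  list(
    meta = features[, meta_cols, drop = FALSE],
    mat = as.matrix(features[, feat_cols, drop = FALSE]),
    meta_cols = meta_cols,
    feat_cols = feat_cols
  )
}
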