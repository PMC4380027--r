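#' BLOSUM62 substitution matrix restricted to the canonical residues
#'
#' @return A 20 x 20 integer matrix in alphabetical residue order.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
}

## Affine-gap (Gotoh) global alignment over a precomputed column-score
## matrix `S` (nrow(a-columns) x ncol(b-columns)). A gap of length L costs
## gap_open + L * gap_extend (both negative). Traceback ties prefer
## diagonal, then up (gap in b), then left (gap in a). Returns the score
## and the path as a two-column matrix of (a-index, b-index) with 0 for a
## gap.
align_dp <- function(S, gap_open, gap_extend) {
  m <- nrow(S); n <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1) # gap in b (consumes a rows)
  Iy <- matrix(NEG, m + 1, n + 1) # gap in a (consumes b columns)
  ptrM <- matrix(0L, m + 1, n + 1) # predecessor state of a diagonal move
  ptrX <- matrix(0L, m + 1, n + 1) # 1 = opened from M, 2 = extended Ix
  ptrY <- matrix(0L, m + 1, n + 1) # 1 = opened from M, 3 = extended Iy
  M[1, 1] <- 0
  if (m > 0) {
    Ix[2:(m + 1), 1] <- gap_open + gap_extend * seq_len(m)
    ptrX[2:(m + 1), 1] <- c(1L, rep(2L, m - 1))
  }
  if (n > 0) {
    Iy[1, 2:(n + 1)] <- gap_open + gap_extend * seq_len(n)
    ptrY[1, 2:(n + 1)] <- c(1L, rep(3L, n - 1))
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      ptrM[i + 1, j + 1] <- which.max(prev) # tie: diagonal, then up, then left
      M[i + 1, j + 1] <- prev[ptrM[i + 1, j + 1]] + S[i, j]
      open_x <- M[i, j + 1] + gap_open + gap_extend
      ext_x <- Ix[i, j + 1] + gap_extend
      if (open_x >= ext_x) {
        Ix[i + 1, j + 1] <- open_x; ptrX[i + 1, j + 1] <- 1L
      } else {
        Ix[i + 1, j + 1] <- ext_x; ptrX[i + 1, j + 1] <- 2L
      }
      open_y <- M[i + 1, j] + gap_open + gap_extend
      ext_y <- Iy[i + 1, j] + gap_extend
      if (open_y >= ext_y) {
        Iy[i + 1, j + 1] <- open_y; ptrY[i + 1, j + 1] <- 1L
      } else {
        Iy[i + 1, j + 1] <- ext_y; ptrY[i + 1, j + 1] <- 3L
      }
    }
  }
  finals <- c(M[m + 1, n + 1], Ix[m + 1, n + 1], Iy[m + 1, n + 1])
  state <- which.max(finals) # 1 = M, 2 = Ix, 3 = Iy; tie prefers M then Ix
  score <- finals[state]
  path <- list()
  i <- m; j <- n
  while (i > 0 || j > 0) {
    if (state == 1L) {
      path[[length(path) + 1L]] <- c(i, j)
      state <- ptrM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      path[[length(path) + 1L]] <- c(i, 0L)
      state <- ptrX[i + 1, j + 1]
      i <- i - 1
    } else {
      path[[length(path) + 1L]] <- c(0L, j)
      state <- ptrY[i + 1, j + 1]
      j <- j - 1
    }
  }
  list(score = score, path = do.call(rbind, rev(path)))
}

## Residue-frequency profile (20 x width) of a set of gapped rows; gap
## characters carry zero weight.
profile_of <- function(rows) {
  width <- nchar(rows[[1]])
  P <- matrix(0, 20, width, dimnames = list(AA_ALPHABET, NULL))
  for (row in rows) {
    ch <- seq_chars(row)
    hit <- ch != "-"
    idx <- match(ch[hit], AA_ALPHABET)
    for (k in seq_along(idx)) {
      P[idx[k], which(hit)[k]] <- P[idx[k], which(hit)[k]] + 1
    }
  }
  P / length(rows)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman--Wunsch/Gotoh optimal global alignment. A gap of length L
#' scores `gap_open + L * gap_extend`. Traceback is deterministic:
#' on ties, diagonal is preferred, then a gap in `b`, then a gap in `a`.
#'
#' @param a,b Peptide sequence strings (non-empty, canonical).
#' @param substitution_matrix Scoring matrix over the 20 residues
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (negative; defaults -10/-1).
#' @return A list with `score` and `alignment` (character vector of the
#'   two gapped sequences).
#' @export
#' @examples
#' pairwise_global_align("ARMKA", "ARKA")$alignment
pairwise_global_align <- function(a, b, substitution_matrix = blosum62(),
                                  gap_open = -10, gap_extend = -1) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  assert_canonical(a); assert_canonical(b)
  ia <- match(seq_chars(a), AA_ALPHABET)
  ib <- match(seq_chars(b), AA_ALPHABET)
  S <- substitution_matrix[ia, ib, drop = FALSE]
  res <- align_dp(S, gap_open, gap_extend)
  ca <- seq_chars(a); cb <- seq_chars(b)
  ga <- ifelse(res$path[, 1] == 0, "-", ca[pmax(res$path[, 1], 1)])
  gb <- ifelse(res$path[, 2] == 0, "-", cb[pmax(res$path[, 2], 1)])
  list(score = res$score,
       alignment = c(paste(ga, collapse = ""), paste(gb, collapse = "")))
}

#' Average-linkage guide tree from pairwise alignment scores
#'
#' Computes all pairwise global alignment scores, converts them to
#' distances (`max score - score`), and clusters agglomeratively with
#' average linkage (UPGMA). Ties resolve by input id order, so the tree
#' is deterministic.
#'
#' @param peptides Peptide tibble (>= 2 rows).
#' @inheritParams pairwise_global_align
#' @return A list with `merge`/`height`/`order` (as [stats::hclust()]),
#'   `labels` (peptide ids), and `groupings`: one nested id grouping per
#'   merge step, closest pair first; the last element is the full nested
#'   grouping of all ids.
#' @export
build_guide_tree <- function(peptides, substitution_matrix = blosum62(),
                             gap_open = -10, gap_extend = -1) {
  check_peptides(peptides)
  n <- nrow(peptides)
  if (n < 2) abort("guide tree needs at least 2 peptides")
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pairwise_global_align(peptides$sequence[i], peptides$sequence[j],
                                 substitution_matrix, gap_open, gap_extend)$score
      score[i, j] <- s; score[j, i] <- s
    }
  }
  d <- max(score) - score
  diag(d) <- 0
  dimnames(d) <- list(peptides$id, peptides$id)
  hc <- hclust(as.dist(d), method = "average")
  nested <- vector("list", n - 1)
  leaf <- function(k) if (k < 0) peptides$id[-k] else nested[[k]]
  for (m in seq_len(n - 1)) {
    nested[[m]] <- list(leaf(hc$merge[m, 1]), leaf(hc$merge[m, 2]))
  }
  c(unclass(hc), list(groupings = nested))
}

#' Progressive multiple sequence alignment
#'
#' Aligns a family of peptides progressively: pairwise scores build an
#' average-linkage guide tree, then profiles are merged bottom-up along
#' the tree with sum-of-pairs column scores (gap characters weight
#' zero) under the same affine gap penalties. Every output row degaps
#' back to its input sequence exactly.
#'
#' @inheritParams build_guide_tree
#' @return An object of class `amp_alignment`: list with `rows` (named
#'   character vector of equal-length gapped sequences) and `guide_tree`.
#' @export
progressive_align <- function(peptides, substitution_matrix = blosum62(),
                              gap_open = -10, gap_extend = -1) {
  check_peptides(peptides)
  n <- nrow(peptides)
  if (n < 2) abort("progressive alignment needs at least 2 peptides")
  tree <- build_guide_tree(peptides, substitution_matrix, gap_open, gap_extend)
  seqs <- setNames(peptides$sequence, peptides$id)
  ## each node holds a named character vector of gapped rows
  node_rows <- vector("list", n - 1)
  get_rows <- function(k) {
    if (k < 0) setNames(seqs[-k], names(seqs)[-k]) else node_rows[[k]]
  }
  insert_gaps <- function(rows, path_col) {
    ## path_col: source column index per output column, 0 = new gap
    vapply(rows, function(r) {
      ch <- seq_chars(r)
      paste(ifelse(path_col == 0, "-", ch[pmax(path_col, 1)]), collapse = "")
    }, character(1))
  }
  for (m in seq_len(n - 1)) {
    A <- get_rows(tree$merge[m, 1])
    B <- get_rows(tree$merge[m, 2])
    PA <- profile_of(as.list(A)); PB <- profile_of(as.list(B))
    S <- t(PA) %*% substitution_matrix %*% PB
    res <- align_dp(S, gap_open, gap_extend)
    node_rows[[m]] <- c(insert_gaps(A, res$path[, 1]),
                        insert_gaps(B, res$path[, 2]))
  }
  structure(list(rows = node_rows[[n - 1]], guide_tree = tree),
            class = "amp_alignment")
}

#' @export
print.amp_alignment <- function(x, ...) {
  cat(sprintf("progressive alignment: %d sequences, %d columns\n",
              length(x$rows), nchar(x$rows[[1]])))
  invisible(x)
}

#' Read / write aligned FASTA
#'
#' Escape hatch for using an externally computed alignment (any published
#' aligner) in place of [progressive_align()].
#'
#' @param path Aligned FASTA path (gap character `-`).
#' @return For the reader, an `amp_alignment` (without a guide tree).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- setNames(toupper(as.character(set)),
                   vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L))
  if (length(unique(nchar(rows))) != 1) abort("alignment rows differ in length")
  structure(list(rows = rows, guide_tree = NULL), class = "amp_alignment")
}

#' @rdname read_alignment
#' @param alignment An `amp_alignment`.
#' @export
write_alignment <- function(alignment, path) {
  set <- Biostrings::BStringSet(alignment$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
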