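#' Partition a peptide sequence into the n1--n4, M, C regions
#'
#' Decomposes a sequence of length `L` into four N-terminal sub-regions
#' (`n1`..`n4`) of nominal length `d_n` each, a C-terminal region of
#' nominal length `d_c`, and the middle region `M` holding the remainder.
#' When the sequence is too short for the nominal layout
#' (`L < 4 d_n + d_c`), region sizes shrink proportionally: the N block
#' receives `floor(L * 4 d_n / (4 d_n + d_c + 1))` residues (split as
#' evenly as possible across `n1..n4`, earlier sub-regions taking the
#' remainder), the C-terminal `floor(L * d_c / (4 d_n + d_c + 1))`, and
#' `M` the rest; if flooring leaves any region empty, single residues are
#' reassigned from the largest region (deterministically) until all six
#' regions are non-empty. Spans are 0-based half-open intervals; they are
#' disjoint, ordered, and cover `[0, L)` exactly.
#'
#' @param sequence_length Sequence length in residues (>= 6).
#' @param d_n Nominal length of each N-terminal sub-region (>= 1).
#' @param d_c Nominal length of the C-terminal region (>= 1).
#' @return A tibble with columns `region`, `start`, `end` (half-open,
#'   0-based) and attributes `L`, `d_n`, `d_c`.
#' @export
#' @examples
#' partition_regions(60, d_n = 10, d_c = 10)
#' partition_regions(19, d_n = 10, d_c = 10) # proportional shrink
partition_regions <- function(sequence_length, d_n = 10, d_c = 10) {
  L <- as.integer(sequence_length)
  if (is.na(L) || L < 6) {
    abort("sequence_length must be >= 6 to form the six regions")
  }
  if (d_n < 1 || d_c < 1) abort("d_n and d_c must be >= 1")
  nominal <- 4L * d_n + d_c
  if (L >= nominal) {
    n_sub <- rep(d_n, 4)
    c_len <- d_c
    lens <- c(n_sub, L - 4L * d_n - d_c, c_len) # M may be empty here
  } else {
    n_block <- floor(L * 4 * d_n / (nominal + 1))
    c_len <- floor(L * d_c / (nominal + 1))
    base <- n_block %/% 4L
    extra <- n_block %% 4L
    n_sub <- base + as.integer(seq_len(4) <= extra)
    lens <- c(n_sub, L - sum(n_sub) - c_len, c_len)
    ## flooring can zero out a region at very small L; repair by moving
    ## one residue at a time from the largest region so all six shrunk
    ## regions stay non-empty
    while (any(lens == 0)) {
      donor <- which.max(lens)
      lens[which(lens == 0)[1]] <- 1L
      lens[donor] <- lens[donor] - 1L
    }
  }
  ends <- cumsum(lens)
  out <- tibble(
    region = REGION_NAMES,
    start = c(0, head(ends, -1)),
    end = ends
  )
  attr(out, "L") <- L
  attr(out, "d_n") <- d_n
  attr(out, "d_c") <- d_c
  out
}

#' Extract the residues of one region of a peptide
#'
#' @param sequence A peptide sequence string.
#' @param partition A region partition from [partition_regions()] matching
#'   the sequence length.
#' @param region One of `"n1"`, `"n2"`, `"n3"`, `"n4"`, `"M"`, `"C"`, or
#'   `"FULL"` for the entire sequence. The special name `"N"` returns the
#'   concatenated N block `n1..n4` (used by the N-region distance
#'   features).
#' @return The residue substring (possibly empty).
#' @export
region_residues <- function(sequence, partition, region) {
  L <- nchar(sequence)
  if (L != attr(partition, "L")) {
    abort(sprintf("partition is for length %d but sequence has length %d",
                  attr(partition, "L"), L))
  }
  if (region == "FULL") return(sequence)
  if (region == "N") {
    i <- match(c("n1", "n4"), partition$region)
    return(substr(sequence, partition$start[i[1]] + 1, partition$end[i[2]]))
  }
  i <- match(region, partition$region)
  if (is.na(i)) abort(sprintf("unknown region name: %s", region))
  substr(sequence, partition$start[i] + 1, partition$end[i])
}
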