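#' Read peptides from a FASTA file
#'
#' Reads a multi-record FASTA file of amino-acid sequences into a peptide
#' tibble. Sequences are uppercased; records containing residues outside
#' the 20 canonical one-letter codes (e.g. B, Z, J, X, U, O) are dropped
#' with a warning, since downstream region encoding requires fully
#' canonical sequences.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ARMRAASKAALLMAHKNAK", ">p2", "GGGG"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("no FASTA records in %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  ok <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs) &
    nchar(seqs) > 0
  if (any(!ok)) {
    warn(sprintf("skipped %d record(s) with non-canonical residues: %s",
                 sum(!ok), paste(ids[!ok], collapse = ", ")))
  }
  out <- tibble(id = ids[ok], sequence = unname(seqs[ok]))
  if (anyDuplicated(out$id)) abort("duplicate sequence ids in FASTA")
  out
}

#' Write peptides to a FASTA file
#'
#' @param peptides A peptide tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  check_peptides(peptides)
  set <- Biostrings::AAStringSet(setNames(peptides$sequence, peptides$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a peptide-to-family label table
#'
#' Reads a two-column tab-separated file (no header) mapping peptide id to
#' family label.
#'
#' @param path Path to a TSV file with columns id, family.
#' @return A tibble with columns `id` and `family`. An empty file yields a
#'   zero-row tibble.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) return(tibble(id = character(), family = character()))
  tab <- readr::read_tsv(path, col_names = c("id", "family"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tab <- dplyr::distinct(tab)
  if (anyDuplicated(tab$id)) {
    dup <- unique(tab$id[duplicated(tab$id)])
    abort(sprintf("conflicting family labels for id(s): %s",
                  paste(dup, collapse = ", ")))
  }
  tab
}

#' Write a peptide-to-family label table
#'
#' @param peptides A tibble with columns `id` and `family`.
#' @param path Output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_family_table <- function(peptides, path) {
  readr::write_tsv(peptides[, c("id", "family")], path, col_names = FALSE)
  invisible(path)
}

#' Parse an AAIndex1 flat file of amino-acid property scales
#'
#' Parses the AAIndex1 dialect: each record opens with an `H <accession>`
#' line, carries a `D` description, and an `I` header line followed by two
#' rows of ten numerical values (residue order
#' A/R/N/D/C/Q/E/G/H/I then L/K/M/F/P/S/T/W/Y/V), terminated by `//`.
#' Records with any `NA` value are excluded (the restrictive-envelope test
#' needs a value for every residue); the number excluded is recorded in the
#' `n_excluded` attribute.
#'
#' @param path Path to an AAIndex1 flat file.
#' @return A property tibble: columns `accession`, `description`, then one
#'   numeric column per canonical residue (alphabetical order). Attribute
#'   `n_excluded` counts records dropped for `NA` values.
#' @export
parse_aaindex <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ## residue order of the two AAIndex1 value rows
  row_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  recs <- list()
  n_excluded <- 0L
  i <- 1L
  acc <- NULL; descr <- ""
  while (i <= length(lines)) {
    line <- lines[i]
    tag <- substr(line, 1, 2)
    if (tag == "H ") {
      acc <- trimws(substring(line, 3))
      descr <- ""
    } else if (tag == "D ") {
      descr <- trimws(substring(line, 3))
    } else if (tag == "I ") {
      if (is.null(acc)) abort("AAIndex record has values before an H line")
      if (i + 2 > length(lines)) {
        abort(sprintf("truncated AAIndex record %s", acc))
      }
      vals <- unlist(strsplit(trimws(c(lines[i + 1], lines[i + 2])), "\\s+"))
      vals <- vals[nzchar(vals)]
      if (length(vals) != 20) {
        abort(sprintf("AAIndex record %s has %d values, expected 20",
                      acc, length(vals)))
      }
      if (any(vals %in% c("NA", "NA."))) {
        n_excluded <- n_excluded + 1L
      } else {
        num <- suppressWarnings(as.numeric(vals))
        if (anyNA(num)) {
          abort(sprintf("AAIndex record %s has non-numeric values", acc))
        }
        named <- setNames(num, row_order)[AA_ALPHABET]
        recs[[length(recs) + 1L]] <- c(list(accession = acc, description = descr),
                                       as.list(named))
      }
      i <- i + 2L
      acc <- NULL
    }
    i <- i + 1L
  }
  out <- if (length(recs) == 0) {
    empty <- c(list(accession = character(), description = character()),
               setNames(rep(list(numeric()), 20), AA_ALPHABET))
    as_tibble(empty)
  } else {
    dplyr::bind_rows(lapply(recs, as_tibble))
  }
  if (anyDuplicated(out$accession)) abort("duplicate AAIndex accessions")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a property table in AAIndex1 flat-file format
#'
#' Inverse of [parse_aaindex()] for the fields this package uses; lets the
#' synthetic property fixtures exercise the real parser.
#'
#' @param properties A property tibble as returned by [parse_aaindex()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(properties, path) {
  row_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(properties))) {
    vals <- as.numeric(properties[k, row_order])
    writeLines(c(
      paste0("H ", properties$accession[k]),
      paste0("D ", properties$description[k]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", paste(formatC(vals[1:10], format = "g", digits = 7), collapse = "  ")),
      paste0("    ", paste(formatC(vals[11:20], format = "g", digits = 7), collapse = "  ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Write / read a feature matrix as TSV
#'
#' The header encodes each feature descriptor as `category:region:name`;
#' `id` and (if present) `family` / `is_target` columns are preserved, so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param features A feature tibble as produced by [encode_basic()] or
#'   [build_family_features()].
#' @param path Output path.
#' @return `path` invisibly for the writer; the feature tibble (with its
#'   `descriptors` attribute rebuilt from the header) for the reader.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  meta_cols <- intersect(c("id", "family", "is_target"), header)
  types <- paste0(
    vapply(header, function(h) {
      if (h == "id" || h == "family") "c" else if (h == "is_target") "l" else "d"
    }, character(1)),
    collapse = ""
  )
  out <- suppressWarnings(readr::read_tsv(path, col_types = types,
                                          progress = FALSE))
  if (!identical(names(out), header)) abort("header/value column mismatch")
  if (nrow(readr::problems(out)) > 0) abort("header/value column mismatch")
  feat_cols <- setdiff(header, meta_cols)
  parts <- strsplit(feat_cols, ":", fixed = TRUE)
  if (length(feat_cols) > 0 && any(lengths(parts) != 3)) {
    abort("feature columns must be named category:region:name")
  }
  attr(out, "descriptors") <- tibble(
    feature = feat_cols,
    category = vapply(parts, `[`, character(1), 1),
    region = vapply(parts, `[`, character(1), 2),
    name = vapply(parts, `[`, character(1), 3)
  )
  out
}
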