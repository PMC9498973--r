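#' Sequence tables: the package's shared data model
#'
#' All user-facing functions in barcodekit exchange *sequence tables*: tibbles
#' with one row per sample and at least the columns `id` (unique sample
#' identifier) and `seq` (uppercase character string over the DNA alphabet
#' `A,C,G,T`, the IUPAC ambiguity codes, and `-` for an alignment gap).
#' Joining sample metadata ([join_metadata()]) adds `species`, `locality`,
#' `accession` and `is_outgroup` columns. A sequence table whose rows all have
#' equal length is treated as an alignment; column positions are always
#' reported 1-based on that alignment.
#'
#' @name seq_tbl
#' @keywords internal
NULL

# allowed residue alphabet: bases, IUPAC ambiguity, gap
IUPAC_CODES <- c("A", "C", "G", "T",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
SEQ_ALPHABET <- c(IUPAC_CODES, "-")

# base sets denoted by each IUPAC code (used by sites + likelihood modules)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

normalise_seq <- function(x) {
  x <- toupper(x)
  x <- gsub(".", "-", x, fixed = TRUE)
  gsub("U", "T", x, fixed = TRUE)
}

# validate one sequence string; `label` names the offending record in errors
check_alphabet <- function(seq, label) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% SEQ_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf(
      "Illegal character '%s' in sequence '%s' at position %d.",
      chars[bad[1]], label, bad[1]
    ))
  }
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file into a sequence
#' table. Sequences are uppercased, `U` is normalised to `T` and `.` to the
#' gap character `-`; any character outside the DNA + IUPAC + gap alphabet is
#' an error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "AC-T"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("FASTA file is empty: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalise_seq(as.character(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA id: '%s'.", ids[duplicated(ids)][1]))
  }
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) abort(sprintf("Empty sequence for record '%s'.", ids[i]))
    check_alphabet(seqs[i], ids[i])
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write a sequence table to FASTA
#'
#' Round-trips through [read_fasta()]: ids and sequences (including gap
#' characters) are preserved verbatim.
#'
#' @param seqs A sequence table (columns `id`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width; sequences are written unwrapped by default.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 20000L) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) == 0) abort("Cannot write an empty record list to FASTA.")
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Reads a TSV with the columns `sample_id`, `species`, `locality`,
#' `accession`, `is_outgroup`. Species strings are taken verbatim (exact-match
#' keys, no fuzzy normalisation); at most one species may be flagged as the
#' outgroup.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A tibble with the five metadata columns, `is_outgroup` logical.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("Metadata file not found: %s", path))
  meta <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      species = readr::col_character(),
      locality = readr::col_character(),
      accession = readr::col_character(),
      is_outgroup = readr::col_integer()
    )
  )
  required <- c("sample_id", "species", "locality", "accession", "is_outgroup")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("Metadata is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  meta <- dplyr::select(meta, dplyr::all_of(required))
  meta$locality[is.na(meta$locality)] <- ""
  meta$accession[is.na(meta$accession)] <- ""
  meta$is_outgroup <- as.logical(meta$is_outgroup)
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf(
      "Duplicate sample_id in metadata: '%s'.",
      meta$sample_id[duplicated(meta$sample_id)][1]
    ))
  }
  out_sp <- unique(meta$species[meta$is_outgroup])
  if (length(out_sp) > 1) {
    abort(sprintf(
      "At most one outgroup species is allowed; found: %s.",
      paste(out_sp, collapse = ", ")
    ))
  }
  meta
}

#' Join sequences to their sample metadata
#'
#' The join is total: every sequence must have exactly one metadata row, or
#' the join fails naming the orphaned ids.
#'
#' @param seqs A sequence table (columns `id`, `seq`).
#' @param meta A metadata table as returned by [read_metadata()].
#' @return The sequence table with `species`, `locality`, `accession` and
#'   `is_outgroup` columns appended.
#' @export
join_metadata <- function(seqs, meta) {
  seqs <- as_seq_tbl(seqs)
  # re-joining a table that already carries metadata replaces it
  seqs <- seqs[setdiff(names(seqs),
                       c("species", "locality", "accession", "is_outgroup"))]
  orphans <- setdiff(seqs$id, meta$sample_id)
  if (length(orphans) > 0) {
    abort(sprintf(
      "Sequence id(s) missing from metadata: %s.",
      paste(head(orphans, 5), collapse = ", ")
    ))
  }
  dplyr::inner_join(seqs, meta, by = c(id = "sample_id"))
}

#' Coerce and validate a sequence table
#'
#' @param x A data frame with columns `id` and `seq`.
#' @param aligned If `TRUE`, additionally require all rows to be equal length.
#' @return A validated tibble.
#' @export
as_seq_tbl <- function(x, aligned = FALSE) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("Expected a data frame with columns `id` and `seq`.")
  }
  x <- as_tibble(x)
  x$seq <- normalise_seq(x$seq)
  if (anyDuplicated(x$id)) {
    abort(sprintf("Duplicate sequence id: '%s'.", x$id[duplicated(x$id)][1]))
  }
  if (aligned && nrow(x) > 0 && length(unique(nchar(x$seq))) != 1) {
    abort("Rows are not aligned: sequence lengths differ.")
  }
  x
}

# sequence table (aligned) -> character matrix, rows named by id
aln_matrix <- function(seqs) {
  seqs <- as_seq_tbl(seqs, aligned = TRUE)
  if (nrow(seqs) == 0) abort("Alignment has no rows.")
  m <- do.call(rbind, strsplit(seqs$seq, "", fixed = TRUE))
  rownames(m) <- seqs$id
  m
}

# character matrix -> sequence table
matrix_to_seq_tbl <- function(m) {
  tibble(id = rownames(m), seq = apply(m, 1, paste0, collapse = ""))
}

# drop gap characters from sequence strings
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
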