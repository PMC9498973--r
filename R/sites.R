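#' Classify alignment columns
#'
#' Each column is classified as `invariant` (at most one distinct unambiguous
#' base among included rows), `variable` (at least two distinct bases, but not
#' parsimony-informative) or `parsimony_informative` (at least two bases each
#' carried by at least two rows). Gap characters and IUPAC ambiguity codes do
#' not count as states for classification but are flagged per column. The
#' logical `is_variable` column marks every column with >= 2 distinct bases
#' (i.e. `variable` plus `parsimony_informative`), which is the "variation
#' site" count reported for barcode datasets.
#'
#' @param aln An aligned sequence table.
#' @param include_outgroup Include rows flagged `is_outgroup`; default `FALSE`.
#' @return A tibble with one row per column: `position`, `n_A`, `n_C`, `n_G`,
#'   `n_T`, `n_gap`, `n_ambig`, `class`, `is_variable`, `gap_present`,
#'   `ambiguity_present`.
#' @export
classify_sites <- function(aln, include_outgroup = FALSE) {
  aln <- as_seq_tbl(aln, aligned = TRUE)
  if (!include_outgroup && "is_outgroup" %in% names(aln)) {
    aln <- aln[!aln$is_outgroup, , drop = FALSE]
  }
  m <- aln_matrix(aln)
  count_of <- function(ch) colSums(m == ch)
  nA <- count_of("A"); nC <- count_of("C"); nG <- count_of("G"); nT <- count_of("T")
  n_gap <- count_of("-")
  n_ambig <- nrow(m) - nA - nC - nG - nT - n_gap
  base_counts <- cbind(nA, nC, nG, nT)
  n_states <- rowSums(base_counts > 0)
  n_minor2 <- rowSums(base_counts >= 2)
  cls <- ifelse(n_states <= 1, "invariant",
                ifelse(n_minor2 >= 2, "parsimony_informative", "variable"))
  tibble(
    position = seq_len(ncol(m)),
    n_A = as.integer(nA), n_C = as.integer(nC),
    n_G = as.integer(nG), n_T = as.integer(nT),
    n_gap = as.integer(n_gap), n_ambig = as.integer(n_ambig),
    class = cls,
    is_variable = n_states >= 2,
    gap_present = n_gap > 0,
    ambiguity_present = n_ambig > 0
  )
}

#' Number of variable sites in an alignment
#'
#' @inheritParams classify_sites
#' @return Integer count of columns with at least two distinct bases.
#' @export
n_variable_sites <- function(aln, include_outgroup = FALSE) {
  sum(classify_sites(aln, include_outgroup)$is_variable)
}

#' Call species-diagnostic sites
#'
#' A `(position, state)` pair is diagnostic for species X iff every included
#' row of X carries exactly that state at the position and no row of any
#' other ingroup species does. Under the default policy the state must be an
#' unambiguous base: any gap or ambiguity code among X's rows disqualifies the
#' position for X; a gap in another species counts as a different state; an
#' ambiguity code in another species disqualifies the site whenever its base
#' set contains the candidate state (conservative, avoiding false
#' diagnostics). With `allow_indel_diagnostics = TRUE` a fixed gap can also be
#' diagnostic. The outgroup is excluded throughout.
#'
#' @param aln An aligned sequence table with `species` metadata.
#' @param allow_indel_diagnostics Permit `-` as a diagnostic state.
#' @param include_outgroup Include outgroup rows as a "species".
#' @return A `diagnostic_key`: a tibble (`species`, `position`, `state`) with
#'   attributes `species_no_sites` (ingroup species with no diagnostic site),
#'   `low_confidence` (species represented by a single row) and
#'   `alignment_length`.
#' @export
diagnostic_sites <- function(aln, allow_indel_diagnostics = FALSE,
                             include_outgroup = FALSE) {
  aln <- as_seq_tbl(aln, aligned = TRUE)
  if (!"species" %in% names(aln)) {
    abort("diagnostic_sites() needs a `species` column; join metadata first.")
  }
  if (!include_outgroup && "is_outgroup" %in% names(aln)) {
    aln <- aln[!aln$is_outgroup, , drop = FALSE]
  }
  species <- unique(aln$species)
  if (length(species) < 2) abort("Need at least two species to call diagnostics.")
  m <- aln_matrix(aln)
  L <- ncol(m)

  states <- c("A", "C", "G", "T", if (allow_indel_diagnostics) "-")
  # which IUPAC codes cover each base (for the conservative other-species rule)
  covers <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) b %in% s, logical(1))]
  })

  rows_of <- split(seq_len(nrow(m)), aln$species)
  key <- purrr::map_dfr(species, function(sp) {
    mine <- m[rows_of[[sp]], , drop = FALSE]
    others <- m[-rows_of[[sp]], , drop = FALSE]
    hits <- purrr::map_dfr(states, function(s) {
      fixed <- colSums(mine == s) == nrow(mine)
      if (s == "-") {
        absent <- colSums(others == s) == 0
      } else {
        clash <- others %in% covers[[s]]
        dim(clash) <- dim(others)
        absent <- colSums(clash) == 0
      }
      pos <- which(fixed & absent)
      tibble(position = pos, state = rep(s, length(pos)))
    })
    hits$species <- rep(sp, nrow(hits))
    hits
  })
  sp_levels <- species
  key <- dplyr::arrange(dplyr::select(key, "species", "position", "state"),
                        match(.data$species, !!sp_levels), .data$position)
  n_rows <- vapply(rows_of[species], length, integer(1))
  structure(
    key,
    species_no_sites = setdiff(species, unique(key$species)),
    low_confidence = species[n_rows == 1],
    alignment_length = L,
    class = c("diagnostic_key", class(key))
  )
}

#' @export
print.diagnostic_key <- function(x, ...) {
  cat(sprintf("<diagnostic_key> %d diagnostic sites across %d species\n",
              nrow(x), length(unique(x$species))))
  NextMethod()
  none <- attr(x, "species_no_sites")
  if (length(none) > 0) {
    cat("No diagnostic sites:", paste(none, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise a diagnostic key per species
#'
#' @param x A `diagnostic_key`.
#' @param ... Unused.
#' @return One row per species (including those with zero sites):
#'   `species`, `n_sites`, `low_confidence`.
#' @export
glance.diagnostic_key <- function(x, ...) {
  all_sp <- union(unique(x$species), attr(x, "species_no_sites"))
  counts <- table(factor(x$species, levels = all_sp))
  tibble(
    species = all_sp,
    n_sites = as.integer(counts),
    low_confidence = all_sp %in% attr(x, "low_confidence")
  )
}

#' Identify a sample from a diagnostic key
#'
#' Matches an aligned query row against every species' full diagnostic site
#' set (exact character equality, so an `N` never matches). Returns the single
#' matching species, `"ambiguous"` if several species' sets match, or
#' `"no-call"` if none does.
#'
#' @param query An aligned sequence string (same length as the key's master
#'   alignment).
#' @param key A [diagnostic_sites()] key.
#' @return A one-row tibble: `call`, `n_candidates`, `candidates` (list
#'   column of matching species).
#' @export
identify_sample <- function(query, key) {
  query <- normalise_seq(query)
  if (nchar(query) != attr(key, "alignment_length")) {
    abort(sprintf(
      "Query length (%d) does not match the key's alignment length (%d).",
      nchar(query), attr(key, "alignment_length")
    ))
  }
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  per_sp <- split(key, key$species)
  matches <- names(per_sp)[vapply(per_sp, function(k) {
    all(qv[k$position] == k$state)
  }, logical(1))]
  call <- if (length(matches) == 1) matches else if (length(matches) > 1) "ambiguous" else "no-call"
  tibble(call = call, n_candidates = length(matches), candidates = list(matches))
}
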