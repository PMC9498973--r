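# deterministic per-species haplotype prefixes: initials of the species name,
# uppercased, de-collided by appending a digit
species_prefix <- function(species) {
  words <- strsplit(species, "[ _.]+")
  pref <- vapply(words, function(w) {
    w <- w[nzchar(w)]
    toupper(paste0(substr(w, 1, 1), collapse = ""))
  }, character(1))
  dup <- duplicated(pref) | duplicated(pref, fromLast = TRUE)
  if (any(dup)) {
    for (p in unique(pref[dup])) {
      idx <- which(pref == p)
      pref[idx] <- paste0(p, seq_along(idx))
    }
  }
  setNames(pref, species)
}

# drop leading/trailing columns that are gaps in every row
trim_shared_gap_padding <- function(m) {
  allgap <- colSums(m != "-") == 0
  keep <- which(!allgap)
  if (length(keep) == 0) return(m[, 0, drop = FALSE])
  m[, min(keep):max(keep), drop = FALSE]
}

#' Collapse aligned sequences into haplotypes
#'
#' Two samples share a haplotype iff their aligned sequences are exactly equal
#' as strings — including gap characters (a 1-bp indel separates haplotypes)
#' and ambiguity codes, which are treated as distinct states rather than
#' expanded. Leading/trailing columns that are gaps in *all* rows are trimmed
#' before comparison. With `scope = "per_species"` (the default) collapsing is
#' done within species, so two species sharing a sequence still get distinct
#' haplotype ids; ids are assigned deterministically as a species-derived
#' prefix plus rank of first occurrence in the input.
#'
#' @param aln An aligned sequence table with `species` metadata (see
#'   [join_metadata()]).
#' @param scope `"per_species"` or `"global"`.
#' @param include_outgroup Include rows flagged `is_outgroup`; default `FALSE`,
#'   so sample and haplotype counts cover the ingroup only.
#' @return A `haplotype_table` object: a list with tibbles `haplotypes`
#'   (`hap_id`, `species`, `seq`, `n_samples`, `members`) and `membership`
#'   (`sample_id`, `species`, `hap_id`).
#' @export
collapse_haplotypes <- function(aln, scope = c("per_species", "global"),
                                include_outgroup = FALSE) {
  scope <- match.arg(scope)
  aln <- as_seq_tbl(aln, aligned = TRUE)
  if (!"species" %in% names(aln)) {
    abort("collapse_haplotypes() needs a `species` column; join metadata first.")
  }
  if (!include_outgroup && "is_outgroup" %in% names(aln)) {
    aln <- aln[!aln$is_outgroup, , drop = FALSE]
  }
  if (nrow(aln) == 0) abort("No rows left to collapse.")
  m <- trim_shared_gap_padding(aln_matrix(aln))
  seqs <- apply(m, 1, paste0, collapse = "")

  key <- if (scope == "per_species") paste(aln$species, seqs, sep = "\r") else seqs
  first <- !duplicated(key)
  hap_of <- match(key, key[first])

  if (scope == "per_species") {
    pref <- species_prefix(unique(aln$species))
    rank <- stats::ave(seq_along(key), aln$species, FUN = function(i) {
      match(hap_of[i], unique(hap_of[i]))
    })
    hap_id <- paste0(pref[aln$species], rank)
  } else {
    hap_id <- paste0("H", match(hap_of, unique(hap_of)))
  }

  membership <- tibble(
    sample_id = aln$id,
    species = aln$species,
    hap_id = hap_id
  )
  if ("locality" %in% names(aln)) membership$locality <- aln$locality

  haplotypes <- membership |>
    dplyr::mutate(seq = unname(seqs), .order = dplyr::row_number()) |>
    dplyr::group_by(.data$hap_id) |>
    dplyr::summarise(
      species = if (scope == "per_species") .data$species[1] else NA_character_,
      seq = .data$seq[1],
      n_samples = dplyr::n(),
      members = list(.data$sample_id),
      .order = min(.data$.order),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.order) |>
    dplyr::select(-".order")

  structure(
    list(haplotypes = haplotypes, membership = membership, scope = scope),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf(
    "<haplotype_table> %d haplotypes in %d samples (scope: %s)\n",
    nrow(x$haplotypes), nrow(x$membership), x$scope
  ))
  print(x$haplotypes, ...)
  invisible(x)
}

#' @describeIn collapse_haplotypes One row per haplotype.
#' @param x A `haplotype_table`.
#' @param ... Unused.
#' @export
tidy.haplotype_table <- function(x, ...) x$haplotypes

#' @describeIn collapse_haplotypes One-row summary (haplotype and sample counts).
#' @export
glance.haplotype_table <- function(x, ...) {
  tibble(
    n_haplotypes = nrow(x$haplotypes),
    n_samples = nrow(x$membership),
    n_species = length(unique(x$membership$species)),
    scope = x$scope
  )
}

#' Haplotype richness and frequencies by group
#'
#' Per-group (species or locality) haplotype richness with a Table-1-style
#' frequency breakdown such as `"MH1(4),MH2(1)"`.
#'
#' @param x A `haplotype_table` from [collapse_haplotypes()].
#' @param group `"species"` or `"locality"`.
#' @return A tibble with the group key, `n_samples`, `n_haplotypes`, and a
#'   formatted `haplotypes` breakdown.
#' @export
counts_by_group <- function(x, group = c("species", "locality")) {
  group <- match.arg(group)
  if (!group %in% names(x$membership)) {
    abort(sprintf("Grouping key '%s' is not present in the membership table.", group))
  }
  x$membership |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_haplotypes = length(unique(.data$hap_id)),
      haplotypes = {
        tab <- table(factor(.data$hap_id, levels = unique(.data$hap_id)))
        paste0(names(tab), "(", as.integer(tab), ")", collapse = ",")
      },
      .groups = "drop"
    )
}

#' Expand a haplotype table back to one row per sample
#'
#' Inverse of collapsing: useful for frequency-weighted analyses and for
#' checking idempotence.
#'
#' @param x A `haplotype_table`.
#' @return An aligned sequence table with one row per sample.
#' @export
expand_haplotypes <- function(x) {
  rep_seq <- setNames(x$haplotypes$seq, x$haplotypes$hap_id)
  tibble(
    id = x$membership$sample_id,
    seq = unname(rep_seq[x$membership$hap_id]),
    species = x$membership$species
  )
}
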