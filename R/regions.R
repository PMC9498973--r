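#' Region boundaries for the ITS1-5.8S-ITS2 partition
#'
#' @param its1,r58s,its2 Length-2 integer vectors `c(start, end)` of 1-based
#'   inclusive alignment columns. A span with `start > end` is empty.
#' @return A `region_boundaries` tibble with columns `region`, `start`, `end`.
#' @export
region_boundaries <- function(its1, r58s, its2) {
  b <- tibble(
    region = c("ITS1", "5.8S", "ITS2"),
    start = as.integer(c(its1[1], r58s[1], its2[1])),
    end = as.integer(c(its1[2], r58s[2], its2[2]))
  )
  nonempty <- b[b$start <= b$end, ]
  if (nrow(nonempty) > 1) {
    ord <- order(nonempty$start)
    if (any(diff(nonempty$end[ord]) <= 0) ||
        any(nonempty$start[ord][-1] <= nonempty$end[ord][-nrow(nonempty)])) {
      abort("Region spans must be ordered and non-overlapping.")
    }
  }
  structure(b, class = c("region_boundaries", class(b)))
}

#' Locate the conserved 5.8S window in an alignment
#'
#' The 5.8S gene is far more conserved than the flanking spacers, so its
#' placement can be inferred without an rDNA model: among all runs of
#' `window_len` consecutive gap-free columns, the window minimising total
#' column diversity (the summed count of rows carrying a non-modal state) is
#' taken as 5.8S; ties go to the leftmost window. Everything left of the
#' window is ITS1 and everything right is ITS2.
#'
#' @param aln An aligned sequence table.
#' @param window_len Window width in columns (default 164, the typical plant
#'   5.8S length).
#' @param include_outgroup Include outgroup rows (if flagged) in the diversity
#'   score; default `FALSE`.
#' @return A [region_boundaries()] tibble.
#' @export
infer_58s_window <- function(aln, window_len = 164L, include_outgroup = FALSE) {
  m <- aln_matrix(aln)
  if (!include_outgroup && "is_outgroup" %in% names(aln) && any(!aln$is_outgroup)) {
    m <- m[!aln$is_outgroup, , drop = FALSE]
  }
  L <- ncol(m)
  if (L <= window_len) abort("Alignment is not longer than the 5.8S window.")
  gap_free <- colSums(m == "-") == 0
  diversity <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0) return(0L)
    as.integer(length(col) - max(table(col)))
  }, integer(1))

  starts <- seq_len(L - window_len + 1L)
  ok <- vapply(starts, function(s) all(gap_free[s:(s + window_len - 1L)]), logical(1))
  if (!any(ok)) {
    abort(paste0(
      "No gap-free window of ", window_len, " columns; ",
      "supply region boundaries manually via region_boundaries()."
    ))
  }
  div_cum <- c(0, cumsum(diversity))
  scores <- div_cum[starts + window_len] - div_cum[starts]
  scores[!ok] <- Inf
  s <- starts[which.min(scores)]   # which.min is leftmost on ties
  e <- s + window_len - 1L
  region_boundaries(
    its1 = c(1L, s - 1L),
    r58s = c(s, e),
    its2 = c(e + 1L, L)
  )
}

# GC% of a character vector: gaps and ambiguity codes excluded from both
# numerator and denominator; NA when no unambiguous base remains
gc_percent <- function(chars) {
  bases <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(bases) == 0) return(NA_real_)
  100 * sum(bases %in% c("G", "C")) / length(bases)
}

#' Per-record region lengths and GC content
#'
#' For each record and each region span, reports the ungapped length (non-gap
#' characters only) and GC percentage (`100 * (G+C) / (A+C+G+T)`, ignoring
#' gaps and ambiguity codes), plus whole-sequence totals. Lengths are reported
#' per record, never asserted equal across records: individual haplotypes may
#' deviate from the canonical region length. GC is rounded to 2 decimals
#' (half away from zero) for reporting.
#'
#' @param aln An aligned sequence table.
#' @param boundaries A [region_boundaries()] tibble (or from
#'   [infer_58s_window()]).
#' @return A tibble with one row per record: `id` (plus `species` if
#'   present), `its1_len`, `its1_gc`, `r58s_len`, `r58s_gc`, `its2_len`,
#'   `its2_gc`, `total_len`, `total_gc`.
#' @export
region_stats <- function(aln, boundaries) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  if (any(boundaries$end > L) || any(boundaries$start < 1 & boundaries$start <= boundaries$end)) {
    abort("Region span lies outside the alignment.")
  }
  span_cols <- function(region) {
    row <- boundaries[boundaries$region == region, ]
    if (nrow(row) == 0 || row$start > row$end) return(integer(0))
    seq.int(row$start, row$end)
  }
  one <- function(chars) {
    c(len = sum(chars != "-"), gc = gc_percent(chars))
  }
  stats <- lapply(c("ITS1", "5.8S", "ITS2"), function(rg) {
    cols <- span_cols(rg)
    t(apply(m[, cols, drop = FALSE], 1, one))
  })
  total <- t(apply(m, 1, one))
  out <- tibble(
    id = rownames(m),
    its1_len = as.integer(stats[[1]][, "len"]),
    its1_gc = round_half_up(unname(stats[[1]][, "gc"])),
    r58s_len = as.integer(stats[[2]][, "len"]),
    r58s_gc = round_half_up(unname(stats[[2]][, "gc"])),
    its2_len = as.integer(stats[[3]][, "len"]),
    its2_gc = round_half_up(unname(stats[[3]][, "gc"])),
    total_len = as.integer(total[, "len"]),
    total_gc = round_half_up(unname(total[, "gc"]))
  )
  if ("species" %in% names(aln)) {
    out <- dplyr::left_join(out, dplyr::select(aln, "id", "species"), by = "id")
    out <- dplyr::relocate(out, "species", .after = "id")
  }
  out
}

# parse "its1:1-246,58s:247-410,its2:411-633" (CLI convenience)
parse_boundaries <- function(spec) {
  parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], "[:-]")
  key <- vapply(parts, `[`, character(1), 1)
  lo <- as.integer(vapply(parts, `[`, character(1), 2))
  hi <- as.integer(vapply(parts, `[`, character(1), 3))
  names(lo) <- names(hi) <- tolower(key)
  region_boundaries(
    its1 = c(lo[["its1"]], hi[["its1"]]),
    r58s = c(lo[["58s"]], hi[["58s"]]),
    its2 = c(lo[["its2"]], hi[["its2"]])
  )
}
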