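#' Kimura 2-parameter distance between two aligned rows
#'
#' Columns where either row carries a gap or an IUPAC ambiguity code are
#' removed pairwise; over the remaining `L_valid` columns, `P` is the
#' proportion of transitions (A<->G, C<->T) and `Q` the proportion of
#' transversions, and
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions/site.
#' When `L_valid` is zero or the log argument is non-positive (saturation),
#' the distance is undefined and flagged rather than returned as `NaN`.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return A one-row tibble: `P`, `Q`, `L_valid`, `d`, `defined`.
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGA")
#' @export
k2p_distance <- function(a, b) {
  av <- strsplit(normalise_seq(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(normalise_seq(b), "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) abort("Sequences must be aligned (equal length).")
  k2p_from_chars(av, bv)
}

# core K2P on character vectors (shared by the matrix builder)
k2p_from_chars <- function(av, bv) {
  bases <- c("A", "C", "G", "T")
  ok <- av %in% bases & bv %in% bases
  L <- sum(ok)
  if (L == 0) {
    return(tibble(P = NA_real_, Q = NA_real_, L_valid = 0L,
                  d = NA_real_, defined = FALSE))
  }
  x <- av[ok]
  y <- bv[ok]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(tibble(P = P, Q = Q, L_valid = as.integer(L),
                  d = NA_real_, defined = FALSE))
  }
  tibble(P = P, Q = Q, L_valid = as.integer(L),
         d = -0.5 * log(w1 * sqrt(w2)), defined = TRUE)
}

# integer base coding (A,C,G,T -> 1..4; gap/ambiguity -> 0); transitions are
# exactly the code pairs differing by 2
encode_bases <- function(m) {
  E <- match(m, c("A", "C", "G", "T"))
  E[is.na(E)] <- 0L
  dim(E) <- dim(m)
  rownames(E) <- rownames(m)
  E
}

# all-pairs K2P from an encoded matrix (hot path: bootstrap replicates)
k2p_matrix_from_codes <- function(E) {
  n <- nrow(E)
  labels <- rownames(E)
  d <- P <- Q <- matrix(0, n, n, dimnames = list(labels, labels))
  L <- matrix(ncol(E), n, n, dimnames = list(labels, labels))
  defined <- matrix(TRUE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    xi <- E[i, ]
    for (j in (i + 1):n) {
      yj <- E[j, ]
      ok <- xi > 0L & yj > 0L
      Lv <- sum(ok)
      if (Lv == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        P[i, j] <- P[j, i] <- Q[i, j] <- Q[j, i] <- NA_real_
        L[i, j] <- L[j, i] <- 0L
        defined[i, j] <- defined[j, i] <- FALSE
        next
      }
      dif <- ok & xi != yj
      nts <- sum(dif & abs(xi - yj) == 2L)
      Pv <- nts / Lv
      Qv <- (sum(dif) - nts) / Lv
      w1 <- 1 - 2 * Pv - Qv
      w2 <- 1 - 2 * Qv
      P[i, j] <- P[j, i] <- Pv
      Q[i, j] <- Q[j, i] <- Qv
      L[i, j] <- L[j, i] <- Lv
      if (w1 <= 0 || w2 <= 0) {
        d[i, j] <- d[j, i] <- NA_real_
        defined[i, j] <- defined[j, i] <- FALSE
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(w1 * sqrt(w2))
      }
    }
  }
  structure(
    list(d = d, P = P, Q = Q, L_valid = L, defined = defined, labels = labels),
    class = "k2p_matrix"
  )
}

#' All-pairs K2P distance matrix
#'
#' @param aln An aligned sequence table (>= 2 rows).
#' @return A `k2p_matrix`: a list of labelled symmetric matrices `d`, `P`,
#'   `Q`, `L_valid` and a logical `defined` mask (diagonal zero / `TRUE`).
#' @export
pairwise_matrix <- function(aln) {
  aln <- as_seq_tbl(aln, aligned = TRUE)
  if (nrow(aln) < 2) abort("Need at least two rows for a distance matrix.")
  k2p_matrix_from_codes(encode_bases(aln_matrix(aln)))
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat(sprintf("<k2p_matrix> %d x %d", length(x$labels), length(x$labels)))
  n_undef <- sum(!x$defined[upper.tri(x$defined)])
  if (n_undef > 0) cat(sprintf(" (%d undefined pairs)", n_undef))
  cat("\n")
  print(round(x$d, 4), ...)
  invisible(x)
}

#' @describeIn pairwise_matrix Long tibble of unordered pairs.
#' @param x A `k2p_matrix`.
#' @param ... Unused.
#' @export
tidy.k2p_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id_a = x$labels[idx[, 1]],
    id_b = x$labels[idx[, 2]],
    P = x$P[idx],
    Q = x$Q[idx],
    L_valid = as.integer(x$L_valid[idx]),
    d = x$d[idx],
    defined = x$defined[idx]
  )
}

#' Intra- and inter-specific mean K2P distances
#'
#' Within-species means average `d` over unordered conspecific pairs;
#' between-species means average over all cross pairs. By default every
#' matrix row counts once (the natural mode when the matrix is built over
#' unique haplotypes); passing per-row frequencies via `freq` gives
#' sample-frequency-weighted means instead (identical samples contribute
#' zero-distance pairs). Undefined pairs are excluded from means with a
#' warning. Percentages are `100 * d` rounded to 2 decimals, half away
#' from zero.
#'
#' @param x A `k2p_matrix`.
#' @param meta A table mapping rows to species: columns `sample_id` (or `id`)
#'   and `species`, plus optional `is_outgroup`.
#' @param include_outgroup Keep outgroup rows; default `FALSE`.
#' @param freq Optional named vector of per-row sample counts for
#'   frequency-weighted means.
#' @return A `distance_summary`: tibbles `within` (`species`, `n_seqs`,
#'   `n_pairs`, `mean_d`, `mean_pct`) and `between` (`species_a`, `species_b`,
#'   `mean_d`, `mean_pct`).
#' @export
group_means <- function(x, meta, include_outgroup = FALSE, freq = NULL) {
  idcol <- if ("sample_id" %in% names(meta)) "sample_id" else "id"
  sp <- setNames(meta$species, meta[[idcol]])
  missing <- setdiff(x$labels, names(sp))
  if (length(missing) > 0) {
    abort(sprintf("No species for row(s): %s.", paste(head(missing, 5), collapse = ", ")))
  }
  keep <- x$labels
  if (!include_outgroup && "is_outgroup" %in% names(meta)) {
    og <- setNames(meta$is_outgroup, meta[[idcol]])
    keep <- keep[!og[keep]]
  }
  labels <- keep
  spv <- sp[labels]
  d <- x$d[labels, labels, drop = FALSE]
  defined <- x$defined[labels, labels, drop = FALSE]
  if (any(!defined[upper.tri(defined)])) {
    warn(sprintf("%d undefined pair(s) excluded from group means.",
                 sum(!defined[upper.tri(defined)])))
  }
  f <- if (is.null(freq)) setNames(rep(1, length(labels)), labels) else freq[labels]

  species <- unique(spv)
  within <- purrr::map_dfr(species, function(s) {
    rows <- which(spv == s)
    n <- length(rows)
    if (n < 2 && (is.null(freq) || sum(f[rows]) < 2)) {
      return(tibble(species = s, n_seqs = n, n_pairs = 0L,
                    mean_d = NA_real_, mean_pct = NA_real_))
    }
    num <- 0; den <- 0; npairs <- 0L
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (!defined[rows[i], rows[j]]) next
          w <- f[rows[i]] * f[rows[j]]
          num <- num + w * d[rows[i], rows[j]]
          den <- den + w
          npairs <- npairs + 1L
        }
      }
    }
    if (!is.null(freq)) {
      # pairs of identical samples within one haplotype have distance zero
      den <- den + sum(f[rows] * (f[rows] - 1) / 2)
    }
    mean_d <- if (den > 0) unname(num / den) else NA_real_
    tibble(species = s, n_seqs = n, n_pairs = npairs,
           mean_d = mean_d, mean_pct = round_half_up(100 * mean_d))
  })

  pairs <- if (length(species) >= 2) combn(species, 2) else matrix(character(0), 2, 0)
  between <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    sa <- pairs[1, k]; sb <- pairs[2, k]
    ra <- which(spv == sa); rb <- which(spv == sb)
    sub_d <- d[ra, rb, drop = FALSE]
    sub_ok <- defined[ra, rb, drop = FALSE]
    w <- outer(f[ra], f[rb])
    num <- sum(w[sub_ok] * sub_d[sub_ok])
    den <- sum(w[sub_ok])
    mean_d <- if (den > 0) num / den else NA_real_
    tibble(species_a = sa, species_b = sb,
           mean_d = mean_d, mean_pct = round_half_up(100 * mean_d))
  })

  structure(list(within = within, between = between),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary>\nWithin species:\n")
  print(x$within, ...)
  cat("Between species:\n")
  print(x$between, ...)
  invisible(x)
}

#' @describeIn group_means Long tibble of within and between means.
#' @export
tidy.distance_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$within, comparison = "within",
                     species_a = .data$species, species_b = .data$species,
                     mean_d = .data$mean_d, mean_pct = .data$mean_pct),
    dplyr::mutate(x$between, comparison = "between", .before = 1)
  )
}

#' Barcode-gap report
#'
#' Summarises the separation between intra- and inter-specific divergence:
#' the largest within-species mean, the smallest between-species mean, their
#' difference (the barcoding gap; negative means overlap), and each species'
#' nearest-neighbour distance.
#'
#' @param summary A `distance_summary` from [group_means()].
#' @return A `barcode_gap_report`: list with one-row `gap` tibble
#'   (`max_within_pct`, `min_between_pct`, `max_between_pct`, `gap_pct`) and a
#'   `nearest` tibble (`species`, `nearest_neighbor`, `distance_pct`).
#' @export
barcode_gap <- function(summary) {
  w <- summary$within$mean_pct
  b <- summary$between$mean_pct
  if (all(is.na(b))) abort("No between-species distances available.")
  max_within <- if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
  gap <- tibble(
    max_within_pct = max_within,
    min_between_pct = min(b, na.rm = TRUE),
    max_between_pct = max(b, na.rm = TRUE),
    gap_pct = min(b, na.rm = TRUE) - max_within
  )
  species <- unique(c(summary$between$species_a, summary$between$species_b))
  nearest <- purrr::map_dfr(species, function(s) {
    rows <- summary$between[summary$between$species_a == s |
                              summary$between$species_b == s, ]
    k <- which.min(rows$mean_pct)
    other <- ifelse(rows$species_a[k] == s, rows$species_b[k], rows$species_a[k])
    tibble(species = s, nearest_neighbor = other, distance_pct = rows$mean_pct[k])
  })
  structure(list(gap = gap, nearest = nearest), class = "barcode_gap_report")
}

#' @export
print.barcode_gap_report <- function(x, ...) {
  cat("<barcode_gap_report>\n")
  print(x$gap, ...)
  cat("Nearest neighbours:\n")
  print(x$nearest, ...)
  invisible(x)
}

#' @describeIn barcode_gap One-row gap summary.
#' @param x A `barcode_gap_report`.
#' @param ... Unused.
#' @export
glance.barcode_gap_report <- function(x, ...) x$gap

#' @describeIn barcode_gap Per-species nearest-neighbour distances.
#' @export
tidy.barcode_gap_report <- function(x, ...) x$nearest

#' Plot the intra/inter-specific distance structure
#'
#' Dot plot of within-species means against each species' nearest-neighbour
#' between-species distance; species above the identity line show a positive
#' local barcoding gap.
#'
#' @param object A `distance_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_summary <- function(object, ...) {
  gapr <- barcode_gap(object)
  df <- dplyr::left_join(
    dplyr::select(object$within, "species", within_pct = "mean_pct"),
    dplyr::select(gapr$nearest, "species", nearest_pct = "distance_pct"),
    by = "species"
  )
  df$within_pct[is.na(df$within_pct)] <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$within_pct, y = .data$nearest_pct,
                                   label = .data$species)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = "Mean intra-specific K2P distance (%)",
      y = "Nearest-neighbour inter-specific distance (%)",
      title = "Barcoding gap"
    )
}
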