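#' Alignment scoring scheme
#'
#' Affine-gap scheme for global alignment of barcode sequences. A gap of
#' length `k` costs `gap_open + k * gap_extend` (both penalties are
#' non-positive). Defaults are EDNAFULL-like; barcode sequences are typically
#' >90% identical so results are insensitive to the exact values, but a fixed
#' default keeps alignments deterministic.
#'
#' @param match Score for an identical base pair (default 5).
#' @param mismatch Score for a substitution (default -4); must be `< match`.
#' @param gap_open Gap opening penalty (default -10, `<= 0`).
#' @param gap_extend Per-residue gap extension penalty (default -0.5, `<= 0`).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4,
                           gap_open = -10, gap_extend = -0.5) {
  if (match <= mismatch) abort("`match` must exceed `mismatch`.")
  if (gap_open > 0 || gap_extend > 0) {
    abort("Gap penalties must be non-positive.")
  }
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment. The returned score is the optimum
#' for the scheme; traceback ties are broken by preferring a diagonal move,
#' then a gap in `b` ("up"), then a gap in `a` ("left"), so layouts are
#' reproducible.
#'
#' @param a,b Ungapped sequence strings.
#' @param scheme A [scoring_scheme()].
#' @return A list with `aligned_a`, `aligned_b` (equal-length gapped strings)
#'   and `score`.
#' @examples
#' pairwise_align("ACGT", "AGT")
#' @export
pairwise_align <- function(a, b, scheme = scoring_scheme()) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("Cannot align an empty sequence.")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE)) {
    abort("pairwise_align() expects ungapped input sequences.")
  }
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  NEG <- -Inf

  # state matrices over (0..n) x (0..m):
  #   M ends in a residue pair, X in a gap in b ("up"), Y in a gap in a ("left")
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- go + ge * seq_len(n)
  Y[1, 2:(m + 1)] <- go + ge * seq_len(m)

  js <- seq_len(m) + 1L
  for (i in seq_len(n) + 1L) {
    sub <- ifelse(av[i - 1L] == bv[js - 1L], scheme$match, scheme$mismatch)
    M[i, js] <- pmax(M[i - 1L, js - 1L], X[i - 1L, js - 1L], Y[i - 1L, js - 1L]) + sub
    X[i, js] <- pmax(M[i - 1L, js] + go + ge,
                     X[i - 1L, js] + ge,
                     Y[i - 1L, js] + go + ge)
    X[i, 1L] <- go + ge * (i - 1L)
    # left-gap state via running-max scan within the row
    V <- pmax(M[i, ], X[i, ])
    W <- cummax(V - ge * (0:m) + go)
    Y[i, js] <- ge * (js - 1L) + W[js - 1L]
  }

  tol <- 1e-9
  states <- c("M", "X", "Y")
  pick <- function(vals, target) states[which(vals >= target - tol)[1]]

  i <- n + 1L
  j <- m + 1L
  final <- c(M[i, j], X[i, j], Y[i, j])
  state <- pick(final, max(final))
  score <- max(final)
  out_a <- character(0)
  out_b <- character(0)
  while (i > 1L || j > 1L) {
    if (state == "M") {
      out_a <- c(av[i - 1L], out_a)
      out_b <- c(bv[j - 1L], out_b)
      vals <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      sub <- if (av[i - 1L] == bv[j - 1L]) scheme$match else scheme$mismatch
      state <- pick(vals, M[i, j] - sub)
      i <- i - 1L
      j <- j - 1L
    } else if (state == "X") {
      out_a <- c(av[i - 1L], out_a)
      out_b <- c("-", out_b)
      vals <- c(M[i - 1L, j] + go + ge, X[i - 1L, j] + ge, Y[i - 1L, j] + go + ge)
      state <- if (i == 2L && j == 1L) "M" else pick(vals, X[i, j])
      i <- i - 1L
    } else {
      out_a <- c("-", out_a)
      out_b <- c(bv[j - 1L], out_b)
      vals <- c(M[i, j - 1L] + go + ge, X[i, j - 1L] + go + ge, Y[i, j - 1L] + ge)
      state <- if (j == 2L && i == 1L) "M" else pick(vals, Y[i, j])
      j <- j - 1L
    }
  }
  list(
    aligned_a = paste0(out_a, collapse = ""),
    aligned_b = paste0(out_b, collapse = ""),
    score = score
  )
}

# k-mer count matrix over a shared k-mer vocabulary (alignment-free distance
# proxy for center selection); one row per sequence
kmer_count_matrix <- function(seqs, k = 5L) {
  kmers_of <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) s else substring(s, 1:(n - k + 1), k:n)
  })
  vocab <- unique(unlist(kmers_of))
  t(vapply(kmers_of, function(km) {
    tabulate(match(km, vocab), nbins = length(vocab))
  }, integer(length(vocab))))
}

#' Center-star multiple sequence alignment
#'
#' Progressive alignment adequate for near-identical barcode sequences: the
#' center is the record minimising the summed alignment-free k-mer distance to
#' all others; every other record is aligned to the center with
#' [pairwise_align()] and the pairwise gap patterns are merged
#' ("once a gap, always a gap", new gap columns padded on the right of each
#' inter-residue slot). Deterministic for a fixed input order and scheme.
#'
#' @param seqs A sequence table (columns `id`, `seq`; metadata columns are
#'   preserved). Sequences must be ungapped.
#' @param scheme A [scoring_scheme()].
#' @return The input table with `seq` replaced by aligned (equal-length) rows.
#' @export
build_msa <- function(seqs, scheme = scoring_scheme()) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) == 0) abort("Cannot align zero records.")
  if (any(grepl("-", seqs$seq, fixed = TRUE))) {
    abort("build_msa() expects ungapped input; use load_prealigned() for aligned rows.")
  }
  if (nrow(seqs) == 1) return(seqs)

  counts <- kmer_count_matrix(seqs$seq)
  n <- nrow(seqs)
  dsum <- numeric(n)
  for (i in seq_len(n - 1)) {
    di <- rowSums(abs(counts[(i + 1):n, , drop = FALSE] -
                        rep(counts[i, ], each = n - i)))
    dsum[i] <- dsum[i] + sum(di)
    dsum[(i + 1):n] <- dsum[(i + 1):n] + di
  }
  center <- which.min(dsum)

  c_res <- strsplit(seqs$seq[center], "", fixed = TRUE)[[1]]
  nres <- length(c_res)
  # master gap-slot sizes: gaps before residue 1, between residues, after last
  g <- integer(nres + 1)
  # each merged row: list(slots = char vectors per slot, res = chars vs residues)
  rows <- vector("list", n)

  decompose <- function(ca, oa) {
    cav <- strsplit(ca, "", fixed = TRUE)[[1]]
    oav <- strsplit(oa, "", fixed = TRUE)[[1]]
    res_idx <- cumsum(cav != "-")          # which residue each column precedes/holds
    slot_of <- res_idx[cav == "-"]         # gap columns fall in slot res_idx (0..nres)
    h <- tabulate(slot_of + 1L, nbins = nres + 1L)
    slots <- lapply(0:nres, function(s) oav[cav == "-" & res_idx == s])
    list(h = h, slots = slots, res = oav[cav != "-"])
  }

  pad <- function(x, len) c(x, rep("-", len - length(x)))

  for (k in seq_len(n)) {
    if (k == center) next
    pa <- pairwise_align(seqs$seq[center], seqs$seq[k], scheme)
    dec <- decompose(pa$aligned_a, pa$aligned_b)
    newg <- pmax(g, dec$h)
    if (any(newg > g)) {
      for (r in seq_len(n)) {
        if (is.null(rows[[r]])) next
        rows[[r]]$slots <- lapply(seq_len(nres + 1L),
                                  function(s) pad(rows[[r]]$slots[[s]], newg[s]))
      }
      g <- newg
    }
    dec$slots <- lapply(seq_len(nres + 1L), function(s) pad(dec$slots[[s]], g[s]))
    rows[[k]] <- dec[c("slots", "res")]
  }
  rows[[center]] <- list(
    slots = lapply(g, function(len) rep("-", len)),
    res = c_res
  )

  assemble <- function(row) {
    pieces <- character(0)
    for (s in seq_len(nres)) {
      pieces <- c(pieces, row$slots[[s]], row$res[s])
    }
    paste0(c(pieces, row$slots[[nres + 1L]]), collapse = "")
  }
  seqs$seq <- vapply(rows, assemble, character(1))
  as_seq_tbl(seqs, aligned = TRUE)
}

#' Accept pre-aligned input
#'
#' Validates that rows are equal length (gaps allowed) and returns the table
#' unchanged, so datasets aligned with external software can enter the
#' pipeline directly.
#'
#' @param seqs A sequence table whose rows are already aligned.
#' @return The validated aligned table.
#' @export
load_prealigned <- function(seqs) {
  as_seq_tbl(seqs, aligned = TRUE)
}

#' Align a sequence table (dispatching on pre-aligned input)
#'
#' If all rows are equal length and any row contains a gap character the input
#' is treated as pre-aligned; otherwise a center-star MSA is built.
#'
#' @inheritParams build_msa
#' @param prealigned Force the pre-aligned path.
#' @return An aligned sequence table.
#' @export
align_sequences <- function(seqs, scheme = scoring_scheme(), prealigned = FALSE) {
  seqs <- as_seq_tbl(seqs)
  lens <- nchar(seqs$seq)
  has_gap <- any(grepl("-", seqs$seq, fixed = TRUE))
  if (prealigned || (length(unique(lens)) == 1 && has_gap)) {
    return(load_prealigned(seqs))
  }
  if (length(unique(lens)) == 1 && !has_gap) {
    # equal-length ungapped barcodes: stacking is already a valid alignment,
    # but gaps could still improve the score; center-star handles both.
    return(build_msa(seqs, scheme))
  }
  build_msa(seqs, scheme)
}
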