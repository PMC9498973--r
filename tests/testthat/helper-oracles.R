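# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations.

# exhaustive global-alignment optimum with affine gaps, by recursive
# enumeration over (i, j, state); feasible for sequences up to ~8 bp
brute_force_align_score <- function(a, b, scheme = scoring_scheme()) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) scheme$match else scheme$mismatch
      rec(i + 1, j + 1, "M", score + s)
    }
    if (i <= length(av)) {
      pen <- if (state == "X") ge else go + ge
      rec(i + 1, j, "X", score + pen)
    }
    if (j <= length(bv)) {
      pen <- if (state == "Y") ge else go + ge
      rec(i, j + 1, "Y", score + pen)
    }
  }
  rec(1, 1, "start", 0)
  best
}

# direct K2P recount on two character vectors (no shared code with the package)
oracle_k2p <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  P <- sum(is_ts(av, bv)) / length(av)
  Q <- sum(av != bv & !is_ts(av, bv)) / length(av)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# least-squares branch lengths for a fixed 4-taxon unrooted topology
# topology given as split list(c(1,2), c(3,4)) over label indices
ls_quartet <- function(D, split) {
  i <- split[[1]][1]; j <- split[[1]][2]
  k <- split[[2]][1]; l <- split[[2]][2]
  # design: paths over branches (bi, bj, bk, bl, bm)
  X <- rbind(
    c(1, 1, 0, 0, 0),  # d(i,j)
    c(1, 0, 1, 0, 1),  # d(i,k)
    c(1, 0, 0, 1, 1),  # d(i,l)
    c(0, 1, 1, 0, 1),  # d(j,k)
    c(0, 1, 0, 1, 1),  # d(j,l)
    c(0, 0, 1, 1, 0)   # d(k,l)
  )
  y <- c(D[i, j], D[i, k], D[i, l], D[j, k], D[j, l], D[k, l])
  fit <- stats::lm.fit(X, y)
  list(branches = fit$coefficients, rss = sum(fit$residuals^2))
}

# random additive distance matrix from a random binary tree (via ape)
random_additive_matrix <- function(n, seed) {
  with_seed_local(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    list(D = ape::cophenetic.phylo(tr), tree = tr)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# tiny aligned fixture: 2 species, fixed difference at column 3, shared
# polymorphism elsewhere
tiny_alignment <- function() {
  tibble::tibble(
    id = c("a1", "a2", "a3", "b1", "b2"),
    seq = c("ACGTACGT", "ACGTACGT", "ACGAACGT", "ACCTACGT", "ACCTACGA"),
    species = c("spA", "spA", "spA", "spB", "spB"),
    is_outgroup = FALSE
  )
}

small_sim <- function(seed = 101, ...) {
  simulate_dataset(sim_config(
    seed = seed, n_species = 4, samples_per_species = 6,
    haplotypes_per_species = 3, seq_len = 420, region_lens = c(130, 164, 126),
    n_diagnostic_per_species = 3, indel_rate = 0, ambiguity_rate = 0, ...
  ))
}

# Robinson-Foulds distance as a bare number (ape returns a classed object)
rf_dist <- function(t1, t2) as.numeric(ape::dist.topo(t1, t2))
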