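# ---- neighbor joining ---------------------------------------------------

# extract a plain symmetric numeric matrix from k2p_matrix / dist / matrix
as_dist_matrix <- function(x) {
  if (inherits(x, "k2p_matrix")) {
    if (any(!x$defined)) {
      abort(paste0(
        "Distance matrix contains undefined pairs; exclude the offending ",
        "rows or impute before tree building."
      ))
    }
    return(x$d)
  }
  if (inherits(x, "dist")) return(as.matrix(x))
  if (is.matrix(x)) {
    if (any(is.na(x))) abort("Distance matrix contains NA entries.")
    return(x)
  }
  abort("Expected a k2p_matrix, dist or matrix.")
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining. Exact on additive
#' matrices; negative branch lengths are clamped to zero. Ties in the
#' minimum-Q criterion are broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its alphabetically first leaf),
#' so the result is deterministic.
#'
#' @param x A `k2p_matrix` from [pairwise_matrix()], a `dist`, or a labelled
#'   symmetric matrix with at least 3 rows.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(x) {
  D <- as_dist_matrix(x)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) abort("Need at least 3 taxa for neighbor joining.")

  fmt_bl <- function(t) format(max(t, 0), digits = 15, scientific = FALSE, trim = TRUE)
  quote_lab <- function(l) {
    if (grepl("[][ ();:,']", l)) paste0("'", gsub("'", "''", l), "'") else l
  }
  # active clusters: newick fragment + sort key (smallest leaf label)
  frag <- vapply(labels, quote_lab, character(1))
  key <- labels
  tol <- 1e-12

  while (n > 3) {
    r <- rowSums(D)
    Qm <- (n - 2) * D - outer(r, r, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm <= qmin + tol * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    best <- cand[order(pair_keys)[1], ]
    i <- best[1]; j <- best[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    new_frag <- paste0("(", frag[i], ":", fmt_bl(bi), ",",
                       frag[j], ":", fmt_bl(bj), ")")
    new_key <- min(key[i], key[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    rownames(D) <- colnames(D) <- key
    n <- n - 1
  }
  # three-point formulas for the final star
  b1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  b2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  b3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  nwk <- paste0("(", frag[1], ":", fmt_bl(b1), ",",
                frag[2], ":", fmt_bl(b2), ",",
                frag[3], ":", fmt_bl(b3), ");")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# ---- K80 likelihood -----------------------------------------------------

# K80 transition probability matrix for branch length t (subst/site) and
# transition/transversion rate ratio kappa; rows/cols in order A,C,G,T
k80_pmatrix <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2   # transition (A<->G, C<->T)
  tv <- 0.25 - 0.25 * e1              # each transversion target
  matrix(c(
    same, tv, ts, tv,
    tv, same, tv, ts,
    ts, tv, same, tv,
    tv, ts, tv, same
  ), 4, 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
}

# compress an alignment (rows matched to tip labels) into leaf partials over
# unique site patterns; gaps/ambiguity become partial indicator vectors
build_pattern_data <- function(aln, tip_labels) {
  m <- aln_matrix(aln)
  missing <- setdiff(tip_labels, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("Alignment has no row for tip(s): %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- m[tip_labels, , drop = FALSE]
  pat_key <- apply(m, 2, paste0, collapse = "")
  first <- !duplicated(pat_key)
  weights <- as.vector(table(factor(pat_key, levels = pat_key[first])))
  mp <- m[, first, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  partials <- lapply(seq_len(nrow(mp)), function(i) {
    sapply(mp[i, ], function(ch) {
      if (ch %in% names(IUPAC_SETS)) as.numeric(bases %in% IUPAC_SETS[[ch]])
      else rep(1, 4)   # gap: missing data
    })
  })
  list(partials = partials, weights = weights, n_patterns = sum(first),
       n_sites = ncol(m))
}

# children list + postorder node sequence for a phylo tree
tree_structure <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- vector("list", n_tip + tree$Nnode)
  edge_of <- integer(n_tip + tree$Nnode)   # edge index leading to each node
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    children[[p]] <- c(children[[p]], ch)
    edge_of[ch] <- e
  }
  post <- integer(0)
  stack <- root
  visit <- integer(0)
  while (length(stack) > 0) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, node)
    stack <- c(stack, children[[node]])
  }
  post <- rev(visit)
  list(children = children, edge_of = edge_of, postorder = post, root = root,
       n_tip = n_tip)
}

#' K80 log-likelihood of a tree
#'
#' Felsenstein pruning under the Kimura 2-parameter (K80) substitution model
#' with equal base frequencies. Gap characters and IUPAC ambiguity codes are
#' treated as (partially) missing data at that leaf and site. Site
#' log-likelihoods are summed over unique site patterns.
#'
#' @param tree A `phylo` whose tip labels match alignment row ids.
#' @param aln An aligned sequence table containing every tip.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return The log-likelihood (scalar).
#' @export
k80_loglik <- function(tree, aln, kappa = 2) {
  pd <- build_pattern_data(aln, tree$tip.label)
  st <- tree_structure(tree)
  k80_loglik_impl(tree, st, pd, kappa)
}

k80_loglik_impl <- function(tree, st, pd, kappa) {
  if (kappa <= 0) return(-Inf)
  S <- pd$n_patterns
  part <- vector("list", length(st$children))
  for (node in st$postorder) {
    kids <- st$children[[node]]
    if (length(kids) == 0) {
      part[[node]] <- pd$partials[[node]]
      next
    }
    acc <- matrix(1, 4, S)
    for (ch in kids) {
      t_ch <- tree$edge.length[st$edge_of[ch]]
      P <- k80_pmatrix(t_ch, kappa)
      acc <- acc * (P %*% part[[ch]])
    }
    part[[node]] <- acc
  }
  site_lik <- 0.25 * colSums(part[[st$root]])
  if (any(site_lik <= 0) || any(!is.finite(site_lik))) {
    bad <- which(site_lik <= 0 | !is.finite(site_lik))[1]
    abort(sprintf("Non-finite likelihood at site pattern %d.", bad))
  }
  sum(pd$weights * log(site_lik))
}

# ---- ML search ----------------------------------------------------------

optimise_branches <- function(tree, st, pd, kappa, lower = 0, upper = 10,
                              tol = 1e-6, max_passes = 20) {
  ll_prev <- k80_loglik_impl(tree, st, pd, kappa)
  for (pass in seq_len(max_passes)) {
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tree$edge.length[e] <- t
        k80_loglik_impl(tree, st, pd, kappa)
      }
      opt <- optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
      cur <- tree$edge.length[e]
      if (opt$objective > f(cur)) tree$edge.length[e] <- opt$maximum
    }
    ll <- k80_loglik_impl(tree, st, pd, kappa)
    if (ll - ll_prev < tol) break
    ll_prev <- ll
  }
  tree
}

optimise_kappa <- function(tree, st, pd, kappa, tol = 1e-6) {
  f <- function(k) k80_loglik_impl(tree, st, pd, k)
  opt <- optimize(f, c(0.02, 100), maximum = TRUE, tol = tol)
  if (opt$objective > f(kappa)) opt$maximum else kappa
}

# the two NNI rearrangements around internal edge (u, v): swap one fixed
# other-subtree of u with each child subtree of v
nni_neighbours <- function(tree, edge_idx) {
  u <- tree$edge[edge_idx, 1]
  v <- tree$edge[edge_idx, 2]
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(list())
  v_children <- tree$edge[tree$edge[, 1] == v, 2]
  u_children <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  if (length(u_children) == 0) return(list())
  x <- u_children[1]
  lapply(v_children, function(c1) {
    t2 <- tree
    ex <- which(t2$edge[, 2] == x)
    ec <- which(t2$edge[, 2] == c1)
    t2$edge[ex, 1] <- v
    t2$edge[ec, 1] <- u
    # renormalise internal bookkeeping
    attr(t2, "order") <- NULL
    t2
  })
}

#' Maximum-likelihood tree search under K80
#'
#' Hill-climbing search alternating (a) per-branch length optimisation by
#' bounded univariate search (branch lengths in `[0, 10]`, tolerance `1e-6`),
#' (b) kappa optimisation, and (c) nearest-neighbour-interchange moves
#' accepting strict likelihood improvements, until an NNI-local optimum is
#' reached. Deterministic for a fixed start tree (default: the
#' neighbor-joining tree on the K2P distance matrix).
#'
#' @param aln An aligned sequence table.
#' @param start Optional `phylo` start tree; default NJ on [pairwise_matrix()].
#' @param kappa Initial transition/transversion ratio (default 2).
#' @param optimise_kappa Jointly optimise kappa (default `TRUE`).
#' @param max_rounds Safety cap on NNI acceptance rounds.
#' @return A `k80_fit`: list with `tree` (branch-length-optimised `phylo`),
#'   `kappa`, `loglik`, `n_nni_accepted`.
#' @export
ml_search <- function(aln, start = NULL, kappa = 2, optimise_kappa = TRUE,
                      max_rounds = 100) {
  aln <- as_seq_tbl(aln, aligned = TRUE)
  if (is.null(start)) start <- neighbor_joining(pairwise_matrix(aln))
  tree <- start
  pd <- build_pattern_data(aln, tree$tip.label)
  eps <- 1e-8
  n_acc <- 0L

  score <- function(tr) {
    st <- tree_structure(tr)
    tr <- optimise_branches(tr, st, pd, kappa)
    list(tree = tr, loglik = k80_loglik_impl(tr, st, pd, kappa))
  }
  cur <- score(tree)
  if (optimise_kappa) {
    st <- tree_structure(cur$tree)
    kappa <- optimise_kappa(cur$tree, st, pd, kappa)
    cur <- score(cur$tree)
  }

  for (round in seq_len(max_rounds)) {
    st <- tree_structure(cur$tree)
    internal <- which(cur$tree$edge[, 2] > st$n_tip)
    best <- NULL
    for (e in internal) {
      for (cand in nni_neighbours(cur$tree, e)) {
        sc <- score(cand)
        if (sc$loglik > cur$loglik + eps &&
            (is.null(best) || sc$loglik > best$loglik)) {
          best <- sc
        }
      }
    }
    if (is.null(best)) break
    cur <- best
    n_acc <- n_acc + 1L
    if (optimise_kappa) {
      st <- tree_structure(cur$tree)
      kappa <- optimise_kappa(cur$tree, st, pd, kappa)
      cur <- score(cur$tree)
    }
  }
  # NNI edits leave the edge table valid but unordered; round-trip through
  # Newick to restore canonical ape ordering for downstream consumers
  cur$tree <- read_newick(write_newick(cur$tree))
  structure(
    list(tree = cur$tree, kappa = kappa, loglik = cur$loglik,
         n_nni_accepted = n_acc, n_sites = pd$n_sites),
    class = "k80_fit"
  )
}

#' @export
print.k80_fit <- function(x, ...) {
  cat(sprintf(
    "<k80_fit> %d tips, logLik %.4f, kappa %.4f, %d NNI move(s) accepted\n",
    length(x$tree$tip.label), x$loglik, x$kappa, x$n_nni_accepted
  ))
  invisible(x)
}

#' @describeIn ml_search Edge table of the fitted tree.
#' @param x A `k80_fit`.
#' @param ... Unused.
#' @export
tidy.k80_fit <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  child <- x$tree$edge[, 2]
  tibble(
    parent = x$tree$edge[, 1],
    child = child,
    label = ifelse(child <= n_tip, x$tree$tip.label[child], NA_character_),
    length = x$tree$edge.length
  )
}

#' @describeIn ml_search One-row fit summary.
#' @export
glance.k80_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    kappa = x$kappa,
    n_tips = length(x$tree$tip.label),
    n_sites = x$n_sites,
    n_nni_accepted = x$n_nni_accepted
  )
}

# ---- bootstrap ----------------------------------------------------------

# canonical string for the bipartition induced by each internal edge
tree_bipartitions <- function(tree) {
  st <- tree_structure(tree)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1]
  tips_below <- vector("list", length(st$children))
  for (node in st$postorder) {
    kids <- st$children[[node]]
    tips_below[[node]] <- if (length(kids) == 0) tree$tip.label[node]
                          else unlist(tips_below[kids])
  }
  internal_edges <- which(tree$edge[, 2] > st$n_tip)
  bip <- vapply(internal_edges, function(e) {
    side <- sort(tips_below[[tree$edge[e, 2]]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    paste(side, collapse = "\r")
  }, character(1))
  # trivial bipartitions (empty or full complement) can arise at the root
  keep <- nzchar(bip)
  setNames(bip[keep], internal_edges[keep])
}

#' Bootstrap support for a point-estimate tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with the chosen builder, and annotates each internal edge of the
#' point-estimate tree with the percentage of replicates containing the same
#' bipartition. Supports are mapped onto the point-estimate tree (not a
#' consensus tree). Replicates whose distance matrix contains undefined pairs
#' are dropped and counted. All randomness flows from `seed`: replicate `r`
#' uses the r-th of `reps` sub-seeds pre-drawn from the master seed, so
#' replicate sets are reproducible.
#'
#' @param aln An aligned sequence table.
#' @param builder `"nj"` (K2P + neighbor joining) or `"ml"` ([ml_search()]).
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer master seed (required).
#' @param point_tree Optional precomputed point-estimate tree.
#' @return The point-estimate `phylo` with `node.label` supports (in %), plus
#'   attributes `n_replicates_used` and `n_replicates_dropped`.
#' @export
bootstrap_support <- function(aln, builder = c("nj", "ml"), reps = 1000,
                              seed, point_tree = NULL) {
  builder <- match.arg(builder)
  if (missing(seed)) abort("A seed is required for bootstrapping.")
  if (reps < 1) abort("Need at least one bootstrap replicate.")
  aln <- as_seq_tbl(aln, aligned = TRUE)
  build <- function(a) {
    if (builder == "nj") neighbor_joining(pairwise_matrix(a))
    else ml_search(a)$tree
  }
  if (is.null(point_tree)) point_tree <- build(aln)

  m <- aln_matrix(aln)
  L <- ncol(m)
  E <- encode_bases(m)   # fast path for distance-based replicates
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, reps))
  bip_point <- tree_bipartitions(point_tree)
  hits <- setNames(numeric(length(bip_point)), bip_point)
  used <- 0L
  dropped <- 0L
  for (r in seq_len(reps)) {
    cols <- with_seed(sub_seeds[r], sample.int(L, L, replace = TRUE))
    rep_tree <- tryCatch({
      if (builder == "nj") {
        neighbor_joining(k2p_matrix_from_codes(E[, cols, drop = FALSE]))
      } else {
        build(matrix_to_seq_tbl(m[, cols, drop = FALSE]))
      }
    }, error = function(e) NULL)
    if (is.null(rep_tree)) {
      dropped <- dropped + 1L
      next
    }
    used <- used + 1L
    rb <- tree_bipartitions(rep_tree)
    found <- bip_point %in% rb
    hits[found] <- hits[found] + 1
  }
  if (used == 0) abort("All bootstrap replicates failed.")
  support <- 100 * hits / used

  n_tip <- length(point_tree$tip.label)
  node_support <- rep(NA_real_, point_tree$Nnode)
  for (k in seq_along(bip_point)) {
    e <- as.integer(names(bip_point)[k])
    node_support[point_tree$edge[e, 2] - n_tip] <- support[k]
  }
  point_tree$node.label <- ifelse(is.na(node_support), "",
                                  format(round_half_up(node_support, 1),
                                         trim = TRUE))
  attr(point_tree, "n_replicates_used") <- used
  attr(point_tree, "n_replicates_dropped") <- dropped
  point_tree
}

# ---- rooting and monophyly ----------------------------------------------

#' Root a tree on the outgroup and assess species monophyly
#'
#' Roots the tree on the outgroup leaves and reports, for every species, whether
#' its samples form a complete clade (single-leaf species are monophyletic by
#' definition).
#'
#' @param tree A `phylo`.
#' @param meta Metadata with `sample_id` (or `id`) and `species` columns.
#' @param outgroup_species Species name used for rooting.
#' @return A list: `tree` (rooted `phylo`) and `monophyly` tibble
#'   (`species`, `n_tips`, `monophyletic`), outgroup excluded from the table.
#' @export
root_and_monophyly <- function(tree, meta, outgroup_species) {
  idcol <- if ("sample_id" %in% names(meta)) "sample_id" else "id"
  sp <- setNames(meta$species, meta[[idcol]])
  tips <- tree$tip.label
  og_tips <- tips[sp[tips] == outgroup_species]
  if (length(og_tips) == 0) {
    abort(sprintf("Outgroup species '%s' has no leaf in the tree.", outgroup_species))
  }
  rooted <- ape::root(tree, outgroup = og_tips, resolve.root = TRUE)

  st <- tree_structure(rooted)
  tips_below <- vector("list", length(st$children))
  clades <- character(0)
  for (node in st$postorder) {
    kids <- st$children[[node]]
    tb <- if (length(kids) == 0) rooted$tip.label[node] else unlist(tips_below[kids])
    tips_below[[node]] <- tb
    if (length(kids) > 0) clades <- c(clades, paste(sort(tb), collapse = "\r"))
  }
  ingroup_sp <- setdiff(unique(sp[tips]), outgroup_species)
  monophyly <- purrr::map_dfr(ingroup_sp, function(s) {
    leafs <- sort(tips[sp[tips] == s])
    mono <- length(leafs) == 1 || paste(leafs, collapse = "\r") %in% clades
    tibble(species = s, n_tips = length(leafs), monophyletic = mono)
  })
  list(tree = rooted, monophyly = monophyly)
}

# ---- Newick IO ----------------------------------------------------------

#' Write a tree as a Newick string
#'
#' Branch lengths are written at full precision; bootstrap supports (stored
#' in `node.label`) appear as internal-node labels; labels containing Newick
#' metacharacters or spaces are single-quoted. Round-trips through
#' [read_newick()].
#'
#' @param tree A `phylo`.
#' @param path Optional file path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  st <- tree_structure(tree)
  n_tip <- st$n_tip
  quote_lab <- function(l) {
    if (grepl("[][ ();:,']", l)) paste0("'", gsub("'", "''", l), "'") else l
  }
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  rec <- function(node) {
    kids <- st$children[[node]]
    lab <- if (node <= n_tip) {
      quote_lab(tree$tip.label[node])
    } else if (!is.null(tree$node.label)) {
      tree$node.label[node - n_tip]
    } else ""
    inner <- if (length(kids) == 0) {
      lab
    } else {
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", lab)
    }
    if (node == st$root) return(inner)
    e <- st$edge_of[node]
    bl <- if (is.null(tree$edge.length)) "" else paste0(":", fmt(tree$edge.length[e]))
    paste0(inner, bl)
  }
  nwk <- paste0(rec(st$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Read a Newick tree
#'
#' @param x A Newick string or a path to a Newick file.
#' @return A `phylo`.
#' @export
read_newick <- function(x) {
  tree <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  unquote <- function(l) {
    quoted <- grepl("^'.*'$", l)
    l[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", l[quoted]))
    l
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}
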