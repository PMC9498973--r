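test_that("NJ reconstructs additive matrices exactly (4 and more taxa)", {
  skip_if_not_installed("ape")
  for (case in 1:20) {
    n <- 4 + (case %% 5)
    ra <- random_additive_matrix(n, seed = 300 + case)
    tr <- neighbor_joining(ra$D)
    expect_equal(rf_dist(tr, ape::unroot(ra$tree)), 0,
                 info = sprintf("case %d (n=%d)", case, n))
    # branch lengths: additive matrices are reproduced exactly
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)],
                 ra$D, tolerance = 1e-8)
  }
})

test_that("the 4-taxon NJ split matches the exhaustive least-squares oracle", {
  for (case in 1:10) {
    ra <- random_additive_matrix(4, seed = 400 + case)
    labs <- rownames(ra$D)
    splits <- list(
      list(c(1, 2), c(3, 4)),
      list(c(1, 3), c(2, 4)),
      list(c(1, 4), c(2, 3))
    )
    rss <- vapply(splits, function(s) ls_quartet(ra$D, s)$rss, numeric(1))
    best <- splits[[which.min(rss)]]
    tr <- neighbor_joining(ra$D)
    # the oracle's best split must be the NJ tree's internal bipartition
    cherry <- sort(labs[best[[1]]])
    anchor <- sort(labs)[1]
    if (anchor %in% cherry) cherry <- sort(setdiff(labs, cherry))
    expect_equal(unname(tree_bipartitions(tr)),
                 paste(cherry, collapse = "\r"),
                 info = sprintf("case %d", case))
  }
})

test_that("3 taxa are resolved by the three-point formulas", {
  D <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.25,
                0.3, 0.25, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (0.2 + 0.3 - 0.25) / 2)
  expect_equal(bl[["b"]], (0.2 + 0.25 - 0.3) / 2)
  expect_equal(bl[["c"]], (0.3 + 0.25 - 0.2) / 2)
})

test_that("tied distances resolve deterministically via the label rule", {
  D <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(write_newick(t1), write_newick(t2))
})

test_that("single invariant column on a zero-length star gives ln(1/4)", {
  aln <- tibble::tibble(id = c("a", "b", "c"), seq = "A")
  tr <- read_newick("(a:0,b:0,c:0);")
  expect_equal(k80_loglik(tr, aln, kappa = 2), log(0.25))
})

test_that("two-taxon likelihood matches the analytic K80 pair formula", {
  with_seed_local(7, {
    a <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    b <- evolve_k80(a, 0.15, kappa = 3)
  })
  aln <- tibble::tibble(id = c("a", "b"), seq = c(a, b))
  t1 <- 0.04; t2 <- 0.08
  tr <- read_newick(sprintf("(a:%f,b:%f);", t1, t2))
  ll <- k80_loglik(tr, aln, kappa = 3)
  # analytic: only the total path length matters for a pair
  kappa <- 3
  beta <- 1 / (kappa + 2)
  t <- t1 + t2
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (kappa * beta + beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  purine <- c("A", "G")
  is_ts <- av != bv & ((av %in% purine) == (bv %in% purine))
  n_same <- sum(av == bv)
  n_ts <- sum(is_ts)
  n_tv <- sum(av != bv & !is_ts)
  ll_ref <- n_same * log(0.25 * p_same) + n_ts * log(0.25 * p_ts) +
    n_tv * log(0.25 * p_tv)
  expect_equal(ll, ll_ref, tolerance = 1e-8)
})

test_that("likelihood is invariant under re-rooting", {
  skip_if_not_installed("ape")
  sim <- small_sim(seed = 61)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- dplyr::filter(aln, !duplicated(species))
  tr <- neighbor_joining(pairwise_matrix(sub))
  ll0 <- k80_loglik(tr, sub, kappa = 2.5)
  for (tip in sub$id[1:3]) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(k80_loglik(rerooted, sub, kappa = 2.5), ll0, tolerance = 1e-9)
  }
})

test_that("kappa = 1 likelihood equals Jukes-Cantor (model nesting)", {
  skip_if_not_installed("phangorn")
  sim <- small_sim(seed = 62)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- dplyr::filter(aln, !duplicated(species), !is_outgroup)
  tr <- neighbor_joining(pairwise_matrix(sub))
  m <- do.call(rbind, strsplit(sub$seq, ""))
  rownames(m) <- sub$id
  fit_jc <- phangorn::pml(tr, phangorn::phyDat(m), model = "JC")
  expect_equal(k80_loglik(tr, sub, kappa = 1), fit_jc$logLik, tolerance = 1e-6)
})

test_that("ML search is a fixed point at the optimum and never decreases", {
  sim <- small_sim(seed = 63)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- dplyr::filter(aln, !duplicated(species), !is_outgroup)
  start <- neighbor_joining(pairwise_matrix(sub))
  ll_start <- k80_loglik(start, sub, kappa = 2)
  fit <- ml_search(sub, start = start, kappa = 2)
  expect_gte(fit$loglik, ll_start)
  refit <- ml_search(sub, start = fit$tree, kappa = fit$kappa,
                     optimise_kappa = FALSE)
  expect_equal(refit$n_nni_accepted, 0L)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-4)
})

test_that("bootstrap supports are reproducible, bounded and strong for deep splits", {
  sim <- small_sim(seed = 64)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  h <- collapse_haplotypes(aln)
  reps_tbl <- dplyr::transmute(h$haplotypes, id = hap_id, seq = seq)
  t1 <- bootstrap_support(reps_tbl, builder = "nj", reps = 50, seed = 11)
  t2 <- bootstrap_support(reps_tbl, builder = "nj", reps = 50, seed = 11)
  expect_identical(write_newick(t1), write_newick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  # species-defining bipartitions should be at/near 100% for deep splits
  spof <- setNames(h$haplotypes$species, h$haplotypes$hap_id)
  rooted <- root_and_monophyly(
    t1, tibble::tibble(sample_id = names(spof), species = unname(spof)),
    outgroup_species = unique(spof)[1]
  )
  expect_true(all(rooted$monophyly$monophyletic))
})

test_that("bootstrapping identical sequences yields a well-defined degenerate tree", {
  aln <- tibble::tibble(id = c("a", "b", "c", "d"), seq = strrep("ACGT", 25))
  tr <- bootstrap_support(aln, reps = 5, seed = 3)
  expect_s3_class(tr, "phylo")
  expect_equal(sum(tr$edge.length), 0)
})

test_that("same seed gives identical supports; point topology is seed-independent", {
  sim <- small_sim(seed = 65)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- dplyr::filter(aln, !duplicated(paste(species, seq)))
  ta <- bootstrap_support(sub, reps = 20, seed = 1)
  tb <- bootstrap_support(sub, reps = 20, seed = 2)
  strip <- function(t) { t$node.label <- NULL; write_newick(t) }
  expect_identical(strip(ta), strip(tb))
})

test_that("rooting and monophyly assessment match ape on planted cases", {
  skip_if_not_installed("ape")
  # planted paraphyly: spB nests inside spA
  tr <- read_newick("(((a1:0.01,a2:0.01):0.02,(b1:0.01,a3:0.05):0.01):0.1,out:0.3);")
  meta <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1", "out"),
    species = c("spA", "spA", "spA", "spB", "outg")
  )
  res <- root_and_monophyly(tr, meta, "outg")
  expect_false(res$monophyly$monophyletic[res$monophyly$species == "spA"])
  expect_true(res$monophyly$monophyletic[res$monophyly$species == "spB"])
  for (s in c("spA", "spB")) {
    tips <- meta$sample_id[meta$species == s]
    expect_equal(
      res$monophyly$monophyletic[res$monophyly$species == s],
      ape::is.monophyletic(res$tree, tips), info = s
    )
  }
  expect_error(root_and_monophyly(tr, meta, "missing_species"), "no leaf")
})

test_that("Newick writing round-trips topology, lengths, supports and odd labels", {
  skip_if_not_installed("ape")
  nwk <- write_newick(read_newick("(A:0.1,B:0.1,C:0.1);"))
  expect_match(nwk, "^\\(A:0\\.1,B:0\\.1,C:0\\.1\\);$")

  sim <- small_sim(seed = 66)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- dplyr::filter(aln, !duplicated(species))
  tr <- bootstrap_support(sub, reps = 10, seed = 4)
  rt <- read_newick(write_newick(tr))
  expect_equal(rf_dist(tr, rt), 0)
  expect_equal(sort(rt$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(rt$node.label, tr$node.label)

  spaced <- read_newick("('Saurauia tristyla':0.2,(B:0.1,C:0.1):0.05);")
  out <- write_newick(spaced)
  expect_match(out, "'Saurauia tristyla'", fixed = TRUE)
  rt2 <- read_newick(out)
  expect_true("Saurauia tristyla" %in% rt2$tip.label)
})
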