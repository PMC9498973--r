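test_that("identical rows give P = Q = d = 0", {
  p <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(p$P, 0)
  expect_equal(p$Q, 0)
  expect_equal(p$d, 0)
  expect_true(p$defined)
})

test_that("K2P matches the closed form on constructed (P, Q) grids", {
  # build 100-site pairs with nP transitions and nQ transversions
  make_pair <- function(nP, nQ, L = 100) {
    a <- rep("A", L)
    b <- rep("A", L)
    if (nP > 0) b[seq_len(nP)] <- "G"                  # A->G transitions
    if (nQ > 0) b[nP + seq_len(nQ)] <- "T"             # A->T transversions
    list(a = paste0(a, collapse = ""), b = paste0(b, collapse = ""))
  }
  for (nP in c(0, 5, 10, 20)) {
    for (nQ in c(0, 5, 10)) {
      pr <- make_pair(nP, nQ)
      res <- k2p_distance(pr$a, pr$b)
      P <- nP / 100
      Q <- nQ / 100
      expect_equal(res$P, P)
      expect_equal(res$Q, Q)
      expect_equal(res$d, -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
                   info = sprintf("P=%g Q=%g", P, Q))
    }
  }
  # hand-evaluated reference point: P = 0.1, Q = 0.05
  pr <- make_pair(10, 5)
  expect_equal(k2p_distance(pr$a, pr$b)$d, -0.5 * log(0.75 * sqrt(0.90)))
})

test_that("saturation and empty overlap are flagged undefined, not NaN", {
  sat <- k2p_distance(strrep("A", 10), strrep("T", 10))
  expect_false(sat$defined)
  expect_true(is.na(sat$d))

  none <- k2p_distance("----", "ACGT")
  expect_false(none$defined)
  expect_equal(none$L_valid, 0L)
})

test_that("gap/ambiguity columns are deleted pairwise", {
  res <- k2p_distance("ACGT-ACGTN", "ACGTTAC-TA")
  expect_equal(res$L_valid, 7L)
})

test_that("K2P agrees with a 1:2 transition:transversion Jukes-Cantor reduction", {
  for (p in c(0.03, 0.09, 0.3)) {
    L <- 300
    nts <- round(p * L / 3)
    ntv <- 2 * nts
    a <- rep("A", L)
    b <- rep("A", L)
    b[seq_len(nts)] <- "G"
    b[nts + seq_len(ntv)] <- rep(c("C", "T"), length.out = ntv)
    res <- k2p_distance(paste0(a, collapse = ""), paste0(b, collapse = ""))
    pdist <- (nts + ntv) / L
    expect_equal(res$d, -0.75 * log(1 - 4 * pdist / 3), tolerance = 1e-12)
  }
})

test_that("d increases in P at fixed Q and in Q at fixed P", {
  dval <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  Ps <- seq(0, 0.2, by = 0.02)
  expect_true(all(diff(vapply(Ps, dval, numeric(1), Q = 0.05)) > 0))
  Qs <- seq(0, 0.2, by = 0.02)
  expect_true(all(diff(vapply(Qs, function(q) dval(0.05, q), numeric(1))) > 0))
})

test_that("the pairwise matrix is symmetric, zero-diagonal and matches per-pair recomputation", {
  sim <- small_sim(seed = 41)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- aln[1:10, ]
  dm <- pairwise_matrix(sub)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 10))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(dm$d[i, j], oracle_k2p(sub$seq[i], sub$seq[j]),
                   info = sprintf("pair %d-%d", i, j))
    }
  }
})

test_that("ape's K80 distances agree with ours", {
  skip_if_not_installed("ape")
  sim <- small_sim(seed = 42)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  sub <- aln[seq(1, nrow(aln), by = 3), ]
  dm <- pairwise_matrix(sub)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(sub$seq), "")))
  rownames(bin) <- sub$id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(dm$d, ref[rownames(dm$d), colnames(dm$d)], tolerance = 1e-10)
})

test_that("group means: singleton species undefined within, cross pair correct", {
  aln <- tibble::tibble(
    id = c("a1", "b1"),
    seq = c(strrep("A", 100), paste0(strrep("A", 90), strrep("G", 10))),
    species = c("spA", "spB"),
    is_outgroup = FALSE
  )
  dm <- pairwise_matrix(aln)
  gm <- group_means(dm, tibble::tibble(sample_id = aln$id, species = aln$species))
  expect_true(all(is.na(gm$within$mean_d)))
  expect_equal(gm$between$mean_pct,
               round(100 * -0.5 * log((1 - 0.2) * sqrt(1)), 2))
})

test_that("group means equal a brute-force average over pairs", {
  sim <- small_sim(seed = 43)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  h <- collapse_haplotypes(aln)
  reps <- dplyr::transmute(h$haplotypes, id = hap_id, seq = seq)
  dm <- pairwise_matrix(reps)
  gm <- group_means(dm, tibble::tibble(sample_id = h$haplotypes$hap_id,
                                       species = h$haplotypes$species))
  # oracle: direct loop over the tidy pair list
  pairs <- tidy(dm)
  spof <- setNames(h$haplotypes$species, h$haplotypes$hap_id)
  for (s in unique(h$haplotypes$species)) {
    sel <- spof[pairs$id_a] == s & spof[pairs$id_b] == s
    if (sum(sel) > 0) {
      expect_equal(gm$within$mean_d[gm$within$species == s],
                   mean(pairs$d[sel]), info = s)
    }
  }
  s1 <- unique(h$haplotypes$species)[1]
  s2 <- unique(h$haplotypes$species)[2]
  sel <- (spof[pairs$id_a] == s1 & spof[pairs$id_b] == s2) |
    (spof[pairs$id_a] == s2 & spof[pairs$id_b] == s1)
  expect_equal(gm$between$mean_d[gm$between$species_a == s1 &
                                   gm$between$species_b == s2],
               mean(pairs$d[sel]))
})

test_that("frequency weighting shrinks within-species means toward zero", {
  aln <- tibble::tibble(
    id = c("h1", "h2"),
    seq = c(strrep("A", 100), paste0(strrep("A", 98), "GG")),
    species = "spA",
    is_outgroup = FALSE
  )
  dm <- pairwise_matrix(aln)
  meta <- tibble::tibble(sample_id = aln$id, species = aln$species)
  unweighted <- group_means(dm, meta)
  weighted <- group_means(dm, meta, freq = c(h1 = 9, h2 = 1))
  expect_lt(weighted$within$mean_d, unweighted$within$mean_d)
  # 9*1 cross pairs at d plus 36 + 0 identical pairs
  d <- dm$d["h1", "h2"]
  expect_equal(weighted$within$mean_d, 9 * d / (9 + 36 + 0))
})

test_that("barcode gap reports extremes and tolerates negative gaps", {
  s <- list(
    within = tibble::tibble(species = c("A", "B"), n_seqs = 2L, n_pairs = 1L,
                            mean_d = c(0.05, 0.01), mean_pct = c(5, 1)),
    between = tibble::tibble(species_a = "A", species_b = "B",
                             mean_d = 0.03, mean_pct = 3)
  )
  class(s) <- "distance_summary"
  g <- barcode_gap(s)
  expect_equal(g$gap$gap_pct, -2)
  expect_equal(g$gap$max_within_pct, 5)
  expect_equal(g$nearest$nearest_neighbor, c("B", "A"))
})

test_that("simulated K80 pairs recover the true distance (spot check)", {
  L <- 2000
  reps <- 40
  d0 <- 0.05
  ests <- with_seed_local(99, {
    vapply(seq_len(reps), function(r) {
      a <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      b <- evolve_k80(a, d0, kappa = 4)
      k2p_distance(a, b)$d
    }, numeric(1))
  })
  se <- stats::sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests) - d0), 2 * se + 1e-4)
})
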