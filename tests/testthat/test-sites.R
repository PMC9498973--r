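test_that("identical rows have zero variable sites; planted substitutions are counted", {
  aln <- tibble::tibble(id = c("a", "b", "c"), seq = rep("ACGTACGT", 3))
  expect_equal(n_variable_sites(aln), 0L)

  sim <- small_sim(seed = 21)
  aln2 <- align_sequences(join_metadata(sim$seqs, sim$meta))
  expect_equal(n_variable_sites(aln2), sim$truth$n_variable_sites)
})

test_that("site classes are mutually exclusive and flags are set", {
  aln <- tibble::tibble(
    id = paste0("s", 1:4),
    seq = c("AAGA-", "AAGC-", "ACGCN", "ACTC-")
  )
  sr <- classify_sites(aln)
  expect_equal(sr$class, c("invariant", "parsimony_informative", "variable",
                           "variable", "invariant"))
  expect_equal(sr$is_variable, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_true(sr$gap_present[5])
  expect_true(sr$ambiguity_present[5])
  expect_equal(sr$n_A, c(4L, 2L, 0L, 1L, 0L))
})

test_that("variable-site count is invariant to row order and invariant padding", {
  sim <- small_sim(seed = 22)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  n0 <- n_variable_sites(aln)
  with_seed_local(2, perm <- sample(nrow(aln)))
  expect_equal(n_variable_sites(aln[perm, ]), n0)
  padded <- dplyr::mutate(aln, seq = paste0(seq, "AAAA"))
  expect_equal(n_variable_sites(padded), n0)
})

test_that("fixed differences are diagnostic for both species; polymorphism disqualifies", {
  aln <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    seq = c("AAAT", "AAAT", "GAAT", "GAAT"),
    species = c("spA", "spA", "spB", "spB"),
    is_outgroup = FALSE
  )
  k <- diagnostic_sites(aln)
  expect_equal(nrow(k), 2L)
  expect_equal(k$position, c(1L, 1L))
  expect_setequal(k$state[k$species == "spA"], "A")
  expect_setequal(k$state[k$species == "spB"], "G")

  aln$seq[2] <- "CAAT"  # spA now polymorphic at column 1
  k2 <- diagnostic_sites(aln)
  expect_false("spA" %in% k2$species)
  expect_true("spB" %in% k2$species)  # G still fixed in B, absent in A
})

test_that("ambiguity handling is conservative", {
  # spA fixed C; spB carries M = {A,C} which could be C -> site disqualified
  aln <- tibble::tibble(
    id = c("a1", "a2", "b1"),
    seq = c("CAAA", "CAAA", "MAAA"),
    species = c("spA", "spA", "spB"),
    is_outgroup = FALSE
  )
  k <- diagnostic_sites(aln)
  expect_false(any(k$species == "spA" & k$position == 1))

  # ambiguity within the target species disqualifies the position for it
  aln2 <- tibble::tibble(
    id = c("a1", "a2", "b1"),
    seq = c("CAAA", "MAAA", "GAAA"),
    species = c("spA", "spA", "spB"),
    is_outgroup = FALSE
  )
  k2 <- diagnostic_sites(aln2)
  expect_false(any(k2$species == "spA" & k2$position == 1))
})

test_that("gaps are diagnostic states only when allowed by policy", {
  aln <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    seq = c("A-CT", "A-CT", "AGCT", "AGCT"),
    species = c("spA", "spA", "spB", "spB"),
    is_outgroup = FALSE
  )
  k_off <- diagnostic_sites(aln)
  expect_false(any(k_off$species == "spA" & k_off$position == 2))
  # spB's G at the column is still diagnostic (gap in spA is a different state)
  expect_true(any(k_off$species == "spB" & k_off$position == 2 & k_off$state == "G"))

  k_on <- diagnostic_sites(aln, allow_indel_diagnostics = TRUE)
  expect_true(any(k_on$species == "spA" & k_on$position == 2 & k_on$state == "-"))
})

test_that("planted diagnostic sites are recovered exactly from synthetic truth", {
  sim <- small_sim(seed = 23)
  # truth-frame alignment: coordinates are comparable position by position
  aln <- join_metadata(
    dplyr::select(sim$truth$alignment, "id", "seq"), sim$meta
  )
  k <- diagnostic_sites(load_prealigned(aln))
  truth <- sim$truth$diagnostics
  found <- dplyr::inner_join(
    k, truth, by = c("species", "position", "state")
  )
  expect_equal(nrow(found), nrow(truth))  # every planted site recovered

  # de novo MSA frame: every species still shows diagnostic sites carrying
  # the planted states (coordinates may shift with the alignment)
  k2 <- diagnostic_sites(align_sequences(join_metadata(sim$seqs, sim$meta)))
  for (sp in unique(truth$species)) {
    planted_states <- sort(truth$state[truth$species == sp])
    found_states <- k2$state[k2$species == sp]
    expect_true(all(planted_states %in% found_states), info = sp)
  }
})

test_that("diagnostic sets only grow when a species is removed", {
  sim <- small_sim(seed = 24)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  k_full <- diagnostic_sites(aln)
  drop_sp <- unique(aln$species[!aln$is_outgroup])[1]
  k_red <- diagnostic_sites(dplyr::filter(aln, species != drop_sp))
  for (sp in setdiff(unique(k_full$species), drop_sp)) {
    full_sites <- with(dplyr::filter(k_full, species == sp),
                       paste(position, state))
    red_sites <- with(dplyr::filter(k_red, species == sp),
                      paste(position, state))
    expect_true(all(full_sites %in% red_sites), info = sp)
  }
})

test_that("sample identification matches, abstains and errors correctly", {
  sim <- small_sim(seed = 25)
  aln <- align_sequences(join_metadata(sim$seqs, sim$meta))
  k <- diagnostic_sites(aln)
  sp1 <- unique(aln$species[!aln$is_outgroup])[1]
  query <- aln$seq[aln$species == sp1][1]
  res <- identify_sample(query, k)
  expect_equal(res$call, sp1)

  alln <- strrep("N", nchar(query))
  expect_equal(identify_sample(alln, k)$call, "no-call")

  expect_error(identify_sample("ACGT", k), "length")
})
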