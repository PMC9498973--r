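#' Simulation configuration for synthetic barcode datasets
#'
#' Defaults emulate an ITS barcoding study of eight closely related congeners
#' plus one outgroup: ~630 bp sequences structured as ITS1 (245 bp), a
#' conserved 5.8S block (164 bp, evolving at a fraction of the spacer rate)
#' and ITS2 (221 bp); between-species K2P divergence in 2-11%;
#' within-species divergence below ~2.3%; species-private fixed (diagnostic)
#' sites; occasional species-level deletions of 1-12 bp; and rare IUPAC
#' ambiguity codes on haplotype representatives.
#'
#' @param n_species Number of ingroup species (default 8).
#' @param samples_per_species Integer vector of per-species sample counts.
#'   Defaults to the study-sized totals `c(59, 19, 14, 18, 27, 16, 15, 17)`
#'   (185 samples) when `n_species == 8`, else 23 per species.
#' @param haplotypes_per_species Haplotype counts per species. Defaults to
#'   `c(9, 5, 4, 6, 6, 5, 3, 8)` (46 haplotypes) when `n_species == 8`,
#'   else 4 each; must not exceed the sample counts.
#' @param seq_len Sequence length in bp (default 630).
#' @param kappa Transition/transversion rate ratio for K80 evolution
#'   (default 4).
#' @param between_range Range of between-species K2P path lengths
#'   (substitutions/site; default `c(0.0228, 0.11)`, the observed
#'   inter-specific span in ITS barcoding of congeners).
#' @param within_range Per-species maximum within-species divergence is drawn
#'   uniformly from this range (default `c(0.0035, 0.0226)`).
#' @param n_diagnostic_per_species Diagnostic sites implanted per species
#'   (default 7).
#' @param indel_rate Probability that a species lineage carries one 1-12 bp
#'   deletion (default 0.2; deletions are placed in the spacers, never in
#'   5.8S or at diagnostic columns).
#' @param within_indel Also give one haplotype per species a private 1 bp
#'   deletion (default `FALSE`).
#' @param ambiguity_rate Per-site probability of replacing a haplotype base
#'   with a two-base IUPAC code containing it (default 0.002; diagnostic
#'   columns are never touched).
#' @param region_lens Lengths of ITS1, 5.8S, ITS2 (must sum to `seq_len`).
#' @param r58s_rate Rate multiplier for the 5.8S block (default 0.1).
#' @param outgroup_divergence Branch length from the ingroup root to the
#'   outgroup (default 0.25 substitutions/site).
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 8,
                       samples_per_species = NULL,
                       haplotypes_per_species = NULL,
                       seq_len = 630,
                       kappa = 4,
                       between_range = c(0.0228, 0.11),
                       within_range = c(0.0035, 0.0226),
                       n_diagnostic_per_species = 7,
                       indel_rate = 0.2,
                       within_indel = FALSE,
                       ambiguity_rate = 0.002,
                       region_lens = c(245, 164, 221),
                       r58s_rate = 0.1,
                       outgroup_divergence = 0.25,
                       seed) {
  if (missing(seed)) abort("sim_config() requires a seed.")
  if (is.null(samples_per_species)) {
    samples_per_species <- if (n_species == 8) c(59, 19, 14, 18, 27, 16, 15, 17)
                           else rep(23, n_species)
  }
  if (is.null(haplotypes_per_species)) {
    haplotypes_per_species <- if (n_species == 8) c(9, 5, 4, 6, 6, 5, 3, 8)
                              else rep(4, n_species)
  }
  samples_per_species <- rep_len(samples_per_species, n_species)
  haplotypes_per_species <- rep_len(haplotypes_per_species, n_species)
  haplotypes_per_species <- pmin(haplotypes_per_species, samples_per_species)
  if (sum(region_lens) != seq_len) {
    abort("`region_lens` must sum to `seq_len`.")
  }
  if (any(c(indel_rate, ambiguity_rate) < 0) || kappa <= 0 ||
      outgroup_divergence < 0) {
    abort("Rates must be non-negative and kappa positive.")
  }
  if (max(within_range) >= min(between_range)) {
    warn("within_range overlaps between_range: no barcoding gap is guaranteed.")
  }
  structure(
    list(
      n_species = n_species,
      samples_per_species = samples_per_species,
      haplotypes_per_species = haplotypes_per_species,
      seq_len = as.integer(seq_len),
      kappa = kappa,
      between_range = between_range,
      within_range = within_range,
      n_diagnostic_per_species = n_diagnostic_per_species,
      indel_rate = indel_rate,
      within_indel = within_indel,
      ambiguity_rate = ambiguity_rate,
      region_lens = as.integer(region_lens),
      r58s_rate = r58s_rate,
      outgroup_divergence = outgroup_divergence,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Evolve a sequence under K80
#'
#' Per-site substitution using the exact K80 transition probabilities
#' `P(i -> j | t, kappa)`; sequence length is preserved. Sites with a rate
#' multiplier evolve on an effectively scaled branch.
#'
#' @param seq A sequence string over A,C,G,T.
#' @param branch_length Branch length in expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param site_rates Optional per-site rate multipliers (default 1).
#' @return The evolved sequence string.
#' @export
evolve_k80 <- function(seq, branch_length, kappa = 4, site_rates = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste0(evolve_chars(chars, branch_length, kappa, site_rates), collapse = "")
}

evolve_chars <- function(chars, branch_length, kappa, site_rates = NULL) {
  if (branch_length < 0) abort("Branch length must be non-negative.")
  if (branch_length == 0) return(chars)
  bases <- c("A", "C", "G", "T")
  if (is.null(site_rates)) site_rates <- rep(1, length(chars))
  out <- chars
  for (rate in sort(unique(site_rates))) {
    t_eff <- branch_length * rate
    if (t_eff == 0) next
    P <- k80_pmatrix(t_eff, kappa)
    for (b in bases) {
      idx <- which(chars == b & site_rates == rate)
      if (length(idx) == 0) next
      out[idx] <- sample(bases, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

# IUPAC code for a two-base set
two_base_code <- function(b1, b2) {
  set <- sort(c(b1, b2))
  names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) identical(sort(s), set), logical(1))]
}

#' Simulate a synthetic barcoding dataset with ground truth
#'
#' Draws a pure-birth species tree rescaled so between-species path lengths
#' span the configured range, evolves a uniform-random root sequence along it
#' under K80 (the 5.8S block at a reduced rate), implants per-species fixed
#' diagnostic substitutions at distinct invariant columns, derives
#' within-species haplotypes as few-mutation derivatives of each species
#' consensus, assigns samples to haplotypes (dominant haplotype plus
#' singletons, as in field barcoding datasets), and optionally sprinkles
#' species-level deletions and IUPAC ambiguity codes. The outgroup evolves on
#' a long basal branch. Deterministic per seed: the same config yields a
#' byte-identical dataset.
#'
#' @param config A [sim_config()].
#' @return A `barcode_sim` list: `seqs` (ungapped sequence table), `meta`
#'   (metadata table), and `truth` with the true alignment, species tree
#'   (`phylo`), species-level pairwise distances, haplotype membership,
#'   diagnostic `(species, position, state)` sets, variable-site count, and
#'   the config.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  ns <- cfg$n_species
  L <- cfg$seq_len
  bases <- c("A", "C", "G", "T")
  if (ns > 26) abort("At most 26 ingroup species are supported.")
  species <- sprintf("species_%s", LETTERS[seq_len(ns)])
  outgroup <- "outgroup"

  # --- species tree, rescaled into the between-species divergence range ---
  if (ns >= 3) {
    tr <- ape::rphylo(ns, birth = 1, death = 0)
    tr$tip.label <- species
    D <- ape::cophenetic.phylo(tr)[species, species]
    dmin <- min(D[upper.tri(D)])
    dmax <- max(D[upper.tri(D)])
    lo <- cfg$between_range[1]
    hi <- cfg$between_range[2]
    if (dmax > dmin) {
      s <- (hi - lo) / (dmax - dmin)
      cst <- (lo - dmin * s) / 2
      if (cst < 0) {
        s <- hi / dmax
        cst <- 0
      }
    } else {
      s <- hi / dmax
      cst <- 0
    }
    tr$edge.length <- tr$edge.length * s
    term <- tr$edge[, 2] <= ns
    tr$edge.length[term] <- tr$edge.length[term] + cst
  } else {
    d <- mean(cfg$between_range)
    nwk <- if (ns == 2) {
      sprintf("(%s:%f,%s:%f);", species[1], d / 2, species[2], d / 2)
    } else {
      sprintf("(%s:0);", species[1])
    }
    tr <- ape::read.tree(text = nwk)
  }

  # --- evolve consensus sequences down the tree ---
  site_rates <- rep(1, L)
  r58s_cols <- (cfg$region_lens[1] + 1):(cfg$region_lens[1] + cfg$region_lens[2])
  site_rates[r58s_cols] <- cfg$r58s_rate
  root_seq <- sample(bases, L, replace = TRUE)

  node_seq <- vector("list", ns + max(1L, tr$Nnode))
  st <- tree_structure(tr)
  node_seq[[st$root]] <- root_seq
  for (node in rev(st$postorder)) {
    for (ch in st$children[[node]]) {
      t_ch <- tr$edge.length[st$edge_of[ch]]
      node_seq[[ch]] <- evolve_chars(node_seq[[node]], t_ch, cfg$kappa, site_rates)
    }
  }
  consensus <- lapply(seq_len(ns), function(i) node_seq[[i]])
  names(consensus) <- tr$tip.label[seq_len(ns)]
  consensus <- consensus[species]
  out_seq <- evolve_chars(root_seq, cfg$outgroup_divergence, cfg$kappa, site_rates)

  # --- implant species-private diagnostic sites at invariant columns ---
  cons_mat <- do.call(rbind, consensus)
  invariant <- which(apply(cons_mat, 2, function(col) length(unique(col)) == 1) &
                       out_seq == cons_mat[1, ] &
                       site_rates == 1)
  need <- ns * cfg$n_diagnostic_per_species
  if (length(invariant) < need) {
    abort(sprintf(
      "Requested %d diagnostic sites but only %d invariant columns available.",
      need, length(invariant)
    ))
  }
  diag_cols <- sample(invariant, need)
  diagnostics <- tibble(
    species = rep(species, each = cfg$n_diagnostic_per_species),
    position = as.integer(diag_cols),
    state = NA_character_
  )
  for (k in seq_len(need)) {
    sp_i <- match(diagnostics$species[k], species)
    pos <- diagnostics$position[k]
    old <- consensus[[sp_i]][pos]
    new <- sample(setdiff(bases, old), 1)
    consensus[[sp_i]][pos] <- new
    diagnostics$state[k] <- new
  }

  # --- species-level deletions (spacers only, never at diagnostic columns) ---
  deleted <- vector("list", ns)
  protected <- union(diagnostics$position, r58s_cols)
  for (i in seq_len(ns)) {
    deleted[[i]] <- integer(0)
    if (runif(1) < cfg$indel_rate) {
      len <- sample.int(12, 1)
      for (attempt in 1:50) {
        start <- sample.int(L - len + 1, 1)
        run <- start:(start + len - 1)
        if (!any(run %in% protected)) {
          deleted[[i]] <- run
          break
        }
      }
    }
  }

  # --- within-species haplotypes ---
  hap_rows <- list()
  membership <- list()
  sample_rows <- list()
  for (i in seq_len(ns)) {
    h <- cfg$haplotypes_per_species[i]
    n_i <- cfg$samples_per_species[i]
    within_target <- runif(1, cfg$within_range[1], cfg$within_range[2])
    max_m <- max(1L, floor(within_target * L / 2))
    free_cols <- setdiff(seq_len(L), c(protected, deleted[[i]]))
    haps <- vector("list", h)
    haps[[1]] <- consensus[[i]]
    seen <- paste0(consensus[[i]], collapse = "")
    for (k in seq_len(h)[-1]) {
      repeat {
        m_k <- sample.int(max_m, 1)
        cols <- sample(free_cols, m_k)
        cand <- consensus[[i]]
        for (cc in cols) cand[cc] <- sample(setdiff(bases, cand[cc]), 1)
        kk <- paste0(cand, collapse = "")
        if (!kk %in% seen) {
          seen <- c(seen, kk)
          haps[[k]] <- cand
          break
        }
      }
    }
    # optional private 1 bp deletion on the second haplotype
    hap_del <- vector("list", h)
    for (k in seq_len(h)) hap_del[[k]] <- deleted[[i]]
    if (cfg$within_indel && h >= 2) {
      pos1 <- sample(setdiff(free_cols, deleted[[i]]), 1)
      hap_del[[2]] <- sort(c(hap_del[[2]], pos1))
    }
    # rare ambiguity codes on non-dominant haplotypes
    if (cfg$ambiguity_rate > 0) {
      for (k in seq_len(h)[-1]) {
        amb_cols <- setdiff(which(runif(L) < cfg$ambiguity_rate),
                            c(protected, hap_del[[k]]))
        for (cc in amb_cols) {
          partner <- sample(setdiff(bases, haps[[k]][cc]), 1)
          haps[[k]][cc] <- two_base_code(haps[[k]][cc], partner)
        }
      }
    }
    aligned_haps <- vapply(seq_len(h), function(k) {
      x <- haps[[k]]
      x[hap_del[[k]]] <- "-"
      paste0(x, collapse = "")
    }, character(1))
    hap_ids <- sprintf("%s_h%d", species[i], seq_len(h))
    hap_rows[[i]] <- tibble(hap_id = hap_ids, species = species[i],
                            seq_aligned = aligned_haps)
    # dominant haplotype + singletons
    counts <- c(n_i - (h - 1L), rep(1L, h - 1L))
    assign <- rep(seq_len(h), counts)
    ids <- sprintf("%s_s%02d", species[i], seq_len(n_i))
    membership[[i]] <- tibble(sample_id = ids, species = species[i],
                              hap_id = hap_ids[assign])
    sample_rows[[i]] <- tibble(
      id = ids,
      seq = ungap(aligned_haps[assign]),
      species = species[i],
      locality = ifelse(seq_len(n_i) <= ceiling(n_i / 2), "site_north", "site_south"),
      accession = "",
      is_outgroup = FALSE
    )
  }

  out_row <- tibble(
    id = "outgroup_s01",
    seq = paste0(out_seq, collapse = ""),
    species = outgroup,
    locality = "",
    accession = "",
    is_outgroup = TRUE
  )
  samples <- dplyr::bind_rows(c(sample_rows, list(out_row)))
  meta <- dplyr::transmute(samples, sample_id = .data$id, species = .data$species,
                           locality = .data$locality, accession = .data$accession,
                           is_outgroup = .data$is_outgroup)
  seqs <- dplyr::select(samples, "id", "seq")

  # --- ground truth ---
  hap_tbl <- dplyr::bind_rows(hap_rows)
  member_tbl <- dplyr::bind_rows(membership)
  truth_aln <- dplyr::left_join(member_tbl, hap_tbl, by = c("hap_id", "species")) |>
    dplyr::transmute(id = .data$sample_id, seq = .data$seq_aligned,
                     species = .data$species)
  truth_aln <- dplyr::bind_rows(
    truth_aln,
    tibble(id = out_row$id, seq = out_row$seq, species = outgroup)
  )
  # variable columns among ingroup rows of the truth alignment (>= 2 bases)
  tm <- do.call(rbind, strsplit(truth_aln$seq[truth_aln$species != outgroup], ""))
  n_var <- sum(apply(tm, 2, function(col) {
    length(unique(col[col %in% bases])) >= 2
  }))

  # full true tree including the outgroup on its basal branch
  inner <- sub(";$", "", write_newick(tr))
  full_tree <- ape::read.tree(text = sprintf(
    "(%s,%s:%f);", inner, outgroup, cfg$outgroup_divergence
  ))
  D_true <- ape::cophenetic.phylo(tr)[species, species]

  structure(
    list(
      seqs = seqs,
      meta = meta,
      truth = list(
        alignment = truth_aln,
        tree = full_tree,
        species_tree = tr,
        distances = D_true,
        haplotypes = hap_tbl,
        membership = member_tbl,
        diagnostics = dplyr::arrange(diagnostics, .data$species, .data$position),
        n_variable_sites = n_var,
        config = cfg
      )
    ),
    class = "barcode_sim"
  )
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat(sprintf(
    "<barcode_sim> %d samples, %d species + outgroup, %d bp, seed %d\n",
    nrow(x$truth$membership), x$truth$config$n_species,
    x$truth$config$seq_len, x$truth$config$seed
  ))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `seqs.fasta`, `meta.tsv`, `tree.nwk` (true tree) and `truth.json`.
#'
#' @param sim A `barcode_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$seqs, file.path(dir, "seqs.fasta"))
  readr::write_tsv(
    dplyr::mutate(sim$meta, is_outgroup = as.integer(.data$is_outgroup)),
    file.path(dir, "meta.tsv")
  )
  write_newick(sim$truth$tree, file.path(dir, "tree.nwk"))
  truth <- list(
    alignment = sim$truth$alignment,
    distances = sim$truth$distances,
    haplotypes = sim$truth$haplotypes,
    membership = sim$truth$membership,
    diagnostics = sim$truth$diagnostics,
    n_variable_sites = sim$truth$n_variable_sites
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", matrix = "rowmajor", digits = NA)
  invisible(dir)
}
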