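#' Run the full barcoding analysis
#'
#' One-command end-to-end analysis of a FASTA + metadata pair: master
#' alignment, region statistics, haplotype collapsing, variable/diagnostic
#' sites, K2P distance structure, and bootstrapped trees (whole ITS plus the
#' ITS1-only and ITS2-only column slices) with species-monophyly assessment.
#' Every stage output is written to `out_dir` under a fixed name (written via
#' a `.partial` temporary that is renamed on success, so an aborted run
#' leaves its failed stage marked). All randomness flows from `seed`.
#'
#' Output files: `aligned.fasta`, `regions.tsv`, `haplotypes.tsv`,
#' `haplotype_seqs.fasta`, `sites.tsv`, `key.json`, `matrix.tsv`,
#' `matrix.phy`, `within.tsv`, `between.tsv`, `tree_<region>.nwk`,
#' `monophyly.tsv`, `run_log.txt`.
#'
#' @param fasta Path to a FASTA file, or a sequence table.
#' @param meta Path to a metadata TSV, or a metadata table.
#' @param out_dir Output directory (created if needed).
#' @param prealigned Treat input rows as already aligned.
#' @param boundaries Optional [region_boundaries()]; inferred via
#'   [infer_58s_window()] when `NULL`.
#' @param bootstrap_reps Bootstrap replicates per tree (default 1000; 0 skips
#'   supports).
#' @param seed Integer seed for bootstrapping.
#' @param method Tree builder, `"nj"` or `"ml"`.
#' @param regions Which column slices to build trees for (subset of
#'   `c("its", "its1", "its2")`).
#' @param freq_weighted Weight group distance means by sample frequencies
#'   instead of treating each haplotype once.
#' @return A `barcode_run` list with every stage's tibble/object and
#'   `out_dir`.
#' @export
run_full_analysis <- function(fasta, meta, out_dir,
                              prealigned = FALSE,
                              boundaries = NULL,
                              bootstrap_reps = 1000,
                              seed = 1,
                              method = c("nj", "ml"),
                              regions = c("its", "its1", "its2"),
                              freq_weighted = FALSE) {
  method <- match.arg(method)
  if (bootstrap_reps < 0) abort("bootstrap_reps must be >= 0.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  emit <- function(writer, path) {
    tmp <- paste0(path, ".partial")
    writer(tmp)
    file.rename(tmp, path)
    path
  }
  emit_tsv <- function(df, name) {
    emit(function(p) readr::write_tsv(df, p), file.path(out_dir, name))
  }

  log_lines <- c(
    "barcodekit run",
    sprintf("  seed: %d", seed),
    sprintf("  method: %s", method),
    sprintf("  bootstrap_reps: %d", bootstrap_reps),
    sprintf("  prealigned: %s", prealigned),
    sprintf("  freq_weighted: %s", freq_weighted)
  )

  seqs <- stage("read", {
    s <- if (is.character(fasta)) read_fasta(fasta) else as_seq_tbl(fasta)
    m <- if (is.character(meta)) read_metadata(meta) else meta
    join_metadata(s, m)
  })

  aln <- stage("align", align_sequences(seqs, prealigned = prealigned))
  stage("align", emit(function(p) write_fasta(aln, p), file.path(out_dir, "aligned.fasta")))
  log_lines <- c(log_lines, sprintf("  alignment: %d rows x %d columns",
                                    nrow(aln), nchar(aln$seq[1])))

  bounds <- stage("regions", {
    b <- if (is.null(boundaries)) infer_58s_window(aln) else boundaries
    emit_tsv(region_stats(aln, b), "regions.tsv")
    b
  })
  reg_stats <- region_stats(aln, bounds)

  haps <- stage("haplotypes", {
    h <- collapse_haplotypes(aln)
    emit_tsv(
      dplyr::mutate(tidy(h),
                    members = vapply(.data$members, paste, character(1),
                                     collapse = ",")) |>
        dplyr::select(-"seq"),
      "haplotypes.tsv"
    )
    emit(function(p) {
      write_fasta(dplyr::transmute(h$haplotypes, id = .data$hap_id, seq = .data$seq), p)
    }, file.path(out_dir, "haplotype_seqs.fasta"))
    h
  })

  site_report <- stage("sites", {
    sr <- classify_sites(aln)
    emit_tsv(sr, "sites.tsv")
    sr
  })
  key <- stage("sites", {
    k <- diagnostic_sites(aln)
    emit(function(p) {
      obj <- lapply(split(k, k$species), function(df) {
        data.frame(pos = df$position, state = df$state)
      })
      jsonlite::write_json(obj, p, dataframe = "rows", auto_unbox = TRUE)
    }, file.path(out_dir, "key.json"))
    k
  })

  # distance structure over unique ingroup haplotypes
  hap_seqs <- dplyr::transmute(haps$haplotypes, id = .data$hap_id, seq = .data$seq)
  hap_meta <- tibble(
    sample_id = haps$haplotypes$hap_id,
    species = haps$haplotypes$species,
    is_outgroup = FALSE
  )
  dist_summary <- stage("distances", {
    dm <- pairwise_matrix(hap_seqs)
    emit_tsv(tidy(dm), "matrix.tsv")
    emit(function(p) {
      con <- file(p, "w")
      on.exit(close(con))
      writeLines(sprintf("%5d", length(dm$labels)), con)
      for (i in seq_along(dm$labels)) {
        writeLines(paste0(formatC(dm$labels[i], width = -12),
                          paste(sprintf("%.8f", dm$d[i, ]), collapse = "  ")), con)
      }
    }, file.path(out_dir, "matrix.phy"))
    freq <- NULL
    if (freq_weighted) {
      freq <- setNames(haps$haplotypes$n_samples, haps$haplotypes$hap_id)
    }
    gm <- group_means(dm, hap_meta, freq = freq)
    emit_tsv(gm$within, "within.tsv")
    emit_tsv(gm$between, "between.tsv")
    gm
  })
  gap_report <- stage("distances", barcode_gap(dist_summary))

  # trees on haplotype representatives plus (deduplicated) outgroup rows
  og_rows <- aln[aln$is_outgroup, , drop = FALSE]
  tree_tbl <- dplyr::bind_rows(
    dplyr::mutate(hap_seqs, species = haps$haplotypes$species),
    dplyr::transmute(og_rows[!duplicated(og_rows$seq), ],
                     id = .data$id, seq = .data$seq, species = .data$species)
  )
  tree_meta <- tibble(sample_id = tree_tbl$id, species = tree_tbl$species)
  outgroup_species <- unique(og_rows$species)
  if (length(outgroup_species) == 0) {
    abort("Stage 'trees' failed: no outgroup flagged in the metadata.")
  }

  region_cols <- list(
    its = seq_len(nchar(aln$seq[1])),
    its1 = {
      b <- bounds[bounds$region == "ITS1", ]
      if (b$start <= b$end) seq.int(b$start, b$end) else integer(0)
    },
    its2 = {
      b <- bounds[bounds$region == "ITS2", ]
      if (b$start <= b$end) seq.int(b$start, b$end) else integer(0)
    }
  )
  m_tree <- aln_matrix(tree_tbl)
  trees <- list()
  monophyly <- list()
  for (rg in regions) {
    res <- stage(paste0("tree_", rg), {
      cols <- region_cols[[rg]]
      sub <- matrix_to_seq_tbl(m_tree[, cols, drop = FALSE])
      tr <- if (bootstrap_reps > 0) {
        bootstrap_support(sub, builder = method, reps = bootstrap_reps, seed = seed)
      } else if (method == "nj") {
        neighbor_joining(pairwise_matrix(sub))
      } else {
        ml_search(sub)$tree
      }
      rooted <- root_and_monophyly(tr, tree_meta, outgroup_species)
      emit(function(p) write_newick(rooted$tree, p),
           file.path(out_dir, sprintf("tree_%s.nwk", rg)))
      rooted
    })
    trees[[rg]] <- res$tree
    monophyly[[rg]] <- dplyr::mutate(res$monophyly, region = rg, .before = 1)
  }
  mono_tbl <- dplyr::bind_rows(monophyly)
  emit_tsv(mono_tbl, "monophyly.tsv")

  log_lines <- c(
    log_lines,
    sprintf("  haplotypes: %d in %d samples", nrow(haps$haplotypes),
            nrow(haps$membership)),
    sprintf("  variable sites: %d", sum(site_report$is_variable)),
    sprintf("  diagnostic sites: %d across %d species", nrow(key),
            length(unique(key$species))),
    sprintf("  barcode gap: max within %.2f%%, min between %.2f%%",
            gap_report$gap$max_within_pct, gap_report$gap$min_between_pct)
  )
  emit(function(p) writeLines(log_lines, p), file.path(out_dir, "run_log.txt"))

  structure(
    list(
      alignment = aln,
      boundaries = bounds,
      region_stats = reg_stats,
      haplotypes = haps,
      site_report = site_report,
      diagnostic_key = key,
      distance_summary = dist_summary,
      barcode_gap = gap_report,
      trees = trees,
      monophyly = mono_tbl,
      out_dir = out_dir,
      seed = seed
    ),
    class = "barcode_run"
  )
}

#' @export
print.barcode_run <- function(x, ...) {
  cat("<barcode_run>\n")
  cat(sprintf("  %d aligned rows, %d haplotypes, %d variable sites\n",
              nrow(x$alignment), nrow(x$haplotypes$haplotypes),
              sum(x$site_report$is_variable)))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

#' @describeIn run_full_analysis One-row summary of the run's headline numbers.
#' @param x A `barcode_run`.
#' @param ... Unused.
#' @export
glance.barcode_run <- function(x, ...) {
  mono_its <- x$monophyly[x$monophyly$region == "its", ]
  tibble(
    n_samples = nrow(x$haplotypes$membership),
    n_haplotypes = nrow(x$haplotypes$haplotypes),
    n_variable_sites = sum(x$site_report$is_variable),
    n_species_with_diagnostics = length(unique(x$diagnostic_key$species)),
    max_within_pct = x$barcode_gap$gap$max_within_pct,
    min_between_pct = x$barcode_gap$gap$min_between_pct,
    max_between_pct = x$barcode_gap$gap$max_between_pct,
    n_monophyletic = sum(mono_its$monophyletic),
    n_species = nrow(mono_its)
  )
}

#' Plot per-region species discriminability
#'
#' Tile plot of the monophyly table: which species are recovered as clades in
#' trees built from the whole ITS versus the ITS1/ITS2 slices.
#'
#' @param object A `barcode_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barcode_run <- function(object, ...) {
  df <- object$monophyly
  ggplot2::ggplot(df, ggplot2::aes(x = toupper(.data$region), y = .data$species,
                                   fill = .data$monophyletic)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f0e")) +
    ggplot2::labs(x = "Region", y = NULL, fill = "Monophyletic",
                  title = "Species discrimination by barcode region")
}
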