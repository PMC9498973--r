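#' Load the published Actinidia ITS survey dataset
#'
#' Expands the 46 ingroup ITS haplotypes (plus the *Saurauia tristyla*
#' outgroup) of the published *Actinidia* barcoding survey into its full
#' 185-sample dataset, using the haplotype-frequency table shipped with the
#' package. The haplotype sequences themselves are GenBank records and are
#' not redistributed: fetch them once with
#' `inst/scripts/fetch_accessions.R` (network required), which caches a FASTA
#' keyed by accession.
#'
#' @param fasta Path to the accession-keyed FASTA produced by the fetch
#'   script.
#' @param counts Path to the haplotype-frequency TSV (default: the copy
#'   shipped in `extdata`), with columns `hap_id`, `species`, `n_samples`,
#'   `accession`.
#' @return A list with `seqs` (one row per sample) and `meta` (matching
#'   metadata, outgroup flagged), ready for [run_full_analysis()].
#' @export
load_published_dataset <- function(fasta,
                                   counts = system.file(
                                     "extdata", "actinidia_haplotype_counts.tsv",
                                     package = "barcodekit"
                                   )) {
  tab <- readr::read_tsv(counts, col_types = readr::cols(
    hap_id = readr::col_character(),
    species = readr::col_character(),
    n_samples = readr::col_integer(),
    accession = readr::col_character()
  ))
  seqs <- read_fasta(fasta)
  missing <- setdiff(tab$accession, seqs$id)
  if (length(missing) > 0) {
    abort(sprintf("Accession(s) absent from the FASTA: %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  seq_of <- setNames(seqs$seq, seqs$id)
  expanded <- tab[rep(seq_len(nrow(tab)), tab$n_samples), ]
  expanded$sample_id <- paste0(
    expanded$hap_id, "_",
    unlist(lapply(tab$n_samples, seq_len))
  )
  list(
    seqs = tibble(id = expanded$sample_id,
                  seq = unname(seq_of[expanded$accession])),
    meta = tibble(
      sample_id = expanded$sample_id,
      species = expanded$species,
      locality = "",
      accession = expanded$accession,
      is_outgroup = expanded$species == "Saurauia tristyla"
    )
  )
}
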