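#' Summaries of externally deposited haplotype data
#'
#' Helpers for cross-checking the package against study-deposited records,
#' which are not bundled (they require network access to fetch): the
#' IIS6/IIIS6 haplotype sequences in GenBank (accessions MN602753-MN602778
#' and MN602779-MN602796, from SRA project PRJNA579141) and per-population
#' haplotype frequency tables distributed as supplementary material.
#'
#' `deposited_record_summary()` reads a FASTA of deposited haplotypes and
#' reports the record count and length range.
#' `supplementary_frequency_summary()` reads a per-population haplotype
#' frequency TSV (columns `population_id`, `segment_id`, `haplotype_name`,
#' `frequency`, optionally `continent`) and reports, per segment, how many
#' populations carry each haplotype, which haplotypes are private to a
#' single population, and the continents those private alleles occur on.
#'
#' @param fasta Path to a FASTA file of deposited haplotypes.
#' @param tsv Path to a haplotype-frequency TSV.
#' @return `deposited_record_summary()`: list with `n_records`,
#'   `min_length`, `max_length`.  `supplementary_frequency_summary()`:
#'   list with `populations_per_haplotype` (named integer vector per
#'   segment), `private_alleles` (named list of haplotype names per
#'   segment) and `private_allele_continents`.
#' @export
deposited_record_summary <- function(fasta) {
  seqs <- read_fasta(fasta)
  list(n_records = length(seqs),
       min_length = min(nchar(seqs)),
       max_length = max(nchar(seqs)))
}

#' @rdname deposited_record_summary
#' @export
supplementary_frequency_summary <- function(tsv) {
  df <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("population_id", "segment_id", "haplotype_name", "frequency")
  if (!all(need %in% names(df)))
    stop("frequency file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- list(populations_per_haplotype = list(), private_alleles = list(),
              private_allele_continents = list())
  for (seg in sort(unique(df$segment_id))) {
    sub <- df[df$segment_id == seg & df$frequency > 0, , drop = FALSE]
    npop <- tapply(sub$population_id, sub$haplotype_name,
                   function(x) length(unique(x)))
    out$populations_per_haplotype[[seg]] <-
      setNames(as.integer(npop), names(npop))
    priv <- names(npop)[npop == 1]
    out$private_alleles[[seg]] <- priv
    if ("continent" %in% names(sub) && length(priv)) {
      out$private_allele_continents[[seg]] <- setNames(
        vapply(priv, function(h)
          unique(sub$continent[sub$haplotype_name == h])[1], ""), priv)
    }
  }
  out
}
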