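#' Sequencing error model for simulated pooled reads
#'
#' A flat per-base error model shaped like Ion Torrent data: uniform
#' substitutions, rarer indels, and an elevated indel rate inside
#' homopolymer runs of three or more identical bases (the platform's
#' dominant artefact).  Base qualities are written as a flat Phred score.
#'
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability outside homopolymers.
#' @param homopolymer_multiplier Factor applied to `indel_rate` at bases
#'   inside homopolymer runs of length >= 3.  Must be >= 1.
#' @param quality_mean Phred score written for every base (Sanger +33).
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.005, indel_rate = 0.001,
                        homopolymer_multiplier = 6, quality_mean = 30L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2,
            homopolymer_multiplier >= 1)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 homopolymer_multiplier = homopolymer_multiplier,
                 quality_mean = as.integer(quality_mean)),
            class = "error_model")
}

#' Configuration of one pooled population sample
#'
#' Describes one population pool: its metadata, its true per-segment
#' haplotype frequencies, the barcode ligated to its library, and how many
#' reads to simulate per segment.  Frequencies must each sum to 1.
#'
#' @param population_id,country,continent Population metadata strings.
#' @param year Collection year.
#' @param barcode Barcode sequence (uppercase A/C/G/T).
#' @param iis6,iiis6 Named numeric vectors of true haplotype frequencies
#'   (names are panel haplotype names), each summing to 1.
#' @param reads_per_segment Reads to simulate for each segment.
#' @return An object of class `population_config`.
#' @export
population_config <- function(population_id, country, continent, year,
                              barcode, iis6, iiis6,
                              reads_per_segment = 2000L) {
  stopifnot(grepl("^[ACGT]+$", barcode), reads_per_segment >= 1)
  for (f in list(iis6, iiis6)) {
    stopifnot(length(f) >= 1, !is.null(names(f)), all(f > 0))
    if (abs(sum(f) - 1) > 1e-9) stop("segment frequencies must sum to 1")
  }
  structure(list(population_id = population_id, country = country,
                 continent = continent, year = as.integer(year),
                 barcode = barcode,
                 frequencies = list(IIS6 = iis6, IIIS6 = iiis6),
                 reads_per_segment = as.integer(reads_per_segment)),
            class = "population_config")
}

# Per-position indel-rate multiplier: elevated inside homopolymer runs >= 3.
.hp_multiplier <- function(seq, mult) {
  ch <- strsplit(seq, "")[[1]]
  r <- rle(ch)
  rep(ifelse(r$lengths >= 3, mult, 1), r$lengths)
}

# Apply the error model to a single read (character vector of bases).
.mutate_read <- function(ch, hp_mult, em) {
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  sub_at <- which(runif(n) < em$substitution_rate)
  for (i in sub_at) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
  ind_at <- which(runif(n) < em$indel_rate * hp_mult)
  if (length(ind_at)) {
    # process right-to-left so positions stay valid
    for (i in rev(ind_at)) {
      if (runif(1) < 0.5) {                       # deletion
        ch <- ch[-i]
      } else {                                    # insertion (duplicate base)
        ch <- append(ch, ch[i], after = i)
      }
    }
  }
  ch
}

#' Simulate one population's pooled amplicon reads
#'
#' Draws each segment's reads from the configured haplotype frequencies
#' (multinomial), prefixes the barcode, and applies the error model across
#' the whole read (barcode included).  Reads are single-end, full-length,
#' forward-oriented.  Output is byte-reproducible for a fixed
#' `(config, error_model, seed)`.
#'
#' @param config A [population_config()].
#' @param panel Result of [build_default_panel()] (or same structure).
#' @param em An [error_model()].
#' @param seed Integer seed; every call uses its own private RNG stream.
#' @return A data frame with columns `id`, `sequence`, `quality` (class
#'   `read_set`).
#' @export
simulate_pool <- function(config, panel, em = error_model(), seed) {
  stopifnot(inherits(config, "population_config"), !missing(seed))
  seqs <- setNames(panel$haplotypes$sequence, panel$haplotypes$name)
  segs <- setNames(panel$haplotypes$segment_id, panel$haplotypes$name)
  .with_seed(seed, {
    out <- list()
    for (seg in c("IIS6", "IIIS6")) {
      freqs <- config$frequencies[[seg]]
      unknown <- setdiff(names(freqs), names(seqs))
      if (length(unknown))
        stop("unknown haplotype name(s): ", paste(unknown, collapse = ", "))
      if (any(segs[names(freqs)] != seg))
        stop("haplotype assigned to the wrong segment in config")
      n <- config$reads_per_segment
      counts <- as.vector(rmultinom(1, n, freqs))
      origin <- rep(names(freqs), counts)
      reads <- character(n)
      for (j in seq_len(n)) {
        full <- paste0(config$barcode, seqs[[origin[j]]])
        ch <- strsplit(full, "")[[1]]
        if (em$substitution_rate > 0 || em$indel_rate > 0) {
          hp <- .hp_multiplier(full, em$homopolymer_multiplier)
          ch <- .mutate_read(ch, hp, em)
        }
        reads[j] <- paste(ch, collapse = "")
      }
      out[[seg]] <- data.frame(
        id = sprintf("%s_%s_%05d", config$population_id, seg, seq_len(n)),
        sequence = reads,
        quality = vapply(nchar(reads), function(L)
          strrep(rawToChar(as.raw(em$quality_mean + 33L)), L), ""),
        stringsAsFactors = FALSE)
    }
    res <- rbind(out$IIS6, out$IIIS6)
    class(res) <- c("read_set", "data.frame")
    res
  })
}

#' Write / read a barcode manifest
#'
#' The manifest is a TSV with columns `barcode`, `population_id`,
#' `country`, `continent`, `year`, one row per population.  Barcodes must
#' be unique; [read_manifest()] restores the table losslessly.
#'
#' @param configs List of [population_config()] objects.
#' @param path Output TSV path.
#' @return `write_manifest()` returns the manifest data frame invisibly;
#'   `read_manifest()` returns the data frame.
#' @export
write_manifest <- function(configs, path) {
  df <- do.call(rbind, lapply(configs, function(cf)
    data.frame(barcode = cf$barcode, population_id = cf$population_id,
               country = cf$country, continent = cf$continent,
               year = cf$year, stringsAsFactors = FALSE)))
  if (anyDuplicated(df$barcode)) stop("duplicate barcode in manifest")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character", "integer"))
  need <- c("barcode", "population_id", "country", "continent", "year")
  if (!all(need %in% names(df)))
    stop("manifest missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$barcode)) stop("duplicate barcode in manifest")
  df
}

#' Default barcode set
#'
#' Twelve 8-mer barcodes with pairwise Hamming distance >= 3, so
#' single-mismatch demultiplexing is unambiguous.
#'
#' @param n Number of barcodes (max 12).
#' @return Character vector of barcodes.
#' @export
default_barcodes <- function(n = 12L) {
  bc <- c("AACCGGTT", "ACGTACGT", "AGTCCATG", "ATACTGCA",
          "CAAGTCAC", "CCTAGAGT", "CGCATTGA", "CTGGACTA",
          "GATCGTTC", "GGAATCCG", "GTTCAAGC", "TCGAGCAT")
  if (n > length(bc)) stop("at most ", length(bc), " packaged barcodes")
  bc[seq_len(n)]
}
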