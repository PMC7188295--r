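#' Parameters of the haplotype caller
#'
#' Defaults reflect pools of roughly 30 diploid individuals: the lowest
#' real allele frequency in such a pool is about 1/60, so the reporting
#' floor (0.01) sits safely below it, while the abundance ratio (20) keeps
#' sequencing-error shoulders from surviving as calls.
#'
#' @param barcode_max_mismatch Mismatches tolerated when matching barcodes
#'   (0-2).
#' @param length_window Two-element numeric, post-trim read length bounds.
#' @param min_mean_quality Minimum mean Phred quality of a read.
#' @param collapse_distance Maximum Levenshtein distance at which a minor
#'   sequence may be absorbed into a dominant one.
#' @param abundance_ratio Minimum dominant/minor count ratio for
#'   absorption (> 1).
#' @param frequency_floor Calls below this frequency are discarded and the
#'   remainder renormalised (0 <= floor < 0.5).
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(barcode_max_mismatch = 1L,
                          length_window = c(300L, 380L),
                          min_mean_quality = 20,
                          collapse_distance = 2L,
                          abundance_ratio = 20,
                          frequency_floor = 0.01) {
  stopifnot(barcode_max_mismatch >= 0, barcode_max_mismatch <= 2,
            length(length_window) == 2, length_window[1] <= length_window[2],
            abundance_ratio > 1,
            frequency_floor >= 0, frequency_floor < 0.5)
  structure(list(barcode_max_mismatch = as.integer(barcode_max_mismatch),
                 length_window = as.integer(length_window),
                 min_mean_quality = min_mean_quality,
                 collapse_distance = as.integer(collapse_distance),
                 abundance_ratio = abundance_ratio,
                 frequency_floor = frequency_floor),
            class = "caller_params")
}

#' Demultiplex barcoded reads
#'
#' Assigns each read to the unique manifest barcode within
#' `barcode_max_mismatch` of its prefix; reads matching no barcode, or more
#' than one, go to the unassigned bin.  The barcode prefix is stripped from
#' assigned reads.
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param params A [caller_params()].
#' @return Named list of read data frames, one per `population_id`, plus
#'   an `".unassigned"` element.
#' @export
demultiplex <- function(reads, manifest, params = caller_params()) {
  if (nrow(manifest) == 0) stop("empty manifest")
  bcs <- manifest$barcode
  if (anyDuplicated(bcs)) stop("duplicate barcode in manifest")
  if (length(unique(nchar(bcs))) != 1) stop("barcodes must share one length")
  nb <- nchar(bcs[1])
  prefix <- substr(reads$sequence, 1L, nb)
  bmat <- vapply(bcs, function(b)
    adist(prefix, b)[, 1], numeric(nrow(reads)))
  if (nrow(reads) == 1) bmat <- matrix(bmat, nrow = 1)
  hits <- bmat <= params$barcode_max_mismatch
  nhit <- rowSums(hits)
  assign_idx <- ifelse(nhit == 1, max.col(hits, ties.method = "first"),
                       NA_integer_)
  out <- list()
  for (i in seq_along(bcs)) {
    sel <- which(!is.na(assign_idx) & assign_idx == i)
    sub <- reads[sel, , drop = FALSE]
    sub$sequence <- substr(sub$sequence, nb + 1L, nchar(sub$sequence))
    sub$quality <- substr(sub$quality, nb + 1L, nchar(sub$quality))
    rownames(sub) <- NULL
    out[[manifest$population_id[i]]] <- sub
  }
  out[[".unassigned"]] <- {
    sub <- reads[is.na(assign_idx), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  out
}

.mean_quality <- function(qual) {
  vapply(qual, function(q) mean(as.integer(charToRaw(q))) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# Locate a primer at the start of a sequence, <= max_mm mismatches.
.primer_at_start <- function(seqs, primer, max_mm = 1L) {
  np <- nchar(primer)
  pre <- substr(seqs, 1L, np)
  ok <- nchar(seqs) >= np
  d <- rep(NA_integer_, length(seqs))
  d[ok] <- adist(pre[ok], primer)[, 1]
  !is.na(d) & d <= max_mm
}

#' Quality- and primer-filter demultiplexed reads
#'
#' Keeps reads of one segment: both primers must be found (at most one
#' mismatch each), reads on the reverse strand are reverse-complemented so
#' the output is forward-oriented, primers are trimmed, and reads are
#' retained only if the trimmed length falls in `length_window` and mean
#' quality is at least `min_mean_quality`.
#'
#' @param reads Demultiplexed read data frame (barcode already stripped).
#' @param model The [segment_model()] the reads should match.
#' @param params A [caller_params()].
#' @return Filtered, trimmed, forward-oriented read data frame.
#' @export
filter_reads <- function(reads, model, params = caller_params()) {
  if (nrow(reads) == 0) return(reads)
  fwd <- model$primer_fwd
  rev_rc <- .revcomp(model$primer_rev)     # expected at the 3' end
  is_fwd <- .primer_at_start(reads$sequence, fwd)
  is_rev <- !is_fwd & .primer_at_start(reads$sequence, model$primer_rev)
  reads$sequence[is_rev] <- .revcomp(reads$sequence[is_rev])
  reads$quality[is_rev] <- vapply(reads$quality[is_rev], function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
  keep <- is_fwd | is_rev
  # 3' primer check on the (now forward) reads
  nrp <- nchar(rev_rc)
  tail_ok <- rep(FALSE, nrow(reads))
  long_enough <- nchar(reads$sequence) >= nchar(fwd) + nrp
  idx <- which(keep & long_enough)
  if (length(idx)) {
    tails <- substr(reads$sequence[idx],
                    nchar(reads$sequence[idx]) - nrp + 1L,
                    nchar(reads$sequence[idx]))
    tail_ok[idx] <- adist(tails, rev_rc)[, 1] <= 1L
  }
  keep <- keep & tail_ok
  out <- reads[keep, , drop = FALSE]
  if (nrow(out)) {
    L <- nchar(out$sequence)
    out$sequence <- substr(out$sequence, nchar(fwd) + 1L, L - nrp)
    out$quality <- substr(out$quality, nchar(fwd) + 1L, L - nrp)
    trimmed_len <- nchar(out$sequence)
    win <- params$length_window
    ok <- trimmed_len >= win[1] & trimmed_len <= win[2] &
      .mean_quality(out$quality) >= params$min_mean_quality
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Homopolymer signature: collapsed base string + run lengths.  Two
# sequences differ "by one homopolymer step" when their collapsed strings
# match and exactly one run length differs, by exactly 1.
.hp_signature <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  list(key = paste(r$values, collapse = ""), lens = r$lengths)
}

.hp_one_step <- function(sig_a, sig_b) {
  if (sig_a$key != sig_b$key) return(FALSE)
  d <- abs(sig_a$lens - sig_b$lens)
  sum(d) == 1L
}

#' Denoise reads of one population and segment into haplotype calls
#'
#' Exact dereplication followed by iterated absorption, processing
#' sequences in ascending count order (ties broken lexicographically).
#' A sequence whose current frequency is below `frequency_floor` cannot
#' be a reportable haplotype and is treated as an error shoulder: it is
#' merged into the *nearest* more-abundant sequence within
#' `collapse_distance` Levenshtein edits (ties: higher count, then
#' lexicographic), so shoulder reads accrue to their most probable source
#' sequence.  A sequence at or above the floor is a candidate haplotype
#' and is merged only under the conservative abundance-ratio rule: into
#' the most abundant sequence within `collapse_distance` whose count is
#' at least `abundance_ratio` times its own.  Sequences differing only by
#' one homopolymer run length (the dominant Ion-Torrent artefact) are
#' merged into any more abundant neighbour regardless of the ratio.
#' Passes repeat until no merge applies.  Surviving sequences below
#' `frequency_floor` are then dropped and frequencies renormalised.
#'
#' @param reads Filtered read data frame (or character vector of
#'   sequences) from a single population and segment.
#' @param params A [caller_params()].
#' @return Data frame `sequence`, `read_count`, `frequency`, sorted by
#'   descending count (class `haplotype_calls`).  Zero retained reads give
#'   a zero-row result with a warning.
#' @export
call_haplotypes <- function(reads, params = caller_params()) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  empty <- data.frame(sequence = character(0), read_count = integer(0),
                      frequency = numeric(0))
  class(empty) <- c("haplotype_calls", "data.frame")
  if (length(seqs) == 0) {
    warning("no retained reads; population dropped")
    return(empty)
  }
  tab <- table(seqs)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sigs <- lapply(setNames(names(counts), names(counts)), .hp_signature)
  hp_keys <- vapply(sigs, `[[`, "", "key")

  total_reads <- sum(counts)
  repeat {
    ord <- order(counts, names(counts))         # ascending count, then lex
    merged_any <- FALSE
    for (s in names(counts)[ord]) {
      if (!s %in% names(counts)) next           # absorbed earlier this pass
      cs <- counts[[s]]
      others <- setdiff(names(counts), s)
      if (!length(others)) break
      bigger <- others[counts[others] > cs]
      absorber <- NULL
      if (length(bigger)) {
        d <- .lev_bounded(s, bigger, params$collapse_distance)
        near <- bigger[d <= params$collapse_distance]
        dn <- d[d <= params$collapse_distance]
        if (cs / total_reads < params$frequency_floor) {
          # error shoulder: nearest neighbour, ties by count then name
          if (length(near)) {
            o <- order(dn, -counts[near], near)
            absorber <- near[o[1]]
          }
        } else if (length(near)) {
          # candidate haplotype: conservative abundance-ratio rule
          elig <- near[counts[near] >= params$abundance_ratio * cs]
          if (length(elig))
            absorber <- elig[order(-counts[elig], elig)][1]
        }
        if (is.null(absorber)) {
          # homopolymer-length-only difference: ratio-free merge
          hp <- bigger[hp_keys[bigger] == hp_keys[[s]] &
                         abs(nchar(bigger) - nchar(s)) == 1L]
          if (length(hp)) {
            sig_s <- sigs[[s]]
            for (b in hp[order(-counts[hp], hp)]) {
              if (.hp_one_step(sig_s, sigs[[b]])) { absorber <- b; break }
            }
          }
        }
      }
      if (!is.null(absorber)) {
        counts[[absorber]] <- counts[[absorber]] + cs
        counts <- counts[names(counts) != s]
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }

  total <- sum(counts)
  freq <- counts / total
  keep <- freq >= params$frequency_floor
  if (!any(keep)) {
    warning("no call above the frequency floor; population dropped")
    return(empty)
  }
  counts <- counts[keep]
  freq <- counts / sum(counts)
  ord <- order(-counts, names(counts))
  out <- data.frame(sequence = names(counts)[ord],
                    read_count = as.integer(counts[ord]),
                    frequency = as.numeric(freq[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("haplotype_calls", "data.frame")
  out
}

#' Merge per-population calls into a frequency table
#'
#' Identical sequences across populations share one haplotype name.  Names
#' are the segment prefix (`2s6_` / `3s6_`) plus the zero-padded rank of
#' the haplotype by total read count across populations; a `name_map`
#' (sequence -> name, e.g. from [panel_inserts()]) overrides the rank names
#' for known sequences.
#'
#' @param calls Named list: `calls[[population_id]][[segment_id]]` is a
#'   [call_haplotypes()] result.
#' @param manifest Manifest data frame with population metadata.
#' @param name_map Optional named character vector mapping sequence ->
#'   haplotype name.
#' @return A `frequency_table` data frame with columns `population_id`,
#'   `country`, `continent`, `year`, `segment_id`, `haplotype_name`,
#'   `read_count`, `frequency`.
#' @export
merge_tables <- function(calls, manifest, name_map = NULL) {
  rows <- list()
  for (pop in names(calls)) {
    meta <- manifest[manifest$population_id == pop, , drop = FALSE]
    if (nrow(meta) != 1) stop("population ", pop, " not in manifest")
    for (seg in names(calls[[pop]])) {
      cc <- calls[[pop]][[seg]]
      if (nrow(cc) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        population_id = pop, country = meta$country,
        continent = meta$continent, year = meta$year, segment_id = seg,
        sequence = cc$sequence, read_count = cc$read_count,
        frequency = cc$frequency, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no calls to merge")
  df <- do.call(rbind, rows)

  df$haplotype_name <- NA_character_
  for (seg in unique(df$segment_id)) {
    sel <- df$segment_id == seg
    tot <- tapply(df$read_count[sel], df$sequence[sel], sum)
    ord <- names(tot)[order(-tot, names(tot))]
    prefix <- if (seg == "IIS6") "2s6_" else "3s6_"
    nm <- setNames(sprintf("%s%02d", prefix, seq_along(ord) - 1L), ord)
    if (!is.null(name_map)) {
      known <- intersect(names(nm), names(.invert_name_map(name_map)))
      nm[known] <- .invert_name_map(name_map)[known]
    }
    df$haplotype_name[sel] <- nm[df$sequence[sel]]
  }
  df <- df[, c("population_id", "country", "continent", "year", "segment_id",
               "haplotype_name", "read_count", "frequency", "sequence")]
  class(df) <- c("frequency_table", "data.frame")
  df
}

# name_map is name -> sequence or sequence -> name; normalise to seq -> name
.invert_name_map <- function(name_map) {
  if (all(grepl("^[ACGT]+$", name_map))) {          # values are sequences
    setNames(names(name_map), as.character(name_map))
  } else {
    name_map
  }
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %d rows, %d population(s), segments: %s\n",
              nrow(x), length(unique(x$population_id)),
              paste(unique(x$segment_id), collapse = ", ")))
  print.data.frame(head(as.data.frame(x)[, setdiff(names(x), "sequence")], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Extract the name -> sequence map of a frequency table
#'
#' @param table A `frequency_table`.
#' @return Named character vector, haplotype name -> sequence.
#' @export
table_sequences <- function(table) {
  u <- unique(table[, c("haplotype_name", "sequence")])
  setNames(u$sequence, u$haplotype_name)
}
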