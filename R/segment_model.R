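#' Annotated reference model for one sodium-channel segment
#'
#' A `segment_model` bundles everything needed to interpret amplicon reads
#' from one Na_V segment: the wild-type amplicon sequence (primer sites
#' included), the exon intervals within it, the residue number of the first
#' exon codon under the housefly (*Musca domestica*) numbering convention,
#' the PCR primers, and the catalogue of knockdown-resistance (kdr) sites
#' the segment harbours.
#'
#' Coordinates are 1-based and intervals are closed on both ends, following
#' the usual R/Bioconductor convention; all reported positions are 1-based.
#'
#' @param segment_id `"IIS6"` or `"IIIS6"`.
#' @param sequence Wild-type amplicon sequence (uppercase A/C/G/T), primer
#'   binding sites at both ends.
#' @param exon_intervals Two-column integer matrix (`start`, `end`), one row
#'   per exon, sorted, disjoint, within the sequence.
#' @param codon_offset Housefly residue number of the first complete exon
#'   codon.
#' @param frame_phase Reading-frame phase of the first exon base (0..2).
#' @param primer_fwd,primer_rev Forward and reverse PCR primers, written
#'   5'->3' on their own strands.
#' @param kdr_catalogue Data frame with columns `residue`, `wild_aa`,
#'   `resistant_aas` (comma-separated amino-acid codes) and `segment_id`.
#'
#' @return An object of class `segment_model`.
#' @seealso [build_default_panel()] for the packaged IIS6/IIIS6 models.
#' @export
segment_model <- function(segment_id, sequence, exon_intervals, codon_offset,
                          frame_phase = 0L, primer_fwd, primer_rev,
                          kdr_catalogue) {
  segment_id <- match.arg(segment_id, c("IIS6", "IIIS6"))
  sequence <- toupper(sequence)
  stopifnot(grepl("^[ACGT]+$", sequence),
            grepl("^[ACGT]+$", primer_fwd), grepl("^[ACGT]+$", primer_rev),
            primer_fwd == toupper(primer_fwd), primer_rev == toupper(primer_rev))
  exon_intervals <- matrix(as.integer(exon_intervals), ncol = 2,
                           dimnames = list(NULL, c("start", "end")))
  if (is.unsorted(exon_intervals[, "start"], strictly = TRUE))
    stop("exon intervals must be sorted")
  if (any(exon_intervals[, "start"] > exon_intervals[, "end"]) ||
      any(exon_intervals < 1L) || any(exon_intervals > nchar(sequence)))
    stop("exon intervals out of sequence bounds")
  if (nrow(exon_intervals) > 1 &&
      any(exon_intervals[-1, "start"] <= exon_intervals[-nrow(exon_intervals), "end"]))
    stop("exon intervals must be disjoint")
  coding_len <- sum(exon_intervals[, "end"] - exon_intervals[, "start"] + 1L)
  frame_phase <- as.integer(frame_phase)
  stopifnot(frame_phase %in% 0:2)
  if ((coding_len - ((3L - frame_phase) %% 3L)) %% 3L != 0L &&
      coding_len %% 3L != 0L)
    stop("exon length inconsistent with frame phase")
  stopifnot(is.data.frame(kdr_catalogue),
            all(c("residue", "wild_aa", "resistant_aas", "segment_id") %in%
                  names(kdr_catalogue)))
  resist <- strsplit(kdr_catalogue$resistant_aas, ",", fixed = TRUE)
  if (any(mapply(function(w, r) w %in% r, kdr_catalogue$wild_aa, resist)))
    stop("wild-type amino acid listed among resistant alleles")
  structure(
    list(segment_id = segment_id, sequence = sequence,
         exon_intervals = exon_intervals, codon_offset = as.integer(codon_offset),
         frame_phase = frame_phase, primer_fwd = primer_fwd,
         primer_rev = primer_rev, kdr_catalogue = kdr_catalogue),
    class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  cat(sprintf("<segment_model> %s, %d bp amplicon\n", x$segment_id,
              nchar(x$sequence)))
  cat(sprintf("  exons: %s (first codon = residue %d)\n",
              paste(sprintf("[%d,%d]", x$exon_intervals[, 1],
                            x$exon_intervals[, 2]), collapse = " "),
              x$codon_offset))
  cat(sprintf("  kdr sites: %s\n",
              paste(sprintf("%s%d", x$kdr_catalogue$wild_aa,
                            x$kdr_catalogue$residue), collapse = ", ")))
  invisible(x)
}

# Intron/flank intervals are everything outside the exons, primer regions
# excluded from the "intron" proper only in reporting.
.intron_intervals <- function(model) {
  ex <- model$exon_intervals
  n <- nchar(model$sequence)
  bounds <- c(0L, as.vector(t(ex)), n + 1L)
  out <- NULL
  for (i in seq(1, length(bounds) - 1, by = 2)) {
    s <- bounds[i] + 1L; e <- bounds[i + 1] - 1L
    if (s <= e) out <- rbind(out, c(s, e))
  }
  colnames(out) <- c("start", "end")
  out
}

# TRUE for each reference position lying in an exon.
.exon_mask <- function(model) {
  mask <- rep(FALSE, nchar(model$sequence))
  for (i in seq_len(nrow(model$exon_intervals)))
    mask[model$exon_intervals[i, 1]:model$exon_intervals[i, 2]] <- TRUE
  mask
}

# Reference view: either the full amplicon or the primer-trimmed insert.
# Called haplotypes are primer-trimmed, panel haplotypes are not; both must
# align cleanly, so downstream code picks the view matching the query.
.model_view <- function(model, trimmed = FALSE) {
  if (!trimmed) {
    return(list(sequence = model$sequence, exon_intervals = model$exon_intervals,
                offset = 0L))
  }
  nf <- nchar(model$primer_fwd)
  nr <- nchar(model$primer_rev)
  ins <- substr(model$sequence, nf + 1L, nchar(model$sequence) - nr)
  ex <- model$exon_intervals - nf
  list(sequence = ins, exon_intervals = ex, offset = nf)
}

# Does this query still carry the forward primer at its 5' end?
.has_fwd_primer <- function(seq, model, max_mismatch = 2L) {
  p <- model$primer_fwd
  if (nchar(seq) < nchar(p)) return(FALSE)
  .hamming(substr(seq, 1L, nchar(p)), p) <= max_mismatch
}

# Residue number -> codon start position (in full-amplicon coordinates),
# NA when the residue is not covered by the segment.
.codon_start <- function(model, residue) {
  idx <- residue - model$codon_offset          # 0-based codon index
  if (idx < 0) return(NA_integer_)
  coding_pos <- idx * 3L + 1L                  # 1-based position in coding seq
  ex <- model$exon_intervals
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    len <- ex[i, 2] - ex[i, 1] + 1L
    if (coding_pos <= cum + len) return(ex[i, 1] + (coding_pos - cum - 1L))
    cum <- cum + len
  }
  NA_integer_
}

#' Substitute codons of a panel haplotype
#'
#' Returns `sequence` with the codon at each requested housefly residue
#' number replaced.  Used to derive kdr haplotypes from a wild-type
#' background and by tests to build round-trip fixtures.
#'
#' @param sequence Full amplicon sequence aligned to `model` without indels
#'   relative to the reference exons.
#' @param model A [segment_model()].
#' @param codon_changes Named character vector, names = residue numbers,
#'   values = replacement codons (3 bases).
#' @return The mutated sequence.
#' @export
mutate_codons <- function(sequence, model, codon_changes) {
  stopifnot(nchar(sequence) == nchar(model$sequence))
  for (res in names(codon_changes)) {
    pos <- .codon_start(model, as.integer(res))
    if (is.na(pos)) stop("residue ", res, " not covered by ", model$segment_id)
    codon <- codon_changes[[res]]
    stopifnot(nchar(codon) == 3L)
    substr(sequence, pos, pos + 2L) <- codon
  }
  sequence
}

# Apply point substitutions / a deletion given in full-amplicon coordinates.
.apply_point_subs <- function(sequence, subs) {
  for (i in seq_along(subs)) {
    pos <- as.integer(names(subs)[i])
    substr(sequence, pos, pos) <- subs[[i]]
  }
  sequence
}

.delete_range <- function(sequence, start, end) {
  paste0(substr(sequence, 1L, start - 1L),
         substr(sequence, end + 1L, nchar(sequence)))
}
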