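#' Align a haplotype to its segment reference
#'
#' Global (Needleman-Wunsch) alignment with affine gaps, scored match +1,
#' mismatch -2, gap open -4, gap extension -1.  The query may be a full
#' amplicon or a primer-trimmed insert; the matching reference view is
#' chosen automatically from the presence of the forward primer.  Gap runs
#' are left-normalised so score-equal placements resolve deterministically.
#'
#' @param sequence Query haplotype (uppercase A/C/G/T).
#' @param model A [segment_model()].
#' @return Object of class `segment_alignment`: aligned query/reference
#'   strings, identity, score, and the reference view used.
#' @export
align_to_reference <- function(sequence, model) {
  stopifnot(nchar(sequence) > 0)
  sequence <- toupper(sequence)
  trimmed <- !.has_fwd_primer(sequence, model)
  view <- .model_view(model, trimmed = trimmed)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(sequence, view$sequence,
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  norm <- .left_normalise_gaps(p, s)
  p <- norm$p; s <- norm$s
  identity <- sum(p == s & p != "-") / length(p)
  if (identity < 0.70)
    stop("foreign sequence: alignment identity ",
         sprintf("%.1f%%", 100 * identity), " below 70%")
  structure(list(query = p, reference = s, identity = identity,
                 score = Biostrings::score(aln), view = view,
                 segment_id = model$segment_id),
            class = "segment_alignment")
}

# Shift every gap run as far left as possible without changing the set of
# aligned pairs' scores (swap a gap with an identical flanking character).
.left_normalise_gaps <- function(p, s) {
  for (v in 1:2) {
    x <- if (v == 1) p else s        # the strand holding the gap
    y <- if (v == 1) s else p
    repeat {
      moved <- FALSE
      i <- 2L
      while (i <= length(x)) {
        if (x[i] == "-" && x[i - 1] != "-") {
          j <- i
          while (j < length(x) && x[j + 1] == "-") j <- j + 1L
          # run is x[i..j]; shifting it one left swaps the partner of
          # x[i-1] from y[i-1] to y[j] -- score-equal iff those characters
          # coincide
          if (y[i - 1] != "-" && y[i - 1] == y[j]) {
            x[j] <- x[i - 1]; x[i - 1] <- "-"
            moved <- TRUE
            i <- max(i - 1L, 2L)
            next
          }
          i <- j + 1L
        } else i <- i + 1L
      }
      if (!moved) break
    }
    if (v == 1) p <- x else s <- x
  }
  list(p = p, s = s)
}

#' Annotate a haplotype's amino-acid changes
#'
#' Projects the reference exon intervals through the alignment, compares
#' exon codons in frame, and reports each differing codon as one
#' amino-acid change under housefly residue numbering.  Intron (and
#' flanking) differences, indels included, are listed separately and never
#' translated.  An exonic indel marks the haplotype a putative artefact:
#' it is excluded from translation with a warning.
#'
#' @param sequence Query haplotype sequence.
#' @param model A [segment_model()].
#' @param name Optional haplotype name carried into the result.
#' @return Object of class `haplotype_annotation`: fields `name`,
#'   `segment_id`, `exon_changes` (data frame: `residue`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `synonymous`, `known_kdr`),
#'   `intron_edits` (data frame: `position`, `ref`, `alt`), `label`
#'   and `artifact`.
#' @export
annotate_haplotype <- function(sequence, model, name = NA_character_) {
  aln <- align_to_reference(sequence, model)
  p <- aln$query; s <- aln$reference
  view <- aln$view
  exon_mask_view <- rep(FALSE, nchar(view$sequence))
  for (i in seq_len(nrow(view$exon_intervals)))
    exon_mask_view[view$exon_intervals[i, 1]:view$exon_intervals[i, 2]] <- TRUE

  ref_pos <- cumsum(s != "-")              # view coordinates per column
  in_exon_col <- s != "-" & exon_mask_view[pmax(ref_pos, 1L)]
  artifact <- FALSE

  # exonic indels -> frameshift artefact
  if (any(p[in_exon_col] == "-")) artifact <- TRUE
  ins_cols <- which(s == "-")
  ins_in_exon <- ins_cols[ref_pos[ins_cols] >= 1 &
                            exon_mask_view[pmax(ref_pos[ins_cols], 1L)] &
                            # insertion between two exon bases
                            c(exon_mask_view, FALSE)[pmax(ref_pos[ins_cols], 1L) + 1L]]
  if (length(ins_in_exon)) artifact <- TRUE

  # intron/flank edits (view coordinates reported 1-based, full-amplicon
  # coordinates when the query carries primers)
  intron_edits <- .collect_noncoding_edits(p, s, ref_pos, in_exon_col,
                                           view$offset)

  exon_changes <- data.frame(residue = integer(0), ref_codon = character(0),
                             alt_codon = character(0), ref_aa = character(0),
                             alt_aa = character(0), synonymous = logical(0),
                             known_kdr = logical(0))
  if (artifact) {
    warning("exonic indel in ", ifelse(is.na(name), "haplotype", name),
            ": flagged putative artifact, excluded from translation")
    label <- "putative-artifact"
  } else {
    ref_coding <- paste(s[in_exon_col & p != "-"], collapse = "")
    qry_coding <- paste(p[in_exon_col], collapse = "")
    usable <- (nchar(ref_coding) %/% 3L) * 3L
    cat_res <- model$kdr_catalogue
    resist <- strsplit(cat_res$resistant_aas, ",", fixed = TRUE)
    k <- 0L
    for (start in seq(1L, usable, by = 3L)) {
      rc <- substr(ref_coding, start, start + 2L)
      qc <- substr(qry_coding, start, start + 2L)
      if (rc != qc) {
        residue <- model$codon_offset + (start - 1L) %/% 3L
        raa <- .translate_codon(rc); qaa <- .translate_codon(qc)
        hit <- which(cat_res$residue == residue)
        known <- length(hit) == 1 && qaa %in% resist[[hit]]
        k <- k + 1L
        exon_changes[k, ] <- list(residue, rc, qc, raa, qaa, raa == qaa,
                                  known)
      }
    }
    # label joins every codon change in ascending residue order; a
    # synonymous change reads e.g. "V1000V"
    label <- if (nrow(exon_changes) == 0) "wild-type" else
      paste(sprintf("%s%d%s", exon_changes$ref_aa, exon_changes$residue,
                    exon_changes$alt_aa), collapse = "+")
  }
  structure(list(name = name, segment_id = model$segment_id,
                 exon_changes = exon_changes, intron_edits = intron_edits,
                 label = label, artifact = artifact,
                 identity = aln$identity),
            class = "haplotype_annotation")
}

.collect_noncoding_edits <- function(p, s, ref_pos, in_exon_col, offset) {
  edits <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0))
  n <- length(p)
  i <- 1L; k <- 0L
  while (i <= n) {
    if (s[i] != "-" && !in_exon_col[i] && p[i] != "-" && p[i] != s[i]) {
      k <- k + 1L
      edits[k, ] <- list(ref_pos[i] + offset, s[i], p[i])
      i <- i + 1L
    } else if (p[i] == "-" && s[i] != "-" && !in_exon_col[i]) {
      j <- i
      while (j < n && p[j + 1] == "-" && s[j + 1] != "-") j <- j + 1L
      k <- k + 1L
      edits[k, ] <- list(ref_pos[i] + offset,
                         paste(s[i:j], collapse = ""), "-")
      i <- j + 1L
    } else if (s[i] == "-" && !isTRUE(in_exon_col[i])) {
      j <- i
      while (j < n && s[j + 1] == "-") j <- j + 1L
      anchor <- if (ref_pos[i] >= 1) ref_pos[i] else 0L
      k <- k + 1L
      edits[k, ] <- list(anchor + offset, "-", paste(p[i:j], collapse = ""))
      i <- j + 1L
    } else i <- i + 1L
  }
  edits
}

#' @export
print.haplotype_annotation <- function(x, ...) {
  cat(sprintf("<haplotype_annotation> %s (%s): %s\n",
              ifelse(is.na(x$name), "<unnamed>", x$name), x$segment_id,
              x$label))
  if (nrow(x$exon_changes)) {
    for (i in seq_len(nrow(x$exon_changes))) {
      ch <- x$exon_changes[i, ]
      cat(sprintf("  codon %d %s->%s (%s->%s)%s%s\n", ch$residue,
                  ch$ref_codon, ch$alt_codon, ch$ref_aa, ch$alt_aa,
                  if (ch$synonymous) " synonymous" else "",
                  if (ch$known_kdr) " [kdr]" else ""))
    }
  }
  if (nrow(x$intron_edits))
    cat(sprintf("  %d intron/flank edit(s)\n", nrow(x$intron_edits)))
  invisible(x)
}

#' Annotate every haplotype of a frequency table
#'
#' Annotates each distinct haplotype and attaches a per-population summary
#' of the total frequency carried by haplotypes with at least one
#' non-synonymous change versus the wild-type remainder.
#'
#' @param table A `frequency_table` (from [merge_tables()]).
#' @param models Named list of [segment_model()] objects (`IIS6`,
#'   `IIIS6`).
#' @return A list of class `annotated_frequency_table`: `table` (input
#'   plus a `label` column), `annotations` (named list of
#'   [annotate_haplotype()] results), and `summary` (data frame
#'   `population_id`, `segment_id`, `nonsynonymous_share`,
#'   `wildtype_share`).
#' @export
annotate_table <- function(table, models) {
  seqs <- table_sequences(table)
  segs <- setNames(table$segment_id[match(names(seqs), table$haplotype_name)],
                   names(seqs))
  anns <- lapply(names(seqs), function(nm)
    annotate_haplotype(seqs[[nm]], models[[segs[[nm]]]], name = nm))
  names(anns) <- names(seqs)
  labels <- vapply(anns, `[[`, "", "label")
  table$label <- labels[table$haplotype_name]

  key <- unique(table[, c("population_id", "segment_id")])
  summ <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- table$population_id == key$population_id[i] &
      table$segment_id == key$segment_id[i]
    nonsyn <- vapply(anns[table$haplotype_name[sel]], function(a)
      !a$artifact && nrow(a$exon_changes[!a$exon_changes$synonymous, ]) > 0,
      logical(1))
    data.frame(population_id = key$population_id[i],
               segment_id = key$segment_id[i],
               nonsynonymous_share = sum(table$frequency[sel][nonsyn]),
               wildtype_share = sum(table$frequency[sel][!nonsyn]))
  }))
  structure(list(table = table, annotations = anns, summary = summ),
            class = "annotated_frequency_table")
}

#' @export
print.annotated_frequency_table <- function(x, ...) {
  cat("<annotated_frequency_table>\n")
  labs <- vapply(x$annotations, `[[`, "", "label")
  cat("  haplotypes:\n")
  for (nm in names(labs)) cat(sprintf("    %-10s %s\n", nm, labs[[nm]]))
  cat("  per-population non-synonymous share:\n")
  print.data.frame(x$summary, row.names = FALSE)
  invisible(x)
}
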