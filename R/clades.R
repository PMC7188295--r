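#' Intron sequence of a haplotype, extracted through its alignment
#'
#' Projects the reference intron interval(s) through the alignment of
#' [align_to_reference()] and returns the haplotype's bases over those
#' columns, insertions anchored in the intron included, gaps removed.
#'
#' @param sequence Haplotype sequence.
#' @param model A [segment_model()].
#' @return Character scalar, the haplotype's intron sequence.
#' @export
intron_sequence <- function(sequence, model) {
  aln <- align_to_reference(sequence, model)
  p <- aln$query; s <- aln$reference
  view <- aln$view
  exon_mask_view <- rep(FALSE, nchar(view$sequence))
  for (i in seq_len(nrow(view$exon_intervals)))
    exon_mask_view[view$exon_intervals[i, 1]:view$exon_intervals[i, 2]] <- TRUE
  # restrict to the true intron (between exon 1 and last exon), not the
  # primer/flank regions
  first_exon_start <- min(view$exon_intervals[, 1])
  last_exon_end <- max(view$exon_intervals[, 2])
  ref_pos <- cumsum(s != "-")
  intronic <- ref_pos > first_exon_start & ref_pos < last_exon_end &
    !exon_mask_view[pmax(ref_pos, 1L)]
  take <- intronic & p != "-"
  paste(p[take], collapse = "")
}

#' Normalised intron distance between two IIS6 haplotypes
#'
#' Levenshtein distance between the two intron sequences (extracted via
#' the reference alignment), divided by the longer intron length, giving a
#' value in `[0, 1]`.  Only IIS6 is supported: the IIIS6 intron does not
#' separate clades.
#'
#' @param a,b Haplotype sequences.
#' @param model The IIS6 [segment_model()].
#' @return Normalised distance in `[0, 1]`.
#' @export
intron_distance <- function(a, b, model) {
  if (model$segment_id != "IIS6")
    stop("unsupported segment: clade structure is defined for IIS6 only")
  ia <- intron_sequence(a, model)
  ib <- intron_sequence(b, model)
  as.numeric(adist(ia, ib)) / max(nchar(ia), nchar(ib))
}

#' Partition IIS6 haplotypes into clades A and B from intron variation
#'
#' Average-linkage hierarchical clustering on pairwise normalised intron
#' distances, cut into two groups at the root.  The group containing a
#' haplotype with a catalogued kdr change (residues 989/1011/1016) is
#' labelled A; when no kdr haplotype is present, A goes to the group whose
#' introns lie nearer the reference (clade A) intron.  Input order never
#' affects the assignment (haplotypes are sorted by name internally).
#'
#' @param sequences Named character vector of IIS6 haplotype sequences
#'   (>= 2).
#' @param model The IIS6 [segment_model()].
#' @return Object of class `clade_assignment`: `labels` (named vector,
#'   `"A"`/`"B"`), `linkage_height` (root merge height), `anchor_used`,
#'   `single_clade` flag.
#' @export
classify_clades <- function(sequences, model) {
  if (model$segment_id != "IIS6")
    stop("unsupported segment: clade structure is defined for IIS6 only")
  stopifnot(length(sequences) >= 2, !is.null(names(sequences)))
  nm <- sort(names(sequences))
  introns <- vapply(nm, function(x) intron_sequence(sequences[[x]], model), "")
  ref_intron <- intron_sequence(model$sequence, model)
  D <- adist(introns)
  norm <- outer(nchar(introns), nchar(introns), pmax)
  Dn <- D / norm
  dimnames(Dn) <- list(nm, nm)
  if (all(Dn == 0)) {
    warning("all intron signatures identical: single clade")
    labels <- setNames(rep("A", length(nm)), nm)
    return(structure(list(labels = labels, linkage_height = 0,
                          anchor_used = NA_character_, single_clade = TRUE),
                     class = "clade_assignment"))
  }
  hc <- hclust(as.dist(Dn), method = "average")
  grp <- cutree(hc, k = 2)

  # anchor: a haplotype whose exons carry a catalogued kdr change
  anchor <- NA_character_
  for (x in nm) {
    ann <- annotate_haplotype(sequences[[x]], model, name = x)
    if (!ann$artifact && any(ann$exon_changes$known_kdr)) { anchor <- x; break }
  }
  if (!is.na(anchor)) {
    a_group <- grp[[anchor]]
  } else {
    ref_d <- adist(introns, ref_intron)[, 1] /
      pmax(nchar(introns), nchar(ref_intron))
    a_group <- grp[[nm[which.min(ref_d)]]]
  }
  labels <- setNames(ifelse(grp == a_group, "A", "B"), nm)
  structure(list(labels = labels,
                 linkage_height = max(hc$height),
                 anchor_used = anchor, single_clade = FALSE),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat("<clade_assignment>\n")
  for (lab in c("A", "B")) {
    members <- names(x$labels)[x$labels == lab]
    if (length(members))
      cat(sprintf("  clade %s (N = %d): %s\n", lab, length(members),
                  paste(members, collapse = ", ")))
  }
  if (!is.na(x$anchor_used))
    cat("  anchored by kdr haplotype:", x$anchor_used, "\n")
  invisible(x)
}
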