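#' Split a frequency table into two-segment population objects
#'
#' @param table A `frequency_table` containing both segments.
#' @return Named list of `two_segment_population` objects, each holding
#'   population metadata and the per-segment haplotype -> frequency maps.
#' @export
two_segment_populations <- function(table) {
  pops <- unique(table$population_id)
  out <- lapply(pops, function(pop) {
    sub <- table[table$population_id == pop, , drop = FALSE]
    maps <- lapply(c(IIS6 = "IIS6", IIIS6 = "IIIS6"), function(seg) {
      ss <- sub[sub$segment_id == seg, , drop = FALSE]
      setNames(ss$frequency, ss$haplotype_name)
    })
    if (any(vapply(maps, length, 1L) == 0)) return(NULL)
    for (m in maps) if (abs(sum(m) - 1) > 1e-6)
      stop("frequencies of population ", pop, " do not sum to 1")
    structure(list(population_id = pop, country = sub$country[1],
                   continent = sub$continent[1], year = sub$year[1],
                   iis6 = maps$IIS6, iiis6 = maps$IIIS6),
              class = "two_segment_population")
  })
  names(out) <- pops
  out[!vapply(out, is.null, logical(1))]
}

.monomorphic <- function(freqs, threshold = 1) {
  if (threshold >= 1) length(freqs) == 1 else max(freqs) >= threshold
}

#' Can a population's two-segment haplotypes be phased?
#'
#' Phase is determined combinatorially and is available exactly when at
#' least one of the two segments is monomorphic in the population: every
#' chromosome then carries the fixed haplotype at that segment, so each
#' haplotype of the other segment must sit beside it.
#'
#' @param pop A `two_segment_population`.
#' @param threshold Monomorphism threshold; 1 (the default) requires
#'   exactly one called haplotype, values below 1 declare a segment
#'   monomorphic when its top haplotype reaches that frequency (a guard
#'   against trace noise in pooled calls).
#' @return Logical.
#' @export
is_phaseable <- function(pop, threshold = 1) {
  .monomorphic(pop$iis6, threshold) || .monomorphic(pop$iiis6, threshold)
}

.short_id <- function(name) {
  m <- regmatches(name, regexpr("[0-9]+$", name))
  if (!length(m)) name else m
}

#' Phase the two segments of a monomorphic population
#'
#' Pairs every haplotype of the polymorphic segment with the fixed
#' haplotype of the monomorphic segment.  Phased haplotypes are named
#' `Phased_<IIS6 id><clade>-<IIIS6 id>` (e.g. `Phased_00B-01`) and carry
#' the polymorphic segment's frequencies (1 when both segments are fixed).
#'
#' @param pop A `two_segment_population` passing [is_phaseable()].
#' @param clades A `clade_assignment` for the IIS6 haplotypes.
#' @param threshold Monomorphism threshold, as in [is_phaseable()].
#' @return Data frame with columns `name`, `population_id`, `iis6_name`,
#'   `iis6_clade`, `iiis6_name`, `frequency`.
#' @export
phase_population <- function(pop, clades, threshold = 1) {
  if (!is_phaseable(pop, threshold))
    stop("population ", pop$population_id,
         " is polymorphic in both segments and cannot be phased")
  mono2 <- .monomorphic(pop$iis6, threshold)
  mono3 <- .monomorphic(pop$iiis6, threshold)
  fixed2 <- names(pop$iis6)[which.max(pop$iis6)]
  fixed3 <- names(pop$iiis6)[which.max(pop$iiis6)]
  if (mono2 && mono3) {
    pairs <- data.frame(iis6_name = fixed2, iiis6_name = fixed3,
                        frequency = 1, stringsAsFactors = FALSE)
  } else if (mono3) {
    pairs <- data.frame(iis6_name = names(pop$iis6), iiis6_name = fixed3,
                        frequency = as.numeric(pop$iis6),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(iis6_name = fixed2, iiis6_name = names(pop$iiis6),
                        frequency = as.numeric(pop$iiis6),
                        stringsAsFactors = FALSE)
  }
  clade <- vapply(pairs$iis6_name, function(nm) {
    if (nm %in% names(clades$labels)) clades$labels[[nm]] else "?"
  }, "")
  out <- data.frame(
    name = sprintf("Phased_%s%s-%s",
                   vapply(pairs$iis6_name, .short_id, ""), clade,
                   vapply(pairs$iiis6_name, .short_id, "")),
    population_id = pop$population_id,
    iis6_name = pairs$iis6_name, iis6_clade = clade,
    iiis6_name = pairs$iiis6_name, frequency = pairs$frequency,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Phase every phaseable population of a table
#'
#' @param table A `frequency_table` with both segments.
#' @param clades A `clade_assignment` for the IIS6 haplotypes.
#' @param threshold Monomorphism threshold, as in [is_phaseable()].
#' @return Data frame of phased haplotypes across populations (possibly
#'   zero rows).
#' @export
phase_table <- function(table, clades, threshold = 1) {
  pops <- two_segment_populations(table)
  phaseable <- Filter(function(p) is_phaseable(p, threshold), pops)
  if (!length(phaseable))
    return(data.frame(name = character(0), population_id = character(0),
                      iis6_name = character(0), iis6_clade = character(0),
                      iiis6_name = character(0), frequency = numeric(0)))
  do.call(rbind, lapply(phaseable, phase_population, clades = clades,
                        threshold = threshold))
}

#' Minimum number of independent origins of a kdr mutation
#'
#' Collects the phased haplotypes carrying a given amino-acid change and
#' counts the distinct genetic backgrounds it is seen on.  For a IIIS6
#' mutation the backgrounds are the IIS6 clades of its phased partners
#' (two clades cannot share a recent mutational event, so their count
#' lower-bounds the number of origins); for a IIS6 mutation, the distinct
#' IIS6 haplotypes carrying it.  A mutation never observed in a phased
#' population yields an "unobserved" report, not zero.
#'
#' @param phased Data frame from [phase_table()] / [phase_population()].
#' @param mutation Change label, e.g. `"F1534C"` or `"V1016I"`.
#' @param annotations Named list of [annotate_haplotype()] results
#'   covering every haplotype name appearing in `phased`.
#' @return Object of class `origin_report`: `mutation`, `segment_id`,
#'   `backgrounds` (data frame `iis6_clade`, `iis6_name`), `min_origins`
#'   (integer, `NA` when unobserved), `status`, `populations`.
#' @export
infer_min_origins <- function(phased, mutation, annotations) {
  carries <- function(nm) {
    ann <- annotations[[nm]]
    if (is.null(ann)) stop("no annotation for haplotype ", nm)
    if (ann$artifact) return(FALSE)
    ch <- ann$exon_changes
    mutation %in% sprintf("%s%d%s", ch$ref_aa, ch$residue, ch$alt_aa)
  }
  seg <- NA_character_
  for (ann in annotations) {
    ch <- ann$exon_changes
    if (nrow(ch) && mutation %in% sprintf("%s%d%s", ch$ref_aa, ch$residue,
                                          ch$alt_aa)) {
      seg <- ann$segment_id
      break
    }
  }
  if (is.na(seg)) {
    # mutation absent from every annotated haplotype: place it by residue
    # number so the report can still say "unobserved"
    res <- as.integer(gsub("[^0-9]", "", mutation))
    seg <- if (!is.na(res) && res < 1300) "IIS6" else "IIIS6"
  }

  if (seg == "IIIS6") {
    hit <- vapply(phased$iiis6_name, carries, logical(1))
  } else {
    hit <- vapply(phased$iis6_name, carries, logical(1))
  }
  obs <- phased[hit, , drop = FALSE]
  if (nrow(obs) == 0) {
    return(structure(list(mutation = mutation, segment_id = seg,
                          backgrounds = data.frame(iis6_clade = character(0),
                                                   iis6_name = character(0)),
                          min_origins = NA_integer_, status = "unobserved",
                          populations = character(0)),
                     class = "origin_report"))
  }
  backgrounds <- unique(obs[, c("iis6_clade", "iis6_name")])
  rownames(backgrounds) <- NULL
  min_origins <- if (seg == "IIIS6") length(unique(backgrounds$iis6_clade))
                 else length(unique(obs$iis6_name))
  structure(list(mutation = mutation, segment_id = seg,
                 backgrounds = backgrounds,
                 min_origins = as.integer(min_origins), status = "observed",
                 populations = sort(unique(obs$population_id))),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat(sprintf("<origin_report> %s (%s segment)\n", x$mutation, x$segment_id))
  if (x$status == "unobserved") {
    cat("  never observed in a phaseable population\n")
  } else {
    cat(sprintf("  minimum independent origins: %d\n", x$min_origins))
    cat(sprintf("  backgrounds: %s\n",
                paste(sprintf("%s (clade %s)", x$backgrounds$iis6_name,
                              x$backgrounds$iis6_clade), collapse = "; ")))
    cat(sprintf("  populations: %s\n", paste(x$populations, collapse = ", ")))
  }
  invisible(x)
}
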