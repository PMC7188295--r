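#' Packaged segment references and haplotype panel
#'
#' Builds the two annotated segment models (IIS6, IIIS6) and a panel of
#' haplotypes whose *relational* structure mirrors what is observed in
#' worldwide *Aedes aegypti* surveys: IIS6 haplotypes fall into two clades
#' (A and B) separated by intron indels and substitutions, every kdr-bearing
#' IIS6 haplotype sits on the clade-A background as a 1-2 substitution
#' derivative of the clade-A wild type, and the IIIS6 kdr haplotypes are
#' single-substitution derivatives of the wild type (with the double mutant
#' 1520I+1534C derived from the 1534C haplotype).  The nucleotide sequences
#' themselves are synthetic; only their mutual relationships (derivation
#' edges, clade indels, codon changes) are modelled on real data.
#'
#' Panel members (all full amplicons, primer sites included):
#' \describe{
#'   \item{2s6_A_03}{clade A wild type (the IIS6 reference)}
#'   \item{2s6_A_01}{I1011M derivative of 2s6_A_03}
#'   \item{2s6_A_02}{V1016I derivative of 2s6_A_03}
#'   \item{2s6_A_06}{S989P+V1016G derivative of 2s6_A_03}
#'   \item{2s6_A_19}{synonymous exon variant of 2s6_A_03}
#'   \item{2s6_B_00}{clade B wild type: 4-bp intron deletion + 4 intron
#'     substitutions relative to clade A}
#'   \item{2s6_B_04}{intron variant of 2s6_B_00}
#'   \item{3s6_00}{IIIS6 wild type (the IIIS6 reference)}
#'   \item{3s6_01}{F1534C derivative of 3s6_00}
#'   \item{3s6_13}{T1520I derivative of 3s6_01 (so 1520I+1534C)}
#'   \item{3s6_02, 3s6_03}{intron variants of 3s6_00}
#'   \item{3s6_11}{I1532T derivative of 3s6_00}
#'   \item{3s6_17}{S1605A derivative of 3s6_00}
#' }
#'
#' @return A list with elements `models` (named list of [segment_model()]
#'   objects, `IIS6` and `IIIS6`) and `haplotypes` (data frame with columns
#'   `name`, `segment_id`, `clade_label`, `sequence`).
#' @examples
#' panel <- build_default_panel()
#' panel$models$IIS6
#' subset(panel$haplotypes, segment_id == "IIS6")$name
#' @export
build_default_panel <- function() {
  iis6_ref <- paste0(
    "CGGGTATTATGCGGCGAGTGCGTGTCAAACACAATTTCTCCTGCTCTTTTCCAGAAGAGT",
    "ATCAACTCCTAGTAAAACCGATAGAGTCAATGACAGTTATAGCGATAGAAGTGGAACCAG",
    "TAGCTCCACCTCCCCCCGATCTGGATTAGGAATGCATTGTACGCTCGCATGATTGCTCTC",
    "TCGCACGTGGCCCGTAAGACCAAATGGATCAGTAGGCCAGGATACACCTTATGGGGGCTT",
    "CGCATTGTTGTTTCCAGAACCACCCGCTAATCGGATCTATCGGTCTAAGTGACCAAACAT",
    "TGCCCCTGACTGGCGCTTTCGAAGATTACCTGCTTAGCCTTGCTTTTGTCCA")
  iiis6_ref <- paste0(
    "GTGGGAAAGCAGCCGATTCGCTTTTATGAAGTGTTAAACACATCGGTAGCACTTCAAAAC",
    "GGGCGAGCTAACATTATACGCTTCCTGGCATTTCGGTTACGGGAACGACCACAGGTTGGA",
    "CTCCCGATGCAGGGCTATTTGTGTCTCTGTGCGTTTTAGTTACTGGCTTGCTCATTGTGG",
    "CGAAGGATCCCAAATCAACTCTTTAAGGTCATCCTTATTCCTCTCACGGGGTAGGGAACA",
    "GGAACTGGCTCTCAGTCGCGAAGAAATCCCACAAGAATTACTTAATGGTCCGGGCCCTCT",
    "ACCTACGGATAGGCCTCCTAGGGGAAAAGTATCAGTTGTTCATCGGGTTCAACA")

  iis6 <- segment_model(
    segment_id = "IIS6", sequence = iis6_ref,
    # primer 1-20 | exon1 21-134 (codons 983-1020) | intron 135-224 |
    # exon2 225-332 (codons 1021-1056) | primer site 333-352
    exon_intervals = rbind(c(21L, 134L), c(225L, 332L)),
    codon_offset = 983L, frame_phase = 0L,
    primer_fwd = "CGGGTATTATGCGGCGAGTG",
    primer_rev = "TGGACAAAAGCAAGGCTAAG",
    kdr_catalogue = data.frame(
      residue = c(989L, 1011L, 1016L),
      wild_aa = c("S", "I", "V"),
      resistant_aas = c("P", "M", "I,G"),
      segment_id = "IIS6"))
  iiis6 <- segment_model(
    segment_id = "IIIS6", sequence = iiis6_ref,
    # primer 1-21 | exon1 22-132 (codons 1514-1550) | intron 133-169 |
    # exon2 170-334 (codons 1551-1605) | primer site 335-354
    exon_intervals = rbind(c(22L, 132L), c(170L, 334L)),
    codon_offset = 1514L, frame_phase = 0L,
    primer_fwd = "GTGGGAAAGCAGCCGATTCGC",
    primer_rev = "TGTTGAACCCGATGAACAAC",
    kdr_catalogue = data.frame(
      residue = c(1520L, 1532L, 1534L),
      wild_aa = c("T", "I", "F"),
      resistant_aas = c("I", "T", "C"),
      segment_id = "IIIS6"))

  a03 <- iis6_ref
  a01 <- mutate_codons(a03, iis6, c("1011" = "ATG"))             # I1011M
  a02 <- mutate_codons(a03, iis6, c("1016" = "ATA"))             # V1016I
  a06 <- mutate_codons(a03, iis6, c("989" = "CCC", "1016" = "GGA"))
  a19 <- mutate_codons(a03, iis6, c("1000" = "GTG"))             # synonymous
  # Clade B background: 4 intron substitutions then a 4-bp intron deletion
  # (intron spans 135-224 in clade-A coordinates).
  b00 <- .apply_point_subs(a03, c("140" = "A", "175" = "C", "200" = "T",
                                  "215" = "A"))
  b00 <- .delete_range(b00, 160L, 163L)
  b04 <- .apply_point_subs(b00, c("145" = "G", "206" = "A"))

  w00 <- iiis6_ref
  h01 <- mutate_codons(w00, iiis6, c("1534" = "TGC"))            # F1534C
  h13 <- mutate_codons(h01, iiis6, c("1520" = "ATA"))            # +T1520I
  h02 <- .apply_point_subs(w00, c("140" = "A"))
  h03 <- .apply_point_subs(w00, c("150" = "T", "160" = "C"))
  h11 <- mutate_codons(w00, iiis6, c("1532" = "ACA"))            # I1532T
  h17 <- mutate_codons(w00, iiis6, c("1605" = "GCA"))            # S1605A

  haplotypes <- data.frame(
    name = c("2s6_A_03", "2s6_A_01", "2s6_A_02", "2s6_A_06", "2s6_A_19",
             "2s6_B_00", "2s6_B_04",
             "3s6_00", "3s6_01", "3s6_13", "3s6_02", "3s6_03", "3s6_11",
             "3s6_17"),
    segment_id = c(rep("IIS6", 7), rep("IIIS6", 7)),
    clade_label = c(rep("A", 5), rep("B", 2), rep("none", 7)),
    sequence = c(a03, a01, a02, a06, a19, b00, b04,
                 w00, h01, h13, h02, h03, h11, h17),
    stringsAsFactors = FALSE)

  list(models = list(IIS6 = iis6, IIIS6 = iiis6), haplotypes = haplotypes)
}

#' Primer-trimmed panel sequences
#'
#' Strips the primer sites from each panel haplotype, giving the insert
#' sequences that the read caller reports.  Used to map called sequences
#' back to panel names.
#'
#' @param panel Result of [build_default_panel()] (or same structure).
#' @return Named character vector: panel name -> trimmed insert.
#' @export
panel_inserts <- function(panel) {
  out <- character(0)
  for (i in seq_len(nrow(panel$haplotypes))) {
    h <- panel$haplotypes[i, ]
    m <- panel$models[[h$segment_id]]
    out[h$name] <- substr(h$sequence, nchar(m$primer_fwd) + 1L,
                          nchar(h$sequence) - nchar(m$primer_rev))
  }
  out
}
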