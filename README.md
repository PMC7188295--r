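# kdrhaplo

Haplotype-level surveillance of knockdown-resistance (*kdr*) alleles in
the *Aedes aegypti* voltage-gated sodium channel (Na<sub>V</sub>), from
pooled, barcoded amplicon sequencing of the IIS6 and IIIS6 segments.

The package is aimed at vector-biology groups running pooled amplicon
panels for insecticide-resistance monitoring. It covers the whole path
from multiplexed FASTQ to population-genetic conclusions:

* **Simulation** — an annotated synthetic reference panel for the two
  segments plus a pooled-read simulator with an Ion-Torrent-like error
  model (substitutions, indels, elevated homopolymer indels).
* **Calling** — demultiplexing by barcode, primer/quality filtering, and
  a deterministic abundance-based denoiser that turns each population's
  reads into haplotype frequency tables.
* **Annotation** — reference-anchored alignment, codon-aware comparison
  in frame, and amino-acid change labels under housefly
  (*Musca domestica*) residue numbering (e.g. `V1016I`, `S989P+V1016G`),
  with known kdr sites flagged from a catalogue
  (IIS6: 989, 1011, 1016; IIIS6: 1520, 1532, 1534).
* **Genealogy** — statistical-parsimony haplotype networks
  (mutational-step edges under a 95% connection limit) and an
  intron-distance bipartition of IIS6 haplotypes into clades A and B.
* **Phasing & origins** — the combinatorial phasing rule for populations
  monomorphic at one segment, and a lower bound on the number of
  independent origins of a kdr mutation from the distinct clade
  backgrounds it is observed phased with.
* **Trends** — haplotype frequency trajectories over collection years
  (Spearman rank correlation of year vs frequency).

The core inference: IIS6 and IIIS6 are ~44.5 kb apart, so no read spans
both. But in a population *fixed* for one segment, every chromosome
carries that fixed haplotype, so each haplotype of the other segment is
phased by necessity. If F1534C (IIIS6) is then found phased with IIS6
partners from both intron-defined clades, one mutational event cannot
explain the data:

> min. origins(mutation) = #{distinct IIS6 clade backgrounds observed
> phased with the mutation}

## Worked example

Phasing five populations fixed for the IIIS6 1534C haplotype (`3s6_01`)
that segregate a clade-B wild type against the clade-A 1016I haplotype
at IIS6:

```r
library(kdrhaplo)
panel <- build_default_panel()
haps <- setNames(panel$haplotypes$sequence, panel$haplotypes$name)

annotate_haplotype(haps[["3s6_13"]], panel$models$IIIS6, name = "3s6_13")
#> <haplotype_annotation> 3s6_13 (IIIS6): T1520I+F1534C
#>   codon 1520 ACA->ATA (T->I) [kdr]
#>   codon 1534 TTC->TGC (F->C) [kdr]

clades <- classify_clades(haps[startsWith(names(haps), "2s6")],
                          panel$models$IIS6)
clades
#> <clade_assignment>
#>   clade A (N = 5): 2s6_A_01, 2s6_A_02, 2s6_A_03, 2s6_A_06, 2s6_A_19
#>   clade B (N = 2): 2s6_B_00, 2s6_B_04
#>   anchored by kdr haplotype: 2s6_A_01

# tab: frequency_table with the five populations (IIIS6 fixed at 3s6_01,
# IIS6 = {2s6_B_00, 2s6_A_02}); ann: annotations for all panel haplotypes
phased <- phase_table(tab, clades)
head(phased, 2)
#>                       name population_id iis6_name iis6_clade iiis6_name frequency
#> PuertoRico.1 Phased_00B-01    PuertoRico  2s6_B_00          B     3s6_01       0.7
#> PuertoRico.2 Phased_02A-01    PuertoRico  2s6_A_02          A     3s6_01       0.3

infer_min_origins(phased, "F1534C", ann)
#> <origin_report> F1534C (IIIS6 segment)
#>   minimum independent origins: 2
#>   backgrounds: 2s6_B_00 (clade B); 2s6_A_02 (clade A)
#>   populations: Amacuzac, Iguala, NewOrleans, PuertoRico, RibeiraoPreto
```

The same mutation observed only on clade-A partners yields
`min_origins = 1`; the IIS6 mutations (V1016I, I1011M, S989P+V1016G),
each confined to a single haplotype, always do.

The full pipeline (simulate → call → annotate → network → clades →
phase → trends) runs with one call:

```r
res <- run_pipeline(demo_scenario("two_origin"), seed = 1)
res$origins$F1534C$min_origins   # 2
```

or from the shell via the thin CLI in `inst/cli/kdrhaplo.R`
(`simulate | call | annotate | network | clades | phase | trends | run`).

## Layout

```
R/                  implementation (panel, simulator, caller, annotator,
                    networks, clades, phasing/origins, trends, IO, pipeline)
src/                Rcpp kernels (mutational-step DP, bounded Levenshtein)
inst/cli/           command-line wrapper
scripts/            acceptance script
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, parameters, design choices)
```
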