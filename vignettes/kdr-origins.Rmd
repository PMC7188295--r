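---
title: "Calling kdr haplotypes from pooled amplicons and counting origins of F1534C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling kdr haplotypes from pooled amplicons and counting origins of F1534C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrhaplo)
```

## The problem

Pyrethroid and DDT resistance in *Aedes aegypti* is driven in large part by
*kdr* (knockdown-resistance) substitutions in the voltage-gated sodium
channel (Na~V~).  The substitutions of practical concern cluster in two
short windows of the protein — the sixth transmembrane segments of domains
II and III (IIS6: residues 989, 1011, 1016; IIIS6: residues 1520, 1532,
1534, all numbered by homology to the *Musca domestica* channel).  Both
windows can be PCR-amplified as ~350-bp amplicons that each span an
exon–intron–exon structure.

Sequencing those amplicons from *pooled* DNA (many mosquitoes of one
population in a single barcoded library) yields population-level haplotype
frequencies at a fraction of the cost of individual genotyping.  This
package implements the full analysis path from multiplexed pooled reads to
three population-genetic conclusions:

1. per-population haplotype frequency tables for each segment,
2. the genealogical structure of the haplotypes (statistical-parsimony
   networks; an intron-based clade bipartition of IIS6), and
3. a lower bound on the number of independent mutational origins of a kdr
   change, obtained by phasing the two segments in populations that are
   monomorphic for one of them.

The phasing argument is combinatorial, not statistical.  The two segments
sit ~44.5 kb apart — far beyond any read — so phase cannot be observed
directly.  But if a population is fixed for one segment, every chromosome
in it carries that fixed haplotype, and each haplotype of the other
segment must co-occur with it.  If a IIIS6 mutation such as F1534C is then
seen phased with IIS6 backgrounds from *both* intron-defined clades, a
single mutational event cannot explain the data: the minimum number of
independent origins is the number of distinct clade backgrounds observed.

## The synthetic panel

The packaged reference panel (`build_default_panel()`) is synthetic: real
deposited haplotypes are available from GenBank (MN602753–MN602778 for
IIS6, MN602779–MN602796 for IIIS6) but are not redistributed here.  What
the panel reproduces is the *relational* structure that the inference
rests on, with sequences generated once and fixed:

* a clade-A IIS6 wild type (`2s6_A_03`) with kdr derivatives `2s6_A_01`
  (I1011M), `2s6_A_02` (V1016I) and `2s6_A_06` (S989P+V1016G) at one or
  two exonic substitutions from it — every kdr haplotype on the clade-A
  background;
* a clade-B IIS6 wild type (`2s6_B_00`) separated from clade A by a 4-bp
  intron deletion plus four intron substitutions (amplicons 352 bp for
  clade A, 348 bp for clade B, within the 324–352 bp range real IIS6
  haplotypes span), with `2s6_B_04` as an intron variant;
* a IIIS6 wild type (`3s6_00`, 354 bp) with `3s6_01` (F1534C) one
  substitution away, the Asian double mutant `3s6_13` (T1520I+F1534C)
  derived from `3s6_01`, intron variants `3s6_02`/`3s6_03`, and the rarer
  exonic variants `3s6_11` (I1532T) and `3s6_17` (S1605A).

Codon identities at the catalogued sites follow the field's conventions
(989 TCC→CCC, 1011 ATA→ATG, 1016 GTA→ATA/GGA, 1520 ACA→ATA, 1534
TTC→TGC), so annotation output reads exactly like published genotyping
reports.  Everything else (exon filler codons, intron sequence) is random
but fixed, chosen free of stop codons in frame.

Tests that pass on this panel therefore validate the *logic* of the
pipeline — annotation arithmetic, clade separation, phasing, origin
counting — not its behaviour on real Ion Torrent data, whose error
structure (flow-order-dependent homopolymer miscalls, strand bias,
chimeras from pooled PCR) is richer than the simulator below.

## The read simulator

`simulate_pool()` draws each segment's reads multinomially from configured
true frequencies, prefixes the population barcode, and corrupts the whole
read under a flat error model: per-base substitutions (default 0.005),
per-base indels (default 0.001) with a multiplier (default 6) inside
homopolymer runs of length ≥ 3, mimicking the dominant Ion Torrent
artefact, and a flat Phred quality (default 30).  Reads are single-end and
full-length, as in an amplicon protocol; fragmentation, paired ends,
quality-score realism and chimera formation are deliberately out of scope.
Pools emulate ~30 individuals, so the smallest real allele frequency is
about 1/60; the default 2000 reads per segment per population gives the
caller enough depth to resolve it.  All randomness flows from one integer
seed per call; identical inputs and seed give byte-identical FASTQ.

## The caller

`demultiplex()` assigns a read to the unique barcode within one mismatch
(ambiguous or unmatched reads are binned separately), and
`filter_reads()` keeps reads that carry both segment primers (≤ 1
mismatch each), re-orients reverse-strand reads, trims the primers, and
applies a length window (default 300–380 bp) and a mean-quality floor
(default Phred 20).

`call_haplotypes()` is a deliberately simple, fully deterministic
denoiser.  After exact dereplication it iterates absorption passes over
sequences in ascending count order:

* a sequence below the reporting floor (default 1% — safely under the
  1/60 minimum real frequency) cannot be a reportable haplotype, so it is
  treated as an error shoulder and merged into its **nearest** more
  abundant neighbour within the collapse distance (default 2 edits).
  Nearest-neighbour assignment matters: a minor true haplotype often sits
  one substitution from a major one, and routing shoulders to the most
  *abundant* neighbour instead would systematically strip the minor
  haplotype of its error reads and bias its frequency downward;
* a sequence at or above the floor is a candidate haplotype and is merged
  only into a neighbour at least `abundance_ratio` (default 20) times
  more abundant — the conservative rule that keeps genuine low-frequency
  haplotypes alive;
* sequences differing only by one homopolymer run length are merged into
  any more abundant neighbour regardless of the ratio, matching the
  platform's error profile.

Reads with more errors than the collapse distance that do not chain onto
an intermediate shoulder remain as sub-floor singletons and are discarded
at the end; this loss is haplotype-unbiased, so renormalised frequencies
stay calibrated.  At the default error rates the caller recovers three
haplotypes at 0.6/0.3/0.1 from 2000 reads with precision = recall = 1 and
a frequency RMSE of about 0.014 across 20 seeded replicates (the
acceptance suite recomputes this).

`merge_tables()` names haplotypes by global abundance rank with a segment
prefix (`2s6_00`, `3s6_01`, ...), or by panel name when the sequence
matches a packaged haplotype.

## Annotation

`annotate_haplotype()` aligns each haplotype to its segment reference
(global affine alignment: match +1, mismatch −2, gap open −4, gap extend
−1), left-normalises gap placement for determinism, projects the exon
intervals through the alignment, and compares codons in frame.  Each
differing codon yields one amino-acid change under housefly numbering
(multi-nucleotide changes in one codon are a single event, matching the
codon-level notation used in genotyping reports); intron and flank edits
are listed but never translated.  Alignments under 70% identity are
rejected as foreign sequence, and an exonic indel flags the haplotype as a
putative artefact and excludes it from translation — in a protein under
this much purifying selection a frameshift allele at appreciable frequency
is far more plausibly a residual sequencing artefact than a real
segregating haplotype.  Coordinates are 1-based in all reports.

## Networks and the connection limit

`mutational_steps()` counts the mutational events separating two
haplotypes: substitution columns of the score-optimal alignment plus the
number of contiguous gap runs, each indel run being one event.  Among
score-tied alignments the smallest step count is used; tests verify the
count against an exhaustive independent alignment search on short
sequences.

`connection_limit()` operationalises statistical parsimony: haplotypes are
connectable while the probability that their observed differences reflect
single mutational hits (no site struck twice, hence no hidden homoplasy)
stays at or above the confidence level (default 0.95).  Under uniform
placement of *j* mutations over *L* sites that probability is
∏ᵢ₌₀^(j−1) (1 − i/L), a no-collision model whose limit for a 354-bp
amplicon at 95% is 6 steps.  This is a deliberately transparent
formulation of the parsimony-limit idea; it is computed from the sequence
length alone and is monotone in it.

`build_network()` adds edges in ascending step order (ties: higher joint
frequency, then name), never joining pairs beyond the limit and skipping
an edge only when its endpoints were already connected at a strictly
smaller step count — score-tied alternative connections at the same level
are kept, producing the reticulations typical of parsimony networks.  No
inferred median (unsampled intermediate) nodes are added: a multi-step
edge carries its step count instead.  This keeps every displayed edge an
observed pairwise distance, testable against brute force, at the price of
not displaying hypothetical intermediates.

## Clades

The IIS6 clades are defined by intron variation, so `classify_clades()`
clusters haplotypes on normalised intron distance (Levenshtein on the
aligned intron, divided by the longer intron length), average linkage, cut
into two groups at the root.  A full likelihood tree with bootstrap adds
nothing here: the partition is driven by a fixed indel difference, and a
deterministic distance bipartition is reproducible and directly testable
(exon mutations can never move a haplotype between clades, which the tests
exercise).  Clade **A** is anchored biologically: it is the group
containing a haplotype with a catalogued kdr change at 989/1011/1016, or,
absent any kdr haplotype, the group nearer the packaged clade-A reference
intron.  IIIS6 input is rejected — its intron does not support clades.

## Phasing and origin counting

`is_phaseable()` requires exactly one called haplotype in a segment
(strict monomorphism).  Because pooled calling can leave trace noise, a
`threshold` argument allows a segment to count as monomorphic when its top
haplotype reaches that frequency; the default (1.0) keeps the strict rule
and the knob is documented rather than silently applied.
`phase_population()` pairs each haplotype of the polymorphic segment with
the fixed haplotype, carrying the polymorphic segment's frequencies, and
names results `Phased_<IIS6 id><clade>-<IIIS6 id>` (e.g. `Phased_00B-01`).

`infer_min_origins()` counts backgrounds: for a IIIS6 mutation, the
distinct IIS6 *clades* among its phased partners (two clades are too
divergent for one recent mutational event to span); for a IIS6 mutation,
the distinct IIS6 haplotypes carrying it.  A mutation never observed in a
phased population is reported "unobserved", not zero — absence of phasing
opportunities is not evidence about origins.  The count is a lower bound
and can only grow as populations are added.  Ancestral narratives (which
phased haplotype derived from which) are left to the network adjacencies;
the module reports observed background sets only.

## Temporal trends

`trajectories()` assembles, per haplotype and country, frequency points
across populations and years (zero-filled where a haplotype is absent) and
summarises the trend as the Spearman rank correlation of year against
frequency, labelled increasing/decreasing beyond ±0.3.  Rank correlation
was chosen because the temporal claim of interest is qualitative (a kdr
haplotype sweeping upward); no selection coefficients or significance
tests are attempted.

## The demonstration scenario

`demo_scenario()` wires the panel into a ten-population world: five
populations (Puerto Rico, New Orleans, Iguala, Amacuzac, Ribeirão Preto)
fixed for `3s6_01` and segregating `2s6_B_00` against `2s6_A_02` — the
configuration from which two origins of F1534C follow; an Asian population
fixed for `2s6_A_06`; an old Brazilian population fixed for `2s6_A_01`;
and a Brazilian series (2001–2015) in which `3s6_01` rises under a
logistic-like schedule.  The `"single_origin"` variant replaces
`2s6_B_00` with `2s6_A_03` in the five named populations, so the same
pipeline must then report a single origin — a parameter-recovery control.

```{r, eval = FALSE}
res <- run_pipeline(demo_scenario("two_origin"), seed = 1)
res$origins$F1534C
```

## Problem sizes and numerical choices

The test and acceptance suites run at the study conditions: 2000 reads
per segment per population, substitution rate 0.005, indel rate 0.001,
20 seeded replicates for caller recovery, and the ten-population scenario
end-to-end in both worlds.  Frequencies are checked to sum to 1 within
1e-6 after every renormalising stage.  Ties everywhere (absorption order,
edge insertion, clustering input order) are broken deterministically by
count then lexicographic name, so every output is reproducible from the
seed alone.

## Known limitations

* The simulator's error model is flat; real Ion Torrent error is
  flow-order- and context-dependent, and PCR chimeras are not modelled.
* The denoiser is frequency-based, not quality-aware; it does not attempt
  SeekDeep- or DADA2-style per-cluster error modelling.
* The clade bipartition assumes the intron signal is bimodal; a panel of
  intermediate intron haplotypes would not be split confidently (the
  26-record deposited IIS6 set can be checked directly — see below).
* Origin counts are lower bounds from observed phaseable populations
  only.

## Checking against deposited data

Users with network access can place the deposited haplotype FASTA files
(GenBank MN602753–MN602778 and MN602779–MN602796) and a TSV transcription
of the per-population frequency table under
`tests/testthat/external/` (`genbank_iis6.fasta`, `genbank_iiis6.fasta`,
`s3_frequencies.tsv`); the acceptance tests then verify record counts,
length ranges, the 6/20 clade partition and the private-allele structure
against those records.  Without the files those two checks report failure
rather than silently passing.
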