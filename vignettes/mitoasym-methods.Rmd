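---
title: "Strand asymmetry, the Control Region, and how mitoasym measures both"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand asymmetry, the Control Region, and how mitoasym measures both}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoasym)
```

## The model

Vertebrate mitochondrial DNA replicates asymmetrically: replication of the
heavy strand initiates at an origin inside the Control Region (CR), leaving
the two strands single-stranded for very different lengths of time and
exposing them to different mutational pressures. The result is a strong,
strand-specific compositional bias. `mitoasym` measures that bias where it
is least filtered by selection — the third positions of fourfold-degenerate
codons, where any substitution is synonymous — using two statistics on each
protein-coding gene's own coding strand:

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C}.$$

A codon contributes iff its first two bases exactly match one of the eight
fourfold families of the vertebrate mitochondrial genetic code (GCN, CCN,
TCN, ACN, CGN, GGN, CTN, GTN) and its third base is unambiguous. A skew
whose denominator is zero is *undefined* and is propagated as `NA`, never
as 0 — zero is a meaningful value (perfect balance).

The central modelling assumption is that the *expected* sign pattern of a
gene is set purely by its coding polarity relative to the CR: a gene on the
CR's strand is expected to show AT skew < 0 and GC skew > 0, a gene on the
opposite strand the negation. No gene is special-cased; nad6's
"anomalous" signs in standard genomes follow from its minority-strand
location. Because only relative polarity enters, every call is invariant
under reverse-complementing the stored sequence — there is no dependence on
which strand a submitter happened to deposit.

## Locating the CR and its polarity

The CR is found through the CSB-II conserved sequence block, a
poly-C/TA/poly-C motif (reference `CCCCCCTACCCCC`). `scan_csb2()` performs
a deterministic consensus scan for `C{m5,}TA C{m3,}` on both strands of
every non-coding region (the complement of all gene features on the
circle, 200 bp minimum by default to skip spacers). The defaults
`min_c5 = 5`, `min_c3 = 4` allow one cytosine of slack per flank relative
to the typical 6/5 runs, accommodating natural poly-C length variation.
When several hits survive, the longest match wins, then the hit in the
longest non-coding region, then the smallest coordinate; an annotated
CR/D-loop feature, when present, is scanned first and the global scan is
the fallback. A deterministic scan was chosen over de-novo motif discovery
deliberately: it is reproducible, dependency-free and auditable, at the
cost of missing heavily degenerate motifs (see Limitations). CSB-III is
not scanned: it is less conserved and often absent in fishes, and CSB-II
alone fixes the CR's orientation.

## The genome-level call

With per-gene skews and a CR polarity in hand, each protein-coding gene is
classified against its CR-relative expectation:

* **concordant** — both signs match and at least one magnitude reaches
  `tau`;
* **reversed** — both signs match the negated expectation likewise;
* **ambiguous** — fewer than `n_min` fourfold codons, an undefined skew,
  both magnitudes below `tau`, or the two axes disagreeing.

The genome call combines the gene states with the CR's orientation
relative to the majority PCG strand: all informative genes concordant with
a co-oriented CR is **standard**; all concordant with a counter-oriented
CR is **reversed** (the fully re-equilibrated state); any informative
contradiction is **disrupted** (the transitory state: architecture moved,
composition not yet re-equilibrated — concretely, after a CR inversion the
unmoved genes keep their old composition and now contradict the
expectation, while a gene inverted *together with* the CR keeps matching
it); **undetermined** is reserved for a missing CSB-II or an informative
fraction below `quorum`. Distinguishing disrupted from undetermined
matters: the former is a biological signal, the latter a data deficit.

Tunable parameters, all dimensionless: `tau = 0.05` (minimum skew
magnitude treated as signed; well below the ~0.3–0.4 magnitudes typical of
fish fourfold sites but above the sampling noise of a 200-codon gene),
`n_min = 10` fourfold codons per gene, `quorum = 0.8` informative fraction.
These operationalise what is otherwise a qualitative sign reading; raising
`tau` can only move genes into ambiguity (a tested monotonicity).
Duplicated PCG labels contribute only their longest copy, so pseudogenised
stubs do not dilute the call.

## Gene-order typing

Gene orders are signed circular sequences over the canonical 37-gene
vocabulary plus the CR (included so a CR inversion is a reportable event),
rotated to a canonical anchor (cox1). `classify_events()` produces a
*typed description*, not a minimal edit script: copy-number differences
become duplications/losses; strand-flipped genes, grouped into maximal
runs contiguous in the observed order, become one inversion each;
remaining displacements are explained as a single moved block where
possible, called a **shuffle** if it moved at most `k = 2` positions
(operationalising "local") and a **translocation** otherwise. Residuals no
single block explains are reported best-effort as one compound event.
Exact rearrangement-distance decomposition is a non-goal; for the
single-event edits the simulator produces, recovery is exact (a tested
property on 200 random cases).

## The synthetic-data generator

`simulate_genome()` emulates exactly the statistical structure the
analysis assumes, nothing more. Each PCG codon is drawn independently:
with probability 0.5 a fourfold-family codon whose third base follows

$$P(A) = f\frac{1+a}{2},\; P(T) = f\frac{1-a}{2},\;
  P(G) = (1-f)\frac{1+g}{2},\; P(C) = (1-f)\frac{1-g}{2},$$

with AT content $f = 0.6$ and targets $(a, g)$ for CR-strand genes and
$(-a, -g)$ otherwise; non-fourfold codons come from stop-free families
with unbiased third positions, so only fourfold sites carry signal.
Defaults: 200 codons per PCG, 70 bp tRNAs, 950/1600 bp rRNAs, a 900 bp CR
with the CSB-II reference embedded mid-CR on the chosen strand, and
$(a, g) = (-0.3, +0.4)$ — the standard sign regime at magnitudes chosen
once as mid-range for fish mitogenomes. At these sizes a gene has ~100
fourfold codons, so each skew is estimated with a standard error near
0.12–0.13 and sign errors are rare but not impossible; tests therefore
assert statistical bounds (3–4 binomial SEs, ≥ 12/13 genes) rather than
exact sign recovery.

Two properties of edits are worth stating. First, a sequence-level
inversion reverse-complements a segment *and* flips its features' strands,
so a gene's coding-strand composition is unchanged — an edited genome is
automatically in the transitory (disrupted) state. The `equilibrate` flag
pre-negates the targets of genes an edit will flip, producing the
re-equilibrated state instead. Second, composition is keyed to the CR
strand, so `cr_strand = "-"` alone yields the fully reversed genome.
`write_fixture_set()` packages the four canonical scenarios (standard;
CR-inverted re-equilibrated; gene-block-inverted re-equilibrated;
CR+block-inverted not re-equilibrated) as GenBank/GFF3/ground-truth
fixtures.

What the generator does *not* emulate: codon-usage structure, among-gene
rate variation, long repeats and unresolvable regions, pseudogene decay,
partial re-equilibration gradients, and real tRNA/rRNA/CR sequence beyond
the embedded motif. Passing tests therefore demonstrate correctness of the
statistics and the classification logic under the stated model — not
robustness to every pathology of real records.

## Numerical and representational choices

Coordinates are 0-based half-open on the stored forward strand; GenBank
I/O converts to and from 1-based inclusive locations, with
origin-spanning `join(a..L,1..b)` locations kept as a single feature
flagged `wraps_origin` so gene-order signatures stay one-entry-per-gene.
Ambiguity codes are preserved in sequence but any codon containing one is
excluded from counting — family membership must be certain. Reading-frame
inference for unannotated fragments minimises internal stop codons under
the vertebrate mitochondrial code, breaking ties by fourfold-codon count
then lowest frame, and flags the result low-confidence when every frame
stops at ≥ 1 per 100 codons; flagged results are reported, never
suppressed. The Leu/Ser tRNA paralogs are split by codon family or
anticodon when deposited, then by template-neighbour position, then by
order of appearance. All simulation is seeded and byte-deterministic;
pipeline TSVs are byte-identical across reruns.

One property often stated loosely deserves precision: fourfold-site skews
are *not* antisymmetric under reverse-complementing a CDS and re-reading
it, because the antisense reading frames select a different codon set.
The exact antisymmetry — which is what strand-asymmetry reversal means
biologically — is that the complementary-strand view of the *same*
fourfold sites swaps A with T and G with C and so negates both skews; this
is the form the tests assert, alongside a statistical antisymmetry on
genes simulated with negated targets.

## Problem sizes

The shipped tests and the acceptance script use: 1000 random CDSs for the
oracle comparison, ~500 simulated gene replicates (39 genomes) for skew
recovery, 200 random single edits for event recovery, 100 random genomes
for end-to-end classifier accuracy, and four named fixtures — sizes at
which every stochastic bound above is comfortably resolved while a full
run stays in the low minutes on one core.

## Known limitations

* The consensus CSB-II scan cannot find motifs that deviate beyond the
  poly-C slack; such genomes come out `undetermined` (deliberately, rather
  than guessing polarity).
* Event typing is greedy: overlapping or compound rearrangements are
  described best-effort, not decomposed optimally.
* Pseudogenes are not detected; copy handling trusts the annotation.
* The classifier reads signs, not magnitudes; partially re-equilibrated
  genomes with consistently tiny skews will be called via the ambiguity
  rules rather than placed on a continuum.
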