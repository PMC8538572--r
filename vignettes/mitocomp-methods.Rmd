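---
title: "Methods and design of mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitocomp)
```

`mitocomp` implements the standard comparative battery for annotated
animal mitochondrial genomes. This vignette records the statistical
methods, the parameters that matter, the design decisions taken where the
field's conventions are ambiguous, and what the synthetic-data generator
does and does not emulate.

## Data model

An `mitogenome` is a circular (or linear) IUPAC DNA sequence plus a
feature table over the canonical 37-gene vocabulary (13 PCGs, 22 tRNAs,
2 rRNAs). Internally all intervals are 0-based half-open; the GenBank
boundary converts to and from 1-based inclusive coordinates, which removes
the usual off-by-one ambiguity from slicing code. Strands are labelled J
(majority, GenBank `+`) and N (minority, `complement(...)`), the
convention used in the insect-mitogenome literature. Features wrapping the
circular origin are stored as two intervals and re-joined on extraction.
`extract_gene()` always returns the coding-sense (5'→3') sequence, so
every downstream statistic is strand-corrected by construction.

Gene names are resolved through a synonym map (`"COX1"` → COI, `"nad2"` →
ND2, `"l-rRNA"` → 16SRNA, ...). Leucine and serine tRNAs are disambiguated
by the anticodon qualifier when present; otherwise the dominant
mitogenome-literature convention applies: trnL1 = Leu(CUN),
trnL2 = Leu(UUR), trnS1 = Ser(AGN), trnS2 = Ser(UCN). This is a
convention, not a fact recoverable from gene names alone, which is why the
anticodon always wins when available. Unresolvable features are retained
with a `warn` flag rather than dropped, so no annotation silently
disappears.

## Composition and skew

Strand skews are `AT skew = (A − T)/(A + T)` and
`GC skew = (G − C)/(G + C)`. Whole-genome values are computed on the J
strand as annotated; per-region values (PCG, tRNA, rRNA) on the
coding-sense concatenation of the class, since a region-level skew mixing
strands is not interpretable. Where genes overlap on the molecule the
overlap contributes once to each class it belongs to — the natural
semantics of concatenation, documented rather than hidden. Ambiguity
codes are preserved in the sequence but excluded from every count
(reported as `n_excluded`). A zero denominator yields `NA`, never an
exception. Percentages are reported to 2 decimals and skews to 4, the
precision conventional in this literature.

## Codon usage and RSCU

Codon statistics pool the 13 PCGs per genome (comparative papers report
genome-level codon tables; a per-gene view is available through
`region_composition(per_gene = TRUE)` and `codon_counts()` on single-gene
input). Under translation table 5 only TAA and TAG are stops, so there are
62 sense codons; AGA/AGG encode serine, ATA methionine and TGA
tryptophan. The synonymous families split leucine and serine into their
two isoacceptor families (Leu1 = CUN, Leu2 = UUR, Ser1 = AGN,
Ser2 = UCN), giving the 22 families conventional in mitogenome codon
plots; outputs carry explicit codon sets so the labelling convention
cannot corrupt downstream numbers.

`RSCU(c) = count(c) × |family| / Σ_family counts`; the family mean is 1 by
construction and `Σ RSCU = |family|` exactly, which the test suite asserts
as an invariant. Terminal incomplete codons (a trailing `T` or `TA` in
frame) are never counted as codons: they are incomplete stop codons
completed to UAA by polyadenylation of the transcript, and are recorded
as `T-`/`TA-` descriptors instead. A CDS with an internal stop is skipped
with a per-gene error and the run continues — one corrupt annotation
should not kill a comparative table.

## tRNA cloverleaf folding

Published comparative tables of tRNA "mismatches" rarely state a folding
algorithm. `mitocomp` therefore defines one, deterministically: a
template-constrained exhaustive search. The acceptor stem is fixed at 7
pairs anchored at the termini (one unpaired discriminator base at the 3'
end), the anticodon stem at 5 pairs around a 7-nt loop with the anticodon
at its centre, and DHU/TΨC stems range over 2–4 pairs with loop and spacer
lengths enumerated over canonical bounds (`CLOVERLEAF_BOUNDS`). Every
layout consistent with the sequence length (and with the anticodon, when
supplied) is scored `2·WC + 1·GU − 1·mismatch` over its stem pairs; ties
break by more acceptor WC pairs, then smaller variable loop, then the
5'-most DHU stem, then the remaining layout parameters in order. The
search is exhaustive and the tie-break total, so identical input yields
identical structure — a property the tests assert. DHU-less layouts are
admitted only for tRNA-Ser(AGN), the one metazoan mitochondrial tRNA that
genuinely lacks the arm.

Because the literature conflates G–U wobble pairs with true mismatches,
`mismatch_profile()` reports both readings: `nonwc` (all non-Watson–Crick
stem pairs, wobbles included) and `strict` (non-WC, non-GU), plus the
grand total of G–U pairs. Externally predicted structures (tRNAscan-SE,
MITOS) can be injected via `parse_structure_string()` for cross-checking.

Known limitation: this is a template fold, not thermodynamic RNA folding —
no energy model, no pseudoknots, no modified bases. For the highly
canonical mitochondrial tRNAs that is the appropriate tool; for divergent
or rearranged tRNAs an external predictor should be preferred and imported
as dot-bracket strings.

## Genetic distances

`kimura2p()` implements `d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with P and
Q the transition and transversion proportions over sites retained after
pairwise deletion (any site gapped or ambiguous in either sequence is
excluded for that pair only). Complete deletion would discard far more
signal in multi-genome supermatrices, which is why pairwise deletion is
the default. Non-positive logarithm arguments produce a typed saturation
marker (`d = NA`, `saturated = TRUE`) that propagates to the distance
matrix metadata; `neighbor_joining()` refuses saturated matrices by
naming the offending pairs, rather than silently imputing.

Whole-mitogenome distances are computed on the all-gene (PCG + rRNA +
tRNA) supermatrix, with a PCG-only matrix reported alongside, because
"whole mitogenome" in comparative papers is ambiguous between the two;
both are labelled in the output.

## Ka/Ks

The counting method is Nei–Gojobori (1986) with Jukes–Cantor correction,
chosen because it is the simplest fully specified estimator and every step
is unit-testable against enumeration: per-codon site counts are the
fraction of one-step neighbours that are synonymous (stop neighbours
excluded from the denominator, so `S + N = 3 ×` codons exactly), and
multi-position codon differences are averaged over all minimal
substitution pathways with stop-passing pathways excluded. Proportions are
corrected by `x → −¾ ln(1 − 4x/3)`; `pS ≥ 3/4` yields a saturation
marker and `Ks = 0` an undefined ratio, both typed, never silent.
`per_gene_kaks()` averages the defined ratios over all genome pairs on
codon-aware alignments and reports how many pairs were excluded.

NG86 assumes equal rates across substitution types. With a
transition/transversion ratio κ > 1 it systematically under-counts
synonymous sites, biasing Ka/Ks downward; this is a property of the
estimator, not of the implementation, and it is visible in the package's
own simulations (genes generated at ω = 0.5 recover mean ratios around
0.55–0.7 at κ = 2). The neutral-recovery check in the test suite therefore
runs the simulator at κ = 1, where the estimator's assumption holds and
mean Ka/Ks over long neutral genes falls in [0.8, 1.2].

## Alignment and trees

The pairwise aligner is an affine-gap Needleman–Wunsch–Gotoh (in C++ for
speed) with a fixed tie-break — diagonal over gap, gap-in-first over
gap-in-second — so alignments are reproducible to the byte. A gap of
length L costs `gap_open + (L − 1)·gap_extend`; defaults (match 1,
mismatch −1, open −5, extend −1) are package defaults, tuned for closely
related mitogenomes, and overridable everywhere. The progressive MSA
builds a guide tree from k-mer distances (average linkage) and merges
profiles by aligning their majority consensus sequences; it is a
desk-scale tool for near-identical sequences, not a ClustalW/MAFFT
replacement, and the supermatrix exporters (PHYLIP, NEXUS with charsets)
exist precisely so that serious ML/Bayesian analyses can be run in
external tools. Codon-aware alignment aligns translated proteins and
back-threads codons, so gaps come only in multiples of three and NG86
always sees in-frame codons; terminal stop codons are excluded from the
alignment.

Tree building is neighbor-joining (via `ape::nj`) with negative branch
lengths clamped to zero, plus column bootstrap: resample alignment
columns, recompute K2P + NJ, map split frequencies (×100) onto the
full-data tree. Under a fixed seed the supports are bit-reproducible.
Full ML (GTR+Γ) and Bayesian inference are deliberately out of scope.

Gene-order comparison is circular-rotation-invariant on signed symbol
lists; breakpoints are counted as adjacencies (unordered, unsigned)
present in one order and absent in the other. The default reference is
the ancestral insect arrangement with its 14 N-strand genes.

## The synthetic-data generator

The generator exists so that every stage of the pipeline runs, and is
validated, with no downloads. `simulate_root_genome()` emulates the data
regime the analysis targets: a circular ~15.5 kb molecule, the 37 canonical
genes in the ancestral arrangement and strand split, AT content ~74%
(base frequencies default A 0.47, T 0.27, G 0.10, C 0.16, giving positive
AT skew and negative GC skew on the J strand), PCGs as valid table-5 ORFs
with ATN starts and TAA/TAG stops, pair-perfect template tRNAs, and an
AT-richer control-region stand-in filling the molecule to the target
length. Gene lengths are fixed realistic defaults (COI longest); no claim
is made of matching any particular species' per-gene lengths. Codon
sampling uses iterative-proportional-fitting-calibrated weights so the
marginal base composition of coding sequence matches the requested
frequencies despite the exclusion of the AT-rich stop codons — without
the calibration the genome-wide AT content lands about a point short of
target.

Two generator details are worth knowing because they are what make exact
recovery tests possible:

- **tRNA unambiguity.** A generated tRNA is accepted only if the template
  fold recovers exactly the constructed pairing with a score margin of
  ≥ 2 over every layout with a different pairing (2 is the attainable
  maximum, since any stem has a sub-stem layout scoring exactly one WC
  pair less). A wobble substitution costs 1 score point and acceptor-stem
  perturbations hit all candidate layouts equally, so single injected
  perturbations are always recovered in place. The
  tRNA-Ser(AGN) DHU-replacement loop is generated purine-only, as in real
  metazoan mt-tRNAs, which also prevents spurious DHU stems.
- **Family-preserving ω thinning.** Substitution events are proposed
  per-site under a κ process and nonsynonymous changes are accepted with
  probability ω ("acceptance thinning" — simple and exactly controllable,
  rather than a full codon rate matrix). "Synonymous" is defined as
  preserving the synonymous codon family (the same Leu1/Leu2, Ser1/Ser2
  partition used for RSCU): a CUN↔UUR leucine flip is thinned like a
  nonsynonymous event. Family-preserving changes only ever differ at the
  third codon position, so with ω = 0 every NG86 pathway between two
  evolved codons is synonymous and Ka is exactly zero — without this
  refinement, two independent synonymous leucine events can compose into
  a pair difference whose pathway average imputes a fractional Nd.

`evolve_on_tree()` evolves each feature on its coding-sense sequence
(annotations fixed; no indels, no rearrangements, no control-region
repeats — all out of scope), with per-gene rate multipliers.
`fixture_suite()` writes an 8-leaf clade (tree depths chosen to span K2P
distances ≈ 0.015–0.08, a within-subfamily regime) as GenBank + FASTA plus
a JSON manifest of ground truth; the tRNA substitution rate is zero in
this suite so that the injected per-species wobble counts (0–8) are
exactly the genomes' non-WC stem pair counts. Regeneration under the same
seed is byte-identical.

What passing tests on this generator do **not** show: robustness to
annotation errors, indels, length heterogeneity, rearrangements, extreme
compositional bias, or tRNAs that deviate from the cloverleaf template —
real-data pathologies the simulator deliberately does not produce. The
neutral K2P substitution process also drifts composition slowly toward
uniform, so evolved leaves sit a fraction of a point below the root's AT
content; composition-recovery guarantees apply to generated (root)
genomes.

## Pipeline and reproducibility

`run_pipeline()` executes composition → codon → tRNA → distances → Ka/Ks
→ gene order → tree, writes one TSV per stage, a JSON summary whose every
number is taken from exactly one stage result (no recomputation drift),
and a log with the resolved seed, package version and per-stage timings.
Stage failures are isolated and collected; comparative stages are skipped
with a notice on single-genome input. Bootstrap replicates default to 200
in the pipeline configuration (1000 is conventional for publication runs;
the smaller default keeps interactive runs fast and is overridable). All
randomness flows from the single configured seed.

Problem sizes used by the package's own validation runs (tests and the
acceptance script): an 8-genome clade of 15.5 kb molecules for the full
pipeline; 200 replicate 10 kb pairs for K2P estimator recovery; 5000-codon
genes, three replicate pairs, for neutral Ka/Ks recovery. These sizes give
estimator standard errors well inside the asserted tolerances while
keeping a full validation run in the low minutes on one CPU.
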