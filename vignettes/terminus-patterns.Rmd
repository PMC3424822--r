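---
title: "cDNA terminus patterns: model, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cDNA terminus patterns: model, scoring and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estclean)
```

## The problem

A raw Sanger EST read is not a cDNA sequence. It is a plasmid-vector
fragment, a cloning adapter, a restriction-enzyme recognition site, the
insert itself, a poly(A) or poly(T) tail, and more vector — in an order
fixed by the library-construction protocol. Conventional cleanup tools trim
vector and low quality but never ask whether the *arrangement* of these
elements makes sense. estclean does: it reconstructs the arrangement (the
read's *terminus pattern*), and uses it both to delimit the bona fide
insert and to recognise reads whose arrangement can only be explained by a
wet-lab accident.

## The terminus model

For a directional EcoRI/XhoI library, four canonical termini delimit the
insert, read in the 5'→3' direction of the raw sequence:

* `5TSS` — vector border `VF1` + `GAATTC` (EcoRI) + adapter `GGCACGAGG`;
* `3TSS` — poly(A) + `CTCGAG` (XhoI) + vector border `VF2`;
* `5TNS` — `VF2'` + `CTCGAG` + poly(T) (the 3' read's left end);
* `3TNS` — `CCTCGTGCC` + `GAATTC` + `VF1'` (the 3' read's right end),

where `X'` is the reverse complement of `X`. Real reads frequently carry
only parts of these structures, so each family expands into sub-variants
(`3TSS-1` = poly(A)+XhoI, `3TSS-3` = poly(A) alone, `5TNS-4` = `VF2'` + a
single `C` replacing the XhoI site + poly(T), and so on — see
`terminus_table(default_protocol())`). Sub-variant composition for
`5TSS-1/5TSS-2/3TNS-2/3TNS-5` is inferred from the abnormality signature
table and the canonical layouts rather than spelled out anywhere
explicitly; the inferred table is the package's reading and can be
overridden through the protocol configuration.

A read's **pattern** is the left-to-right sequence of disambiguated
terminus names interleaved with context tokens: `V` for vector, `N` for
non-vector, refinable to `HV/LV/HN/LN` by sequence quality. `5TSS,N,3TSS`
is a healthy short-insert 5' read; `5TSS-2,V,3TSS-2` is a vector that lost
neither enzyme site and contains no cDNA at all.

## Confidence scoring

Each detected terminus gets three sub-scores on a 0–100 scale, combined as
a weighted sum (default weights 1/3 each; the source protocol fixes the
functional form but not the weights, and with no basis for preferring any
component the uniform simplex point is the default):

* **A (completeness)** — `100 × (components present) / (components of the
  family's canonical terminus)`. Single-base stand-ins (the `G`/`C` of the
  replaced-site variants) count zero, which keeps exactly one maximal
  definition per family.
* **B (context)** — each flank is compared with what the protocol expects
  there (vector on the vector-facing side, non-vector on the insert side):
  match 100, low-quality mismatch 50, high-quality mismatch 0, averaged
  over both flanks. The stated rule covers only the upstream flank of
  `5TSS`; applying it symmetrically to both flanks of every family is this
  package's generalisation. A flank that ends at the read boundary, or
  that is occupied by a *different, non-overlapping* terminus, is neutral
  (100): an abutting foreign terminus is neither vector nor insert, and
  punishing it would systematically favour truncated sub-variants in
  adapter-concatenation layouts.
* **C (base match)** — `100 × matched bases / terminus length`.

Overlapping variants at one locus are resolved after scoring: a same-family
hit wholly contained in a fuller variant is treated as a fragment of it and
dropped first (completeness marks the authentic terminus); among the rest
the highest confidence wins, with ties broken by completeness, then
leftmost-longest, then name — fully deterministic.

## Abnormality classification

Restriction-enzyme cutting abnormalities (RECA) are recognised by exact,
direction-specific pattern templates (types A1–A3, B1–B2, C, D, E, F), the
frequent abnormal cases (1–8) by templates honouring their optional leading
context and repetition notation, double-termini adapters (DBT) by their two
24-base concatenation motifs, and direction conflicts by a read carrying
only the other direction's terminus families. When several apply, the
primary call follows the precedence RECA > DBT > frequent case >
direction-conflict, with the rest kept as secondary annotations. Two
template-matching choices are the package's own:

* the type-F signature (`V,N` / `N,V`) is accepted only when the vector
  alignment falls within 200 bases of the EcoRI-side cloning border, since
  type F is EcoRI cutting the vector elsewhere — without this check any
  read beginning in vector would be called F;
* a pattern with a `V` token strictly between two termini that matches no
  template is reported `RECA-other` (retained vector between termini is
  the RECA hallmark).

A DBT inside a valid `5TNS…3TNS` span of a 3' read is an internal
concatenation: the insert is recovered by excising the DBT. Any other DBT
marks a chimera and the read is filtered. Termini wholly contained inside a
DBT hit are suppressed — the DBT's own adapter/enzyme components would
otherwise masquerade as termini — while termini merely overlapping one
(as in adapter-insertion layouts) are kept.

## Trimming

Reads with a RECA call or a chimeric DBT are filtered outright; the insert
in such reads cannot be delimited unambiguously. Otherwise the best
*reasonable pair* — a direction-consistent (5'-family, 3'-family) pair, in
order, separated by at least 200 bases, maximising the summed confidence —
delimits the insert; both ends then shrink past overlapping vector
alignments and low-quality segments, and survivors shorter than 100 bases
are rejected. When no pair exists but exactly one terminus was found *and*
its family matches the read's designated direction, a fallback trims from
its inner edge to the read's far quality/vector boundary. This fallback is
an explicit extension: pair selection alone would discard every read whose
insert is longer than the read, which is the common case in practice. Reads
with two or more unpaired termini, or a direction-conflicting one, are
filtered as undecidable; reads with no terminus at all are emitted
clean-untrimmed (quality/vector trimming only) under an explicit warning
category rather than silently dropped.

## Detection parameters

| parameter | default | rationale |
|---|---|---|
| quality window / threshold | 20 bases, Q16 | standard Sanger sliding-window practice; the segmentation algorithm is unspecified upstream, so the package uses window means with per-base boundary refinement, which is deterministic and segments clean transitions exactly |
| poly-tail | ≥ 8 bases, ≤ 10% interior impurity | no threshold is stated upstream; single-base interior miscalls merge, multi-base gaps do not |
| vector match | ≥ 20 bases at ≥ 94% identity | cross_match-style local alignment defaults; implemented as exact 12-mer diagonal seeding with ungapped X-drop extension and a banded local alignment for gapped candidates |
| enzyme sites (6-mers) | exact in the global scan | a 1-mismatch 6-mer anywhere is noise |
| enzyme rescue | 1 mismatch, context-restricted | a degraded enzyme site flanked on *both* sides (within the component gap) by other detected terminus elements or vector alignment is accepted; restores scoring-relevant sites lost to sequencing error without global false positives |
| adapters (9-mers), DBT (24-mers) | 1 mismatch | long enough to stay specific |
| component gap | ≤ 2 bases | tolerates one or two ambiguous calls between components |
| pair separation | ≥ 200 bases | a shorter gap cannot contain a meaningful insert |
| min clean length | 100 bases | applies after trimming on both the pair and fallback paths; the 200-base rule governs pair separation only |
| context rule | ≥ 50% coverage | the four context labels are named upstream without quantitative rules; majority coverage is this package's choice |

All of these are arguments of `est_params()`.

## Coordinates

All intervals, internal and reported, are 1-based inclusive — the R and
Bioconductor convention (`IRanges`, `Biostrings`), and the convention of
per-read displays in this field's tools. Using one convention end to end
removes an entire class of off-by-one errors at the cost of none.

## The synthetic-read generator

`make_construct()` assembles reads segment by segment for every supported
layout: the expected construct (both directions), all nine RECA types (both
directions), both chimeric DBT concatenations, the internal-DBT rescue
layout, and the eight frequent abnormal cases, each with an exact segment
map and the true clean interval. `generate_dataset()` draws a labelled
mixture (default: equal shares of the 18-layout mix in `est_layouts()`)
and applies the noise model.

Inserts are uniform random DNA at GC 0.45 — typical for plant ESTs — and
are *rejected-and-resampled* until free of enzyme/adapter motifs,
detectable poly runs, and any 12-mer shared with the vector; junctions
against planted poly tails are guarded and runs assembled across segment
junctions are disrupted. These constraints exist so that the recorded truth
is the *only* valid reading of each read: recovery failures then measure
the pipeline, not generator ambiguity. The incompatible-sticky-end junction
of the A2/B2 layouts carries a random spacer of 3–15 bases (described
upstream only as "some uncertain random sequences"). Poly tails are 20
bases; the retained-vector fragment of type F ends 10 bases inside VF1, so
no border element survives at the junction, matching the wrong-site-cut
mechanism. The bundled 2.7-kb vector is synthetic (a pBluescript-like
stand-in with the same cloning-site architecture; the real sequence is not
redistributable from text sources), with `VF1`/`VF2` defined as the 50
vector bases flanking the cloning sites — long enough for confident
alignment, short enough for Sanger read ends, and configurable.

The noise model applies per-base substitutions and indels at uniform rates
and a Sanger-shaped quality profile (low start, high plateau, slow tail
decay). Two simplifications matter for interpreting results: quality values
are *not* coupled to the injected error positions, and the default profile
never crosses the low-quality threshold, so low-quality trimming is
exercised by explicit quality vectors in the unit tests rather than by the
generator. Passing the round-trip experiments therefore demonstrates
correctness of detection, classification and trimming logic under clean
and uniformly-noisy reads — not performance on real chromatogram-derived
quality tails, mixed-quality chimeras, or vectors with repetitive content.

## Experiment sizes

The bundled experiments use 1,800-read mixtures (100 reads per layout, the
18-layout mix) for the zero-error and 1%-substitution round-trips, and
10,000 random sequences with planted motifs for the scanner/oracle
equivalence checks; `scripts/acceptance.R` recomputes all of them from a
single seed.

## Known limitations

* Protocols are limited to two restriction enzymes and one adapter pair;
  the element table cannot express more exotic cloning designs.
* RECA templates are matched exactly; a RECA read whose pattern is
  perturbed by an extra noise-induced token degrades to `RECA-other` or to
  no call rather than to the nearest template.
* Chimeric DBT reads are filtered, not split into their two inserts.
* Quality must arrive as FASTA+QUAL; chromatograms (SCF/ABI) are out of
  scope.
* Whether upstream practice classified quality base-wise or window-wise,
  and whether its B score used one flank or two, is unrecorded; this
  package's choices are documented above and in the parameter table.
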