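# estclean

Pattern analysis and cleanup of raw Sanger EST reads.

A raw expressed sequence tag (EST) read is a composite: plasmid-vector
borders, a cloning adapter, restriction-enzyme recognition sites, the cDNA
insert, a poly(A)/poly(T) tail — in an order dictated by the
library-construction protocol. estclean reconstructs that arrangement for
each read (its **cDNA terminus pattern**), uses it to cut out the bona fide
insert, and — unlike quality/vector trimmers — recognises reads whose
arrangement can only be explained by a wet-lab accident: restriction-enzyme
cutting abnormalities (RECA), double-termini adapter (DBT) chimeras,
replaced-site artifacts, and reads sequenced in the direction opposite to
their designation. It is written for people curating Sanger EST collections
(or auditing what older pipelines deposited in public databases) and for
anyone who needs a fully synthetic, ground-truthed EST read simulator to
test cleanup pipelines against.

## The model in brief

For a directional EcoRI/XhoI library, four canonical termini delimit the
insert in a raw read: `5TSS` = VF1 + GAATTC + GGCACGAGG, `3TSS` = poly(A) +
CTCGAG + VF2, and their reverse-complement counterparts `5TNS`, `3TNS` on
3'-end reads (VF1/VF2 are the vector borders flanking the cloning sites).
Each family expands into partial sub-variants (`3TSS-3` = poly(A) alone,
`5TNS-4` = VF2' + C + poly(T), ...). Every detected terminus is scored

    Confidence = w_A · A + w_B · B + w_C · C,    w_A = w_B = w_C = 1/3

with A = completeness (components present / components of the canonical
terminus, ×100), B = flank context (expected context 100, low-quality
mismatch 50, high-quality mismatch 0, averaged over both flanks), and C =
matched bases / terminus length ×100. The read's pattern — terminus names
interleaved with `V` (vector) / `N` (non-vector) context tokens — is then
matched against abnormality templates (e.g. `5TSS-2,V,3TSS-2` = neither
enzyme site cut, no cDNA; `N,3TNS-1,V,3TSS-2` = insert ligated in
inverted orientation). Clean reads are trimmed between the best
*reasonable pair* of termini (direction-consistent, in order, ≥ 200 bases
apart, maximal summed confidence), shrinking ends past vector and
low-quality sequence.

See `vignette("terminus-patterns")` for the full model, parameter table and
design choices.

## Worked example

Simulate a 300-read mixed library (every supported construct layout, 1%
substitution noise), run the full pipeline, and summarize:

```r
library(estclean)
protocol <- default_protocol()          # EcoRI/XhoI, bundled demo vector
sim <- generate_dataset(n = 300, sub_rate = 0.01, seed = 7,
                        protocol = protocol)
reports <- process_reads(sim$reads, protocol)
reports[1:3, c("id", "direction", "pattern", "primary_call",
               "outcome", "clean_start", "clean_end")]
#> # A tibble: 3 × 7
#>   id                direction pattern primary_call outcome clean_start clean_end
#> 1 expected_00001.g… 5'        5TSS,N… <NA>         clean            66       466
#> 2 RECAD_00002.g1_S  5'        N,3TNS… RECA-D       filter…          NA        NA
#> 3 RECAA2_00003.g1_S 5'        5TSS,N… RECA-A2      filter…          NA        NA
summarize_reports(reports)
#> <est_summary>
#>   n_reads n_with_termini pct_with_termini n_clean n_filtered n_abnormal pct_abnormal
#> 1     300            285               95      78        222        272        90.67
#>
#> Top patterns:
#>                 pattern  n   pct
#> 1           5TNS,N,3TNS 32 10.67
#> 2                5TSS,N 25  8.33
#> 3   N,3TSS-3,N,3TSS-3,N 25  8.33
#> 4       5TSS-2,V,3TSS-2 22  7.33
#> ...
```

Read 1 is a healthy 5' read (`5TSS,N,3TSS`): its insert is positions
66–466, i.e. everything between the inner edges of the two termini. Read 2
carries retained vector between two inverted-insert termini (RECA type D)
and read 3 an insert ligated at the un-recut EcoRI site (type A2) — both
are filtered because their true insert cannot be delimited unambiguously.
In the summary, `pct_with_termini` is the fraction of reads with any
detectable terminus, and the per-category tables count primary calls
(this simulated mixture is deliberately abnormality-heavy; real libraries
are mostly `expected`).

From a shell, the same pipeline runs as

```sh
Rscript inst/cli/estclean.R simulate --n 300 --seed 7 --out-dir sim/
Rscript inst/cli/estclean.R trim --fasta sim/reads.fasta --qual sim/reads.qual --out-dir out/
```

writing `report.tsv` (one row per read, 1-based inclusive coordinates),
`clean.fasta`, summary TSVs and a per-read annotated text dump.

Per-read evidence is kept in the report's list-columns (`termini` with all
A/B/C sub-scores, `tokens`, `dbt`); `plot_read_map(reports, id)` draws a
read's token map and `autoplot(summarize_reports(reports))` the category
tallies.

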