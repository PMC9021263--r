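# castsv — Cas9-assisted targeted nanopore typing of structural variants

Whole-genome optical mapping finds structural variants (SVs) economically,
but only as kilobase-resolution intervals: it cannot say where a breakpoint
falls at base precision, what sequence was inserted, or — without further
work — confirm a genotype. `castsv` implements the computational pipeline
around a targeted assay that closes that gap: SpCas9 guide pairs are
designed to excise a small fragment spanning each SV's diagnostic junction,
the fragments are amplified and sequenced on a nanopore flow cell, and the
breakpoints and genotypes are resolved from split-read and soft-clip
patterns in the alignments.

The package is for people who have an SV call set (BED or a minimal
SMAP-like table) and a reference genome, and want to (a) design per-SV
guide panels and synthesis oligos, (b) know in advance what fragment each
allele should produce and how it should align, and (c) turn targeted-read
alignments into base-precise breakpoint calls, genotypes, and a VCF. A
seeded simulator with exact truth alignments makes the whole loop testable
without any sequencing data.

## The model in brief

For a deletion with optical interval `[s, e]`, three guides acting as two
pairs share the 5′ anchor A: the A–B pair cuts the undeleted haplotype into
a fragment of known length (target 3.5 kbp, an internal control), while the
A–C pair spans the deletion and yields, on the deleted haplotype, a
shorter fragment of unknown length `d(A,C) − L_del` whose alignment shows a
5′ match, a reference gap, then a 3′ match. The 5′ breakpoint is the last
aligned base of the 5′ segment, the 3′ breakpoint the first aligned base of
the 3′ segment, aggregated as medians across supporting reads.

For an insertion, a flank guide plus a guide designed on a mobile-element
consensus (e.g. LINE-1) produce a fragment `(b − cut_A) + offset` whose
reads align up to the insertion point `b` and are soft-clipped beyond it;
the clipped-tail consensus is aligned back to the element consensus for
confirmation (identity ≥ 0.80 over ≥ 200 bp).

For an inversion with junctions `(s, e)`, a flank cut at `f < s` and an
internal cut at `p` near `e` come together on the inverted allele into a
fragment of length `(s − f) + (e − p)` (target 6.5 kbp) that aligns as one
reference-orientation and one inverted-orientation segment; each segment's
boundary away from its anchoring cut estimates a junction. Genotypes are
presence/absence of allele-class support (≥ 3 reads), deliberately without
an allele-balance test. Under PCR enrichment every designed product must
stay under 30 kbp; oversize targets are rejected at design time.

## Worked example

The bundled toy study is a 200-kbp contig with a het 13.2-kbp deletion, a
hom 6-kbp element insertion and a hom 30-kbp inversion, all generated from
a seed:

```r
library(castsv)
toy <- toy_genome(42)
res <- run_typing_workflow(toy$ref, toy$catalog, toy$applied, toy$element,
                           pipeline_config(), seed = 7, outdir = "out")
res$calls$del1
#> <breakpoint_call> del1 (deletion): genotype het, support ref=20 alt=20
#>   5p breakpoint ctg1:60,000 [high]
#>   3p breakpoint ctg1:73,201 [high]
#>   sv_length: 13200 bp
res$calls$ins1
#> <breakpoint_call> ins1 (insertion): genotype hom_alt, support ref=0 alt=40
#>   insertion breakpoint ctg1:120,000 [high]
#>   inserted consensus: 5866 bp
#>   flags: element_confirmed
res$calls$inv1
#> <breakpoint_call> inv1 (inversion): genotype hom_alt, support ref=0 alt=40
#>   junction_5p breakpoint ctg1:150,000 [high]
#>   junction_3p breakpoint ctg1:180,000 [high]
#>   sv_length: 30000 bp
```

The deletion was applied at 0-based [60000, 73200), so the reported
1-based breakpoints (last retained base 60,000; first retained base
73,201) are exact, as are the insertion point (last base before the insert,
120,000) and both inversion junctions; support counts are reads per allele
class, and `het` follows from both classes clearing the 3-read threshold.
`out/` holds the guide panel, expected fragments, simulated FASTQ, truth
SAM, `calls.vcf` and `report.tsv`.

The same stages run from the shell over files:

```sh
Rscript inst/cli/castsv.R end2end --seed 7 --outdir out
Rscript inst/cli/castsv.R design --reference ref.fa --sv-table svs.bed --element l1.fa
Rscript inst/cli/castsv.R call   --reference ref.fa --sv-table svs.bed \
        --alignments reads.bam --outdir out
```

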