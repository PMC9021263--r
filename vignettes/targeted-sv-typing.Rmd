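---
title: "Targeted typing of structural variants with Cas9-directed nanopore sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted typing of structural variants with Cas9-directed nanopore sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castsv)
```

## The problem and the assay

Whole-genome optical mapping detects structural variants (SVs) cheaply and
at long range by comparing motif-label spacing between a sample's assembled
maps and a reference, but its label resolution is on the order of
kilobases: it yields an interval and an SV class, never a base-precise
breakpoint. Conversely, whole-genome long-read sequencing resolves
breakpoints but is expensive when only a handful of loci matter.

`castsv` implements the computational side of a hybrid strategy: take SV
intervals discovered by optical mapping, design SpCas9 guide RNA pairs that
excise a small fragment spanning each SV's diagnostic junction, amplify and
sequence those fragments on a low-throughput nanopore flow cell, and
resolve base-level breakpoints and genotypes from the read alignments. The
wet-lab chemistry (end blocking, cleavage, ligation, PCR) is out of scope;
its consequences enter the model only as simulator parameters (on-target
fraction, per-allele read weights, amplicon error rates).

## Coordinate conventions

All internal coordinates are 0-based half-open; every user-facing number —
printed calls, VCF, report tables — is 1-based inclusive. The single
conversion point is `to_report_coords()`; no other code adds or subtracts
one. Cas9 cut sites are 0-based *inter-base* coordinates: a cut at `c`
falls between bases `c` and `c + 1` in 1-based terms. The blunt cut is
placed 3 nt 5&prime; of the NGG PAM, the canonical SpCas9 geometry.

Breakpoint reporting follows VCF conventions: a deletion is reported by its
last retained 5&prime; base and first retained 3&prime; base; an insertion
by the last reference base before the inserted sequence; an inversion by
the last base before the inverted block and the last inverted base.

## Guide design per SV class

Candidate protospacers are all 20-mers adjacent to NGG on either strand
(`find_protospacers()`), screened for GC fraction in [0.25, 0.75],
homopolymer runs of at most 5, and genome-wide uniqueness of the
spacer+PAM 23-mer by exact matching on both strands (`screen_guides()`).
Exact-match uniqueness is a deliberate desk-scale simplification: no
mismatch-tolerant off-target scoring is attempted, which is adequate for
selecting among abundant candidates in non-repetitive flanks but will not
rank guides inside repeats — a known limitation.

Class-specific geometry:

* **Deletion** — three guides acting as two pairs sharing the 5&prime;
  anchor A. A cuts within `[start - w_out, start + w_in]`; interior
  placement (`w_in` = 4 kbp by default) is allowed because optical-map
  intervals over-extend past true breakpoints by label resolution. The
  internal guide B is chosen so the A–B reference-allele fragment is
  closest to `ref_fragment_target` (3.5 kbp): on the undeleted haplotype
  the pair yields a fragment whose expected length is *known*, an internal
  positive control. The 3&prime; guide C cuts just past the interval,
  minimizing the A–C span; on the deleted haplotype B's site is gone and
  A–C yields a shorter fragment of unknown length carrying both junctions.
* **Insertion** — with a mobile-element consensus (e.g. a LINE-1
  consensus), one flank guide 5&prime; of the locus plus one guide chosen
  from the consensus, expected to cut only inside element copies; the
  element guide's reference cut position is undefined and its consensus
  offset is recorded. It is chosen as deep into the element as the PCR
  bound allows, to capture the longest confirmable inserted prefix.
  Without a consensus, a flank pair is used and the expected mutant
  fragment (reference span + estimated inserted length) must stay under
  the PCR bound — which is exactly what limits the insertion sizes this
  mode can target.
* **Inversion** — one guide in the 5&prime; flank at `f`, one inside the
  inversion near its 3&prime; end at `p`. In the inverted sample the
  internal site is carried next to the flank site, producing a fragment of
  length `(start - f) + (end - p)`, targeted at 6.5 kbp; on the reference
  allele the same two cuts are tens of kilobases apart and yield no PCR
  product, so the assay reads out the inverted allele specifically.

Among feasible candidates the designers minimize distance to the target
fragment length, breaking ties by distance to the nearest reference N and
then by the leftmost coordinate, so designs are deterministic.

Under PCR mode (default) every designed product must lie within
`[min_fragment, max_fragment]` = [1, 30] kbp, reflecting the extension
limit of long-range PCR; `pcr_mode = FALSE` lifts the bound for PCR-free
protocols. Synthesis oligos are emitted as the fixed 55-mer layout: 21-nt
T7 promoter + 20-nt spacer + 14-nt overlap, with a single scaffold oligo
shared by all guides (stored verbatim as printed in the protocol source;
its stated "80 base" length corresponds to a 79-nt printed sequence, which
is kept as-is).

## Expected fragments and alignment signatures

`predict_fragments()` turns a guide set into per-allele expected fragments
with an alignment signature each: `contiguous` (reference-allele product),
`gapped_two_segment` (deletion allele: 5&prime; match, reference gap,
3&prime; match), `clipped_tail` (insertion allele: aligned flank +
soft-clipped inserted prefix), `inverted_dual` (inversion allele: one
reference-orientation and one inverted-orientation segment anchored at
opposite junctions). Deletion-allele lengths are reported with an upper
bound (`span - min_del`) because the true deleted length is unknown before
sequencing; the point estimate uses the optical interval. Digestion
(`digest_sequence()`) is exact partitioning — circular molecules and cuts
at sequence ends are rejected rather than producing zero-length fragments.

## The synthetic-data engine

`apply_svs_to_reference()` builds two haplotypes (het SVs on haplotype 2
only, hom on both) together with exact block-level liftover maps, so
ground-truth alignments can be computed rather than guessed.
`simulate_reads()` implements an amplicon model: on-target reads are whole
fragments between consecutive cut sites on the sampled haplotype — the
protocol amplifies and sequences entire cut fragments, so no shearing or
length distribution is modelled for targets. Per-base errors are i.i.d.
substitutions/insertions/deletions at 0.03/0.02/0.04 by default,
a nanopore-like regime chosen as a conservative stand-in since the source
protocol reports no error rates. Background reads ("blocking leakage")
default to 30% of the total with log-normal lengths (median 2 kbp);
residual background after end-blocking is not quantified in the source
either, so 30% is a deliberately pessimistic choice. Per-haplotype
sampling weights can reproduce extreme allele imbalance (the assay's
per-allele cut efficiencies differ wildly; a real het call was supported
171× on one allele and 5× on the other).

`emit_truth_alignments()` converts each read's haplotype interval into
reference-space SAM records through the liftover: deletions appear as a
CIGAR `D` when the deleted span is at most `split_threshold` (10 kbp,
chosen so that deletions in the assay's typical 13-kbp class exercise the
split-read representation) and as SA-linked primary + supplementary records
above it; insertion tails become soft clips; inverted blocks become
opposite-strand record pairs. `NM` is defined as the simulated edit count
within each record's aligned span. This replaces an external aligner for
testing; real data aligned with minimap2 enters through the same
`load_alignments()` surface (SAM/BAM via Rsamtools, PAF with `cg` tags).

What the simulator deliberately does *not* emulate: basecaller-specific,
context-dependent error profiles (homopolymer compression above the i.i.d.
deletion rate), PCR chimeras and length bias, partial digestion, and real
repeat structure around breakpoints. Passing tests therefore demonstrate
that the geometric conventions and evidence extraction are correct and
robust to uniform noise — not that the caller survives every pathology of
real nanopore data; the alignment-ingest surface is where a real aligner's
quirks would enter.

## Breakpoint calling

Reads are grouped per query, linked across supplementary records, and
assigned to the target whose designed cut lies within `tol` (100 bp) of any
segment boundary. Per class:

* **Deletion** — evidence is a within-segment deletion op of at least
  `min_del` (1 kbp) or two same-strand segments with a reference gap of at
  least `min_del` that are adjacent in read coordinates (`adj_tol` =
  50 bp). A positive read-coordinate gap is tolerated when those bases are
  soft-clipped in both records — the unaligned-wedge situation that arises
  when novel sequence faces a reference N gap — and downgrades the
  resumption side to low confidence; N runs of 10+ inside the called gap
  set the `reference_N_gap` flag. Breakpoints are per-read junction
  positions aggregated by median with ties toward the smaller coordinate
  (the aggregation rule is this package's choice; single positions are
  what the assay ultimately reports).
* **Insertion** — the breakpoint is the last aligned base before the
  soft-clipped tail (at least `min_clip` = 200 bp), median across reads;
  the tails give a plurality consensus (`clipped_consensus()`, columns
  under `cons_min` = 2 coverage emitted as N). When an element consensus is
  supplied, the call is flagged `element_confirmed` at local-alignment
  identity ≥ 0.80 over ≥ 200 columns — first attempted on the tail
  consensus, then, if that fails, on the longest individual tails (a
  majority of up to five must confirm). The fallback matters because a
  per-column plurality consensus loses phase beyond a few dozen bases once
  reads carry indel errors, while each read individually still aligns to
  the element at its raw accuracy; confirming at read level is also how
  the assay itself validates inserted sequence. The columnar consensus is
  still reported, and is exact when reads are indel-free. Breakpoint
  placement is VCF-compatible: the base *before* the insert.
* **Inversion** — requires groups with opposite-strand segments; each
  segment is anchored to its nearest designed cut and contributes the
  boundary *away* from that anchor as a junction estimate. When the
  reference inward of the two called junctions is near-identical in
  inverted orientation (identity ≥ 0.90 over the 5-kbp `rep_span`), the
  call is flagged `inverted_repeat_ambiguity` and left ambiguous rather
  than silently resolved — dual placements are intrinsic to inverted
  repeats, not an error to suppress.

Genotyping is presence/absence per allele class at `min_support` = 3 reads,
deliberately without an allele-balance requirement: per-allele cut and
amplification efficiency in this assay vary by orders of magnitude, so
balance would destroy valid het calls. Calls below support become
`no_call`; nothing is emitted on thin evidence. Insertion calls can be
validated by `build_custom_reference()`, which splices the called
consensus into the reference so that true insertion reads re-align
contiguously.

`local_align()` (Smith–Waterman, affine gaps; match 2, mismatch −4, gap
open −4, extend −2, a gap of length L costing open + L·ext) backs the
element confirmation and the inverted-repeat check; the test suite verifies
it against an independent quadratic dynamic-programming oracle.

## Configuration, outputs and reproducibility

All thresholds live in one validated configuration (`pipeline_config()`;
YAML on disk via `load_config()`, unknown keys rejected). YAML was chosen
as the configuration format as the de-facto standard for R pipeline
tooling in this environment. Outputs are standard formats: guide panel and
report TSVs, expected-fragment TSV, FASTQ/SAM from the simulator, and VCF
4.2 with symbolic `<DEL>/<INS>/<INV>` alleles, `END/SVLEN/SUPPORT/BPCONF`
INFO keys and `LowConf` filtering. Every stochastic stage takes an explicit
seed and is bitwise reproducible.

## Problem sizes used in the checks

The bundled study (`toy_genome()`) is a 200-kbp contig carrying a het
13.2-kbp deletion, a hom 6-kbp synthetic-element insertion and a hom
30-kbp inversion — one SV per supported class at assay-typical sizes, kept
at a scale where the whole design → simulate → call loop runs in seconds.
Recovery experiments use 50 seeded replicates per class on 30–60-kbp
single-SV references at default error rates, asserting breakpoints within
±10 bp in at least 90% of replicates; the feasibility panel
(`feasibility_panel()`) places candidate targets spanning 1–60 kbp on a
200-kbp reference to exercise the PCR bound, including targets that must be
rejected. These sizes are the package's chosen desk-scale study
conditions; the algorithms have no dependence on them.

## Known limitations

Off-target screening is exact-match only. The insertion caller reports the
junction it can see from clipped tails on one side; a second junction (and
target-site duplication) would need reads from the other flank. Inversion
calls assume the two designed cuts anchor the observable segments; nested
or complex rearrangements are out of scope, as are translocations and
duplications (cataloged but not designed for). Genotypes reflect fragment
presence, not dosage.
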