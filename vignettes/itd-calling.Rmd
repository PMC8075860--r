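---
title: "Calling internal tandem duplications in amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling internal tandem duplications in amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandup)
```

## The variant class and the assay model

An internal tandem duplication (ITD) inserts a copy of an adjacent
reference segment head-to-tail: the allele is
`ref[0:j] + ref[d:j] + ref[j:]` for a duplicated segment `[d, j)`.
`tandup` analyses reads from a PCR amplicon covering the affected
region (for *FLT3*, exons 14–15), aligned against the wild-type
amplicon sequence — not a genome. All coordinates are 0-based; an
insertion "at position p" sits between `ref[p-1]` and `ref[p]`, and
intervals are half-open. Because a duplication in periodic sequence
context admits several equivalent descriptions, reported calls are
left-aligned (`canonical_dup_site()`), so identical variants always get
identical coordinates and insert sequences.

The pipeline is: FASTQ → mean-quality filter → mate orientation →
unique-sequence collapsing → alignment → insert extraction → tandem
verification → clone merging → quantification → filtering. Each
distinct read sequence is aligned once and its result weighted by
multiplicity, which is what makes million-read amplicon samples cheap:
an error-free deep sample collapses to a handful of distinct sequences.
Every step is deterministic, so a rerun on the same input is
byte-identical.

## Alignment

Reads are aligned semi-globally with affine gap penalties and free end
gaps on both sequences: the read may map anywhere inside the amplicon,
and read sequence that cannot be aligned (the far side of a long
duplication's junction) is clipped as a free overhang rather than
forced into the alignment. Internally this "free ends" contract is
realised as a local (clip-optimal) alignment.

The scoring defaults required some care, because two pressures pull in
opposite directions:

* the insert of a true ITD must surface as **one contiguous gap run**
  that beats end-clipping whenever at least `min_insert_length` (6)
  anchoring bases follow it. Clipping gains `match × flank` relative to
  gapping, so the gap cost for *any* insert length must stay below
  `match × min_insert_length = 30`. Hence `gap_open = 29`,
  `gap_extend = 0`: every insert costs a flat 29, one point under the
  minimum anchor's reward, whatever its length;
* the unalignable tail of a trailing read is effectively random with
  respect to the downstream reference, and an optimal aligner with
  cheap gaps will happily chain lucky match islands across long
  bridges, corrupting the clipped structure. The harsh mismatch penalty
  (−15) makes such mosaics unprofitable in all but rare island
  configurations.

Those rare configurations are why alignment is not left to the dynamic
program alone. Reads are first placed by three unique 25-mer seeds
(read start, middle, end) looked up in a precomputed index of the
reference:

* one placement diagonal → the read is reference-like; it is scored
  ungapped with optimal end-clipping, accepted if it has at most
  `fast_max_mismatch` (2) mismatches — a placement that provably beats
  any gapped alternative under the default scoring;
* two diagonals with the tail diagonal upstream → the tandem-duplication
  signature. The duplication length is the diagonal difference, exact
  by construction and immune to island chaining; only the junction
  split is optimised. The read is emitted as a single-gap-run alignment
  (insert fully contained) or as a clipped alignment whose overhang
  carries the trailing insert;
* anything else (no seeds, conflicting seeds, deletion-like offsets)
  falls back to the full dynamic program.

The full dynamic program is itself exercised against an independent
brute-force Gotoh implementation on hundreds of random short pairs in
the test suite, and the fast paths are tested for score equality
against it.

Alignments scoring under `min_score_fraction` (0.5) of the read's
maximum achievable score are discarded as off-target. Overhang bases
contribute nothing to the score, so with the default fraction a
trailing read keeps support as long as its anchored half reaches half
the read — consistent with the geometry that makes an ITD trailing in
the first place.

## Insert extraction and tandem verification

Candidates are maximal reference-row gap runs of at least
`min_insert_length` bases (internal inserts) and read-end overhangs of
at least that length (trailing candidates). Deletions are never
candidates — the method targets duplications. Discarding sub-minimum
read-end inserts is what bounds the longest detectable duplication at
`read_length − min_insert_length` (244 bp at 250 bp reads).

A candidate becomes an ITD call only if its sequence matches a
reference window at identity ≥ 1 − `tandem_max_mismatch_fraction`
(default 10 %, tolerating ITDs that carry point mutations or
non-templated junction bases) positioned so that insert and window form
a tandem. For internal inserts the upstream window is tested first,
then the downstream one (shifts ordered 0, +1, −1, … up to
`merge_site_tolerance`); a candidate whose only matches are
non-adjacent is reported in the non-ITD insertions table instead. Calls
are canonicalised to the upstream-copy representation (insertion site =
end of the duplicated segment), so the aligner's gap-placement choice
cannot split one variant into two.

For trailing inserts only a portion of the duplication is sequenced.
Any sufficiently matching upstream window is tandem-compatible, and the
length is estimated as the offset between the copies
(`ref_pos − window_start` for a 3' overhang). Among equally good
windows the smallest estimate wins — the most parsimonious duplication.
These estimates are flagged non-exact; on simulated data they are
within 3 bp of truth (seed-placed reads recover the offset exactly).

## Clones and quantification

Calls merge into clones by transitive closure of a pairwise rule: same
evidence class (trailing vs non-trailing; a flag allows crossing),
identical length for non-trailing calls or estimates within 3 bp for
trailing ones, sites within `merge_site_tolerance` (2 bp), and
identical sequence over the overlap of the sequenced portions. Portions
are compared anchored at the duplication end they were read from, so
two trailing calls whose length estimates differ by a base still
compare the bases actually sequenced. The consensus insert is the
most-supported call's sequence.

Coverage at a site counts reads whose alignment spans both flanking
reference bases (the single existing base at the amplicon boundaries);
supporting reads span by construction and are always included. Then
`vaf = supporting_reads / coverage` and `ar = vaf / (1 − vaf)` — the
allelic-ratio scale used by fragment analysis, with the standard
inverse `vaf = ar / (1 + ar)`. The denominator counts *reads*, each
mate separately; whether to require support from both mates is a flag
(off by default, since a site near an amplicon end is visible to one
mate only).

Clone filtering keeps clones with `min_supporting_reads` (2) support
and applies no VAF floor: at amplicon coverage of 10⁵–10⁶ reads, a
fixed floor would forfeit exactly the 10⁻³–10⁻⁵ VAF range that makes
deep sequencing attractive for residual-disease monitoring. Filtered
clones are retained in an audit table with reasons.

Serial samples are matched clone-by-clone using exactly the
within-sample merge rule — a deliberately strict choice: a looser
cross-sample tolerance would let clone identity drift along an MRD
series. Matched clones are categorised `persisting` (first and last
timepoint), `lost`, `gained`, or `transient` (intermediate only; the
first three categories partition clones seen at either endpoint). A
caveat: clone tables store only the consensus insert, so cross-sample
matching treats it as prefix-anchored; for 5'-overhang-derived trailing
clones from paired-end data this is an approximation.

## The simulator and what it does (not) emulate

`simulate_reads()` emulates the assay's validation experiments:
alleles are the wild-type amplicon and ITD alleles built by exact
segment duplication (optionally with deterministic point changes in the
second copy); 250 bp reads are drawn either single-end from a common
offset chosen so every read spans the insertion site — making the
constructed read fraction of each allele exactly its expected VAF — or
as mate pairs from the allele ends. Mixtures are count-exact (rounded
counts; used for the deterministic VAF-recovery checks) or sampled
per-read (binomial noise, as in a real dilution). Substitution errors
are applied per base under a seed; qualities are constant Q37.
`simulate_dilution_series()` chains this into the classic serial
1:10 dilution, and `linearity_r2()` summarises measured-versus-expected
VAF by ordinary least squares.

Deliberately not modelled: PCR amplification bias and chimeras, indel
sequencing errors (substitution-dominated short-read chemistry; an
indel error model would mainly stress the 6 bp minimum-insert floor),
quality-score profiles, and primer artefacts. Passing simulations
therefore demonstrate the *algorithmic* properties — exact VAF
arithmetic, length/site recovery, specificity against substitution
noise, linearity — not robustness to amplification artefacts of real
libraries.

The packaged reference is a fixed 600 bp seeded-random synthetic
sequence (`synthetic_reference()`); analyses of real data must supply
the actual sequenced amplicon. Protein/transcript coordinate annotation
is an optional user-supplied lookup table, since amplicon boundaries
are assay-specific.

## Numerical and design choices

* **Problem sizes in the checks.** The validation script and acceptance
  tests use 10 × 50,000 reads for specificity, 100,000-read count-exact
  mixtures for VAF recovery, a 10⁶-read mixture for the
  67-per-million detection check, and 5 × 300,000 reads for dilution
  linearity — deep enough that the lowest dilution step still expects
  ~20 supporting reads, so detection there is signal, not luck.
* **Boundary rules.** All thresholds are inclusive (`≥`): a read at
  exactly the mean-quality threshold, an alignment at exactly the score
  fraction, and a clone at exactly the support minimum all pass.
* **Tie-breaks.** Unique-read collapsing orders by descending count
  then lexicographically; tandem windows are searched upstream before
  downstream, shifts 0, +1, −1, …; equal-identity trailing windows
  resolve to the smallest length estimate; consensus ties resolve
  lexicographically. All choices are documented so results are
  bit-stable.
* **Degenerate inputs.** Empty FASTQ files yield empty (but
  well-formed) outputs and exit status 0 — an ITD-negative sample is a
  valid result, not an error. `N`-containing reads are dropped at QC
  (an `N` inside a putative insert is unverifiable). The reference
  itself must be unambiguous A/C/G/T.
* **Known limitations.** Duplications longer than
  `read_length − min_insert_length` are undetectable by construction.
  Trailing lengths are estimates. Reads carrying both an ITD and a
  large deletion fall back to the dynamic program and may be dropped by
  the score filter. Non-tandem insertions are reported but not called.

```{r example}
ref <- synthetic_reference()
reads <- simulate_reads(ref, list(itd_spec(300, 126), "WT"),
                        counts = c(330, 670))
res <- detect_itds(reads = reads, reference = ref, sample = "pl21_like")
tidy(res)[, c("length_estimate", "exact_length", "trailing", "vaf", "ar")]
```

A 126 bp duplication cannot be spanned together with its wild-type copy
by a 250 bp read (2 × 126 > 250), so it is reported trailing with an
estimated length; the count-exact mixture is recovered at VAF 0.33.
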