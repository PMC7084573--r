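---
title: "Comparative super-enhancer analysis of a master TF cistrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative super-enhancer analysis of a master TF cistrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secistrome)
```

# The problem

Super-enhancers (SEs) are clusters of highly active enhancers that
concentrate transcription factors (TFs) and co-activators within a short
genomic span and dominate the regulation of cell-identity genes. A single
master TF — estrogen receptor alpha is the motivating example — can drive
SEs in several tissues, yet the collaborating TFs differ between tissues.
`secistrome` implements the complete comparative workflow for such a
question: given the master TF's ChIP-seq peaks and coverage in two cell
lines, plus collaborator cistromes, a genome, motif matrices and an
expression table, it calls SEs in each line, classifies SE constituents as
line-specific or shared, characterises their motif landscape and TF
co-occupancy, and asks whether SEs present in both lines drive similar
transcriptional output.

# Models and procedures

## SE calling

Peaks of the master TF closer than `stitch_gap_bp` (default 12,500 bp,
edge-to-edge, strict) are stitched into candidates. Each candidate's tag
density is reads per million mapped reads per base pair over the stitched
region. Candidates are sorted ascending and both axes scaled to `[0, 1]`
(`x` = rank/(n−1), `y` = density/max). SEs are the candidates strictly
above the discrete tangent point of a slope-1 line, i.e. above the index
minimising `y − x`. This discrete argmin is exactly equivalent to the
tangent construction for the convex rank curve and, unlike a fitted
tangent, is exactly testable against a brute-force enumeration — the test
suite verifies the equivalence on 1,000 random curves. Ties in `y − x`
(possible with integer counts) resolve to the largest index, so a flat
curve yields zero SEs; the tangent-point candidate itself is never an SE.
Only the master TF's binding density defines SEs; H3K27ac- or
Mediator-based definitions are out of scope.

## Quantification

Read densities are RPKM over `[summit − h, summit + h)` windows (default
`h` = 50 bp, window length 100 bp — the half-open reading of "±50 bp" was
chosen so windows have even length and downstream 30-bp bins tile evenly).
Coverage is consumed as bedGraph intervals whose value is a read count and
a separately supplied library size; a stored read interval counts fully
towards a window if it overlaps it by at least 1 bp. An alternative 5'-end
containment rule is available (`read_count_mode = "start"`) because
published pipelines differ on this point; overlap is the default.

## Constituent classification

A constituent is SHARED when a master-TF peak of one cell line overlaps
(≥ 1 bp) a peak of the other; overlapping groups merge into one shared
constituent whose summit is taken from the member with the higher own-line
summit RPKM (deterministic, favours the stronger signal). All other peaks
keep their line of origin. The RPKM ratio
`log2(RPKM_B + 0.1) − log2(RPKM_A + 0.1)` is used only as the heat-map
sort key, not as the cluster rule: an explicit ratio threshold would need
an arbitrary cut, whereas overlap is reproducible and matches how
peak-set intersections are usually counted. This was a genuinely open
design point; the overlap reading is the default and the sort key is
exported so a ratio-based reanalysis is possible.

## Motif engine

PWMs are probability matrices over (A, C, G, T) regularised with a 0.001
pseudocount; scores are summed log2-odds against a uniform background, both
strands, with N-containing windows skipped. Score thresholds are selected
per motif by a histogram heuristic: bin the top scores (0.5-bit bins) and
take the left edge of the rightmost local maximum that is markedly high —
at least twice the median bin height (empty bins included) and holding at
least two scores. The underlying published rule ("before the last markedly
high peak of the score distribution") is not algorithmically defined, so
this heuristic is an explicit stand-in; per-motif manual overrides take
precedence and are flagged `provenance = "manual"`. Enrichment uses a
binomial upper tail with the background hit fraction as the rate (the
practice of common known-motif scanners; a hypergeometric would treat the
background as a finite sample, which it is not here). A zero background
rate with target hits present is replaced by `1/(n_background + 1)`.
Motif distribution matrices count thresholded hits in 30-bp bins over
1.5-kb summit frames, assigning each hit by its centre
(`offset + floor(L/2)`).

## Annotation and expression

Each SE is extended ±100 kb around its centre. Among protein-coding genes
whose promoter (TSS −1000/+100, strand-aware — a common convention; the
source methods do not state a promoter extent) overlaps the window, the
highest-expressed (replicate-mean FPKM at the stated timepoint) is
assigned; ties go to the nearest TSS, then lexicographic id, making the
assignment order-independent. Without a promoter in the window the nearest
protein-coding gene with ≥ 1 FPKM is used. Expression classes compare the
two cell lines at their respective timepoints with pseudocount 0.1: a gene
is line-specific only if *every* cross-line replicate pair exceeds the
2-fold band strictly (a conservative reading of "between both replicates";
a replicate-mean variant is available via `replicate_rule = "mean"`).
Exactly-2-fold genes are therefore SIMILAR. In the orchestrated pipeline,
cell-line-specific SEs are annotated with their own line's expression;
shared-SE hulls are annotated with cell line A's (the choice is arbitrary
but deterministic, and the 2-fold classification that follows uses both
lines symmetrically).

# The synthetic scenario

`generate_scenario()` emulates the structure of the real two-cell-line
data so the whole pipeline can be exercised with planted truth and no
downloads. On a 2 × 2 Mb genome it plants 10 shared, 10 A-specific and 10
B-specific SEs of 4–6 constituents (gaps 1.5–3 kb), each shared SE
nucleated by a consensus estrogen-response-element "mother" constituent
present in both lines, flanked by A-only constituents carrying Fox/AP2
consensi and B-only constituents carrying TEAD/TCF consensi (singly or in
pairs, so the co-binding analysis sees both one- and two-collaborator
sites); A-specific SEs carry ERE/Fox/AP2 programs, B-specific SEs carry NR
half-site/TEAD/TCF/SIX programs, and a CEBP motif is never planted,
serving as the negative control for enrichment. Coverage is Poisson
background (0.002 reads/bp) plus 300–500 reads per SE constituent and
10–30 reads per typical (non-SE) enhancer, binned as 50-bp read-start
counts; with these levels the weakest planted SE's tag density is ~1.5×
the strongest typical enhancer's, so the slope-1 cutoff falls in the gap
between the two populations. FPKM values are lognormal
(`meanlog 3, sdlog 0.6`) with multiplicative replicate noise
(`sdlog 0.15`, chosen so far fewer than 5% of equal-mean genes exceed the
2-fold band by chance) and a 4-fold own-line multiplier for specific-SE
genes. Everything derives from one seed and regenerates byte-identically.

What the scenario deliberately does *not* model: mappability artefacts and
blacklist regions (the filter is exercised with synthetic blacklists in
unit tests instead), fragment-length effects, copy-number variation,
chromatin-state marks, indirect (tethered) TF binding and transient
induction kinetics. Passing the planted-truth tests therefore shows the
algorithms are correct under the stated statistical model, not that the
biological conclusions transfer to any particular real dataset.

Problem sizes were chosen so the full scenario plus pipeline completes in
well under a minute of compute per run: ~160 planted constituents, ~80
ranked candidates and ~70 genes per cell line give every stage non-trivial
input while keeping the whole test suite fast.

# Numerical choices and degenerate inputs

* Coordinates are BED-style 0-based half-open at every file boundary;
  internally regions live in `GRanges` (1-based closed), with the shift
  applied exactly once at I/O. Summits stay 0-based as in narrowPeak.
* Ties: ranking ties break by region start then chromosome; the slope-1
  cutoff resolves `y − x` ties (within 1e-12, to absorb float noise from
  the rpm normalisation) to the largest index; annotation ties by
  distance then gene id.
* A ranked curve needs ≥ 2 candidates and a non-zero maximum density;
  all-zero signal is an error, not an empty call.
* Zero-variance density columns yield `NA` correlations, never 0.
* narrowPeak summit offsets of −1 fall back to the interval midpoint;
  summits outside their interval drop the record with a warning.
* Peaks are blacklist-filtered before stitching (the published order is
  not stated; filtering first is the conservative choice and is applied
  consistently).

# Known limitations

* The score-threshold heuristic is a stand-in for a manual, plot-based
  selection; thresholds used for any particular published figure are not
  recoverable, so real-data reanalyses should prefer manual overrides.
* De novo motif discovery is out of scope; enrichment is restricted to
  user-supplied PWMs.
* SE-to-gene annotation is distance- and expression-based only; no
  chromatin-contact information is used, and genes regulated from outside
  the ±100 kb window are missed.
* The binomial enrichment model treats background regions as exchangeable
  with targets; GC- or accessibility-matched backgrounds are the caller's
  responsibility (any region set can be supplied).
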