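---
title: "Methods: scoring, simulating and benchmarking pooled pHLA presentation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, simulating and benchmarking pooled pHLA presentation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapeseq)
```

## The measurement model

A single-chain trimer (SCT) fuses an 8–12-mer peptide, β2-microglobulin
and an HLA class I heavy chain; the complex traffics to the cell surface
only when the peptide binds the groove stably. A pooled SCT library is
sorted by surface fluorescence into four bins — background, low, medium,
high — whose centres sit at roughly 100, 400, 1600 and 6400 a.u., i.e.
evenly spaced on a log scale, and each bin is sequenced. The data for one
peptide–allele pair ("trimer") are therefore four read counts.

Two normalisations precede scoring. First, **depth**: within each
(bin, replicate) file every count is divided by the mean count across all
trimers in that file. This removes sequencing-depth differences between
bin libraries without a log transform (read counts from a sorted pool are
not plausibly log-normal, so a log would distort rather than stabilise).
Second, **per trimer**: each trimer's four depth-normalised values are
divided by their sum, giving bin occupancy fractions that sum to one and
estimate where that construct's cells sat on the sorter. The E-score is
the weighted sum of these fractions with weights 0/2/4/8 — the bins'
log-scale geometry with the background pinned at zero — so it ranges from
0 (all cells background) to 8 (all cells in the top bin), is invariant to
rescaling any single bin file, and is monotone under moving occupancy
into higher bins. A trimer with zero reads in every bin has no defined
score and is reported as missing (`NA`), never as 0: a zero would assert
confident non-presentation that the data do not support.

## Per-allele mode alignment

In combinatorial screens, alleles differ in intrinsic surface efficiency,
which shifts each allele's whole score distribution. Score histograms are
bimodal with a dominant negative peak (most peptides do not bind a given
allele), so the location of that peak is a per-allele nuisance offset.
`align_alleles()` estimates the lower-peak mode per (allele, replicate)
by Gaussian kernel density (Silverman's rule-of-thumb bandwidth,
`stats::density(bw = "nrd0")`) restricted to scores below a valley bound
(default 4, the midpoint of the range, above the combinatorial cutoff),
then shifts each allele's scores **additively** so all modes meet the
panel-median mode. An additive shift (rather than a rescale) is the
minimal correction consistent with an offset nuisance; it preserves score
differences within an allele, and aligning an already-aligned table is
the identity up to KDE grid resolution. Groups with fewer than `min_n`
(default 50) sub-valley scores keep a zero shift and are flagged —
estimating a mode from a handful of points is noise. Replicates are
aligned independently and averaged afterwards; both the per-replicate raw
and aligned values remain in the output so the choice is auditable.

Binder calls use strict inequality against 3.2 (single-allele screens) or
3.8 (combinatorial screens, where multi-allele noise raises the floor);
overrides are accepted but a combinatorial threshold outside 3.5–4
triggers a warning, since calls become unstable outside that band.
Replicate QC requires pairwise Pearson r > 0.9 on raw scores.

## Library design conventions

All coordinates are 1-based inclusive residue indices. Tiling uses a step
of one residue (a 3-bp in-frame shift at the DNA level); a protein of
length L yields L − k + 1 windows. An interior point mutation is covered
by exactly k windows of length k (nine 9-mers).

Fusion junctions admit two conventions, and the package implements both
because the design literature uses both. **Strict spanning** (default)
keeps windows with at least one residue from each parent, giving k − 1
windows per junction; summed over k = 8..12 that is 45 windows per
target, matching the ~45-peptides-per-target budget of multi-length
designs. **Position mode** treats the first residue right of the junction
as a mutated position and yields k windows. Each emitted window records
which convention produced it.

Reverse translation is deterministic — the most-used human codon per
residue — so a design regenerates identically; forbidden restriction
sites (default Esp3I/BsmBI, the cloning enzyme) are screened on both
strands including flank junctions, and repaired by synonymous swaps (an
unavoidable site is an error, not a silent acceptance). Allele barcodes
live in synonymous codons of an invariant 12-residue B2M tail (default
`SQPKIVKWDRDM`, the C-terminus of mature human B2M; synonymous space
~5.5 × 10^4), selected greedily over a seeded random ordering under a
minimum pairwise Hamming distance (default 2). Infeasible requests fail
with the size of the synonymous space.

Demultiplexing anchors must occur exactly once in every assembled
construct; `validate_constructs()` checks this, and `random_library()`
regenerates any random peptide whose codons would embed an anchor. This
is a genuine design constraint of exact-match demultiplexing, not an
implementation artefact.

## Demultiplexing policy

Inserts are recognised only between **exact** matches of their 6–10 nt
flanking anchors; peptide and barcode inserts are then mapped to the
designed oligo and barcode sets by exact identity. Anything else is a
categorized discard (`no_anchor`, `multi_anchor`, `bad_insert_length`,
`unknown_peptide`, `unknown_barcode`); assigned + discarded = total reads
per file, always. Reads with a duplicated anchor are discarded rather
than resolved by first occurrence — without the vector map the ambiguity
is unresolvable. A Hamming-tolerant rescue was considered and rejected as
default: with 36-nt barcodes at pairwise distance ≥ 2, single-error
rescue risks silent cross-allele reassignment, the exact failure mode the
spike-ins exist to quantify. Base-call qualities are ignored (sequence
identity is the only criterion), and a sequencing error anywhere in an
anchor simply becomes a categorized discard.

## Recombination (chimera) estimation

Spike-in pools pair known peptide sets with known allele sets; a read
whose spike-in peptide carries a barcode from outside its own pool is a
recombination chimera. The raw mispaired fraction underestimates the true
swap rate because a swap can land back inside the construct's own pool
and become invisible; under a uniform-swap model the detectable fraction
is `(n_panel − n_pool) / (n_panel − 1)`, and `estimate_recombination()`
divides it out by default (the raw fraction is also reported). With two
25-allele pools in a 50-allele panel the factor is ~0.51, so the
correction matters; the test suite verifies unbiasedness at injected
rates of 0, 2, 5 and 10%.

## Benchmarking machinery

IC50 affinities map to the 0–1 training scale via
`1 − log(IC50)/log(50000)`; the base of the logarithm cancels, and the
implementation pins the conventional checkpoint (500 nM → 0.426 to three
decimals). Binder labels use strict `IC50 < 500 nM`, with elution flags
as fallback. ROC-AUC is the tie-aware Mann–Whitney concordance (ties
count half), verified against an all-pairs brute-force oracle and against
pROC. PR-AUC integrates the precision–recall staircase by **step**
interpolation — linear interpolation of precision is optimistically
biased, so the conservative staircase is used and documented. Confidence
intervals are percentile bootstrap with B = 1000 resamples, seeded;
resamples where a metric is undefined (e.g. single-class) are skipped and
counted. Metrics are computed per allele first — pooled values are
reported separately — because alleles differ wildly in positive rate and
pooling hides that structure.

## Allele similarity

Pseudo-sequences are the 34 cleft-lining polymorphic residues; they are
supplied as input (deriving them from structures is out of scope). The
published position-wise BLOSUM62 comparison divides by the *product* of
the two self-similarity sums, which makes even identical sequences have
nonzero "distance"; the package ships that form verbatim (`as_printed`)
plus a square-root-normalised variant (default) under which self-distance
is exactly zero. The quantity is named a distance throughout — it has the
form 1 − (normalised agreement) — and the discrepancy with its published
name is noted rather than silently resolved. Functional similarity is
cosine distance between allele E-score profiles; the triangle inequality
is *not* asserted anywhere (cosine distance violates it). Heatmap
preparation keeps peptides with at least one above-threshold score and
clips scores to [2, 5] for display; clustering is hierarchical (complete
linkage) on cosine distance, and the orderings/linkage are the tested
artifact — rendering is left to the caller.

For 2-D embedding no UMAP implementation exists in this package's R
dependency set, so `embed_2d()` defaults to Kruskal non-metric MDS
(`MASS::isoMDS`, initialised from classical MDS, hence deterministic for
a fixed input), which consumes only the distance matrix. A `"umap"`
backend delegating to a system Python with umap-learn is provided with
the conventional small-panel settings (`n_neighbors = 5`,
`min_dist = 0.01`, seed 42); for panels of ~50 alleles the qualitative
neighbourhood structure, which is all the embedding is used for, is
stable across both backends.

## Population coverage

Per mutation, an allele "presents" it if it presents at least one tiling
window. A diploid individual draws two alleles per locus (HLA-A, -B, -C)
independently from population frequencies — Hardy–Weinberg within loci
and linkage equilibrium between them. Coverage has the closed form
`1 − Π_locus (1 − p_locus)²` with `p_locus` the summed frequency of
presenting alleles; the seeded Monte-Carlo sampler agrees within three
standard errors across random configurations (property-tested). Frequency
mass absent from the table belongs to unpanelled alleles and never
presents — a conservative convention. Real HLA haplotypes show strong
linkage disequilibrium across loci; ignoring it is a stated limitation,
acceptable because presenting-allele sets here are defined within a fixed
panel. The package takes any frequency table; it retrieves none.

## The simulator: what it emulates and what it does not

`sorter_model()` encodes the screen's generative story: a construct's
presentation strength θ ∈ [0, 1] sets its mean log10 fluorescence by
linear interpolation between the background centre (100 a.u., θ = 0) and
the top centre (6400 a.u., θ = 1); cell-to-cell noise is Gaussian on
log10 fluorescence with σ = 0.12 (about a 1.3-fold coefficient of
variation — a realistic cytometry spread under which a θ = 0 construct
places ≥ 99% of its cells in the background bin); gates sit at the
geometric midpoints 200/800/3200, implementing log-evenly divided bins. A
logistic θ-link is available, mirroring the saturating
fluorescence–affinity relationship seen at high affinities. Per
replicate, each construct's cells (default 1000) are multinomially
binned, and each bin's reads (default 10^5) are drawn multinomially over
constructs proportional to cell counts. By default 10% of constructs are
true binders with θ ~ U(0.45, 1); non-binders take θ ~ Beta(1.2, 25).
Recombination swaps a read's barcode to a uniformly random other allele —
the chimera mechanism is PCR re-pairing of peptide and barcode, so the
peptide read is kept; anchor corruption flips one anchor base, which
under exact matching is equivalent to any sequencing error.

The simulator reproduces the features the pipeline's correctness depends
on: bimodal log-scale fluorescence, log-spaced gates, multinomial
sampling noise, depth imbalance, replicate variation, recombination, and
discard-generating corruption. It does **not** emulate position-specific
binding motifs (θ is drawn independently of peptide sequence), construct
abundance skew from cloning, carry-over between sort gates, PCR
duplicates, or per-base error profiles. Consequently, passing recovery
tests demonstrates that the pipeline faithfully inverts the generative
model of sorting and sequencing — not that any particular biological
motif would be found; motif-level claims require real screen data.

## Problem sizes and numerical choices

The test-suite and acceptance-script scales are the package's chosen
study conditions: a 20 × 3 "tiny" screen at 5 × 10^3 reads per bin for
exactness checks (noise-free demultiplexing must equal the simulator's
latent table bit-for-bit), and a 200 × 10 screen at 10^5 reads per bin —
read depth comparable to real bin libraries relative to pool complexity —
for recovery (binder-call ROC-AUC vs ground truth, within-allele Spearman
rank agreement with θ, replicate correlation). Recombination recovery
uses two 15-peptide × 3-allele spike-in pools at injected swap rates up
to 10%. Bootstrap coverage is measured over 500 simulated repeats of a
normal-mean estimator at B = 1000. Ties in ROC computations are grouped
per distinct score; KDE modes are read off the default 512-point density
grid; zero distances between distinct alleles are nudged by 10^-3 of the
smallest positive distance before non-metric MDS (which cannot handle
exact ties at zero); all seeded helpers save and restore the caller's RNG
state so seeding is local.

## Known limitations

Exact-match demultiplexing discards rather than rescues erroneous reads,
trading depth for assignment certainty. Mode alignment assumes a
detectable negative peak per allele; alleles presenting a large fraction
of the pool (or with too few constructs) are flagged and left unshifted.
The coverage model ignores HLA linkage disequilibrium and treats
unpanelled alleles as non-presenting. The simulator's θ is
sequence-independent, so sequence-level analyses (motifs, pseudo-sequence
vs function comparisons) are exercised for correctness of bookkeeping,
not for biological signal.
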