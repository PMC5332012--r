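---
title: "Models and methods behind bartrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bartrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bartrap)
```

# The screen and its data model

A pooled insertional-mutagenesis screen in haploid ES cells works because a
single piggyBac gene-trap integration fully disrupts its gene. Each
transposon carries an independent random 25-bp barcode at both ends
(PB3/"West", PB5/"Sims"). Two sequencing assays feed the analysis:

* **Barcode amplicons** (single-end): the relative read count of a barcode
  tracks the relative number of cells carrying that insertion. Comparing
  drug-treated to vehicle-treated pools turns this into a fitness readout.
* **Inverse-PCR pairs** (paired-end): one mate carries the barcode, the
  other opens with the transposon terminal sequence followed by genomic
  flank. These pairs build the barcode → integration-site database that
  converts barcode-level fitness calls into gene-level calls.

The package keeps the two transposon ends separate throughout (each end has
its own barcode and its own junction); they are only brought together by
site linking, and a barcode tied to more than one merged site is flagged
ambiguous rather than silently assigned.

# Barcode extraction and error clustering

Extraction matches a constant flank immediately 5′ of the barcode by
Hamming distance over a fixed window (default budget 2 mismatches). Using a
fixed window rather than an indel-aware alignment keeps extraction O(1) per
read; an indel in the flank costs the read, which is the conservative
failure mode. Reads with an N inside the barcode window are discarded, not
wild-carded — a wildcard would let unrelated barcodes coalesce during
grouping.

Barcodes within Levenshtein distance ≤ 2 (default) are clustered by single
linkage across the pooled barcode universe and counted together. Levenshtein
rather than Hamming because the sequencing platforms involved produce
indels as well as substitutions; single linkage because "count errors with
their parent" is exactly the transitive closure of pairwise similarity, and
it is order-independent. The canonical barcode is the most abundant member
(ties broken lexicographically, for deterministic output), and per-sample
counts are summed over members, so reads are conserved exactly — an
invariant the tests assert. Candidate pairs are found with a pigeonhole
substring index (split each 25-mer into `max_edit + 1` chunks; two barcodes
within the edit radius must share a chunk at a shift of at most `max_edit`);
all candidates are verified with an exact distance, so the index affects
speed only. Correctness is checked against an all-pairs brute-force oracle
on hundreds of random instances.

With 25 random bases, unrelated barcodes sit at expected distance ≫ 2, so
a radius-2 cluster around an abundant barcode captures PCR/sequencing
errors with negligible risk of joining genuinely distinct barcodes. At a 1%
per-base error rate the simulator shows ≥ 99.9% of reads restored to their
true canonical barcode.

# Junction mapping and site curation

The built-in mapper anchors an exact 16-mer seed (the junction bases
adjacent to the transposon, where sequencing quality is best) and extends
without gaps on both strands; a junction maps if it has a unique best hit
with ≥ 95% identity over ≥ 20 aligned bases, and ties are discarded as
multimapping. This is deliberately simple — junction reads are short,
ungapped, near-exact matches — and it is verified against a brute-force
scan of every reference offset. Pre-computed alignments (e.g. bwa) can be
imported from SAM instead; reverse-strand positions are derived from the
POS plus the reference-consumed CIGAR length, so clipped and gapped records
are handled.

Site coordinates are 1-based; the site position is the first genomic base
flanking the transposon end (leftmost aligned base on the + strand,
rightmost on the −). Sites with fewer than 10 reads per million within
their (library, end) mapping run are discarded — strict inequality, read
literally from the filtering rule — and surviving same-library, same-end,
same-strand sites within 5 bp are merged transitively. The merged site
takes the position of its most-supported member (ties to the smallest
position) and the summed read count. These merge semantics are a package
choice where the rule's fine print is unstated; they were picked for
determinism, idempotence (merging twice changes nothing) and read
conservation, all of which are property-tested against an independent
pairwise-closure implementation. The rpm denominator is the mapping run
(library × end) because filtering was applied per run; a pooled denominator
is available as a flag.

Gene annotation assigns every gene whose gene-body span (min start to max
end of its GTF records) overlaps the site position, strand-agnostically.
Gene-trap disruption is in reality orientation-dependent, but orientation
filtering is deliberately not applied — orientation is recorded and the
user can filter downstream.

# Differential abundance

## Normalization

Between-sample scaling uses trimmed mean of M-values: log ratios (M) and
average log abundances (A) are computed against a reference sample (the one
whose 75th-percentile count/library-size is closest to the mean), barcodes
zero in either sample are dropped, the top and bottom 30% of M and 5% of A
are trimmed, and the factor is the inverse-variance-weighted mean of the
surviving M values (delta-method binomial weights), rescaled so factors
have geometric mean 1. The implementation is validated against an
independent reference implementation to 10⁻⁶ on random matrices with
composition bias.

## Dispersion

A common NB dispersion φ is estimated by conditional maximum likelihood on
quantile-adjusted pseudo-counts. Conditioning each barcode's within-group
counts on their sum removes the unknown per-barcode means; the profile

$$\ell(\varphi) = \sum_{g,\,\text{groups}} \Big[ \sum_i \log\Gamma(y_i + 1/\varphi) + \log\Gamma(n/\varphi) - \log\Gamma(z + n/\varphi) - n \log\Gamma(1/\varphi) \Big]$$

is maximised by golden-section search on log φ over [10⁻⁶, 10]. The
conditioning argument requires equal library sizes, so counts are first
mapped to a common library size (geometric mean of the effective sizes) by
quantile matching under a moment-matched gamma approximation to the NB
(shape μ/(1+φμ), scale 1+φμ); two rounds of adjust-then-maximise are run
since the adjustment itself needs φ. The gamma-only approximation is a
simplification of the usual gamma/normal average; in the screens' regime
(near-equal library sizes after TMM) the adjustment is near-identity and
the estimate matches the reference implementation to ~10⁻⁵. Parameter
recovery is verified by simulation (true φ = 0.2 recovered within
[0.15, 0.25] in ≥ 90% of runs; Poisson data drives φ̂ below 0.01). With no
replication anywhere, a configured default (0.1) is returned with a
warning rather than an unidentifiable estimate.

## The exact test

For one barcode, let the equalized counts in conditions A and B sum to
$s_A$ and $s_B$, $t = s_A + s_B$. A sum of $n$ i.i.d. NB variables with
common mean/size ratio is NB with size $n/\varphi$, so conditional on $t$
the split follows a negative hypergeometric law,

$$P(a \mid t) = \frac{\binom{a + r_A - 1}{a}\binom{t - a + r_B - 1}{t-a}}{\binom{t + r_A + r_B - 1}{t}},
\qquad r_A = n_A/\varphi,\; r_B = n_B/\varphi,$$

free of the unknown mean. The two-sided P-value sums $P(a \mid t)$ over
all splits with probability ≤ that observed (minimal-likelihood
summation, with a 1+10⁻¹² tolerance on the comparison to absorb floating
point). This rule was chosen over tail doubling because it is exactly what
direct enumeration of the conditional distribution gives, so the test can
be — and is — checked against an independent enumeration oracle for every
total ≤ 50 across φ ∈ {0, 0.01, 0.1, 1}, and against the matching option
of the reference package. At φ = 0 the law is binomial with
p = n_A/(n_A+n_B); t = 0 returns P = 1 by convention, keeping the BH
vector well-defined. The P-value is symmetric under group swap and
monotone away from the conditional mode (property-tested).

Fold changes are log₂ ratios of prior-augmented mean CPM (prior 0.125,
scaled by effective library size), finite even when one condition has zero
reads. `run_screen_test()` chains normalization → dispersion → exact test →
BH; barcodes with zero counts everywhere are excluded from testing and
from the BH denominator, and samples are compared within their own library
when a library column is present, since each pool was screened against its
own replicates.

# Gene-level aggregation

Per-insertion results (unambiguous barcodes only, by default) are grouped
by gene and direction; insertions passing both |log₂FC| ≥ 1 and P ≤ 0.05
(defaults; raw P, since reported screen P-values are typically raw — an
`use_fdr` flag switches) count as significant, and a gene needs ≥ 2
significant insertions in one direction to be reported. Evidence is
combined across the significant members by Fisher's method
(−2Σln P ~ χ² with 2k d.f.); combining only significant members mirrors
"multiple depleted insertions in the same gene" as the unit of evidence,
and a flag combines all members instead. Insertions from different
libraries count as independent. Raising either cutoff can only shrink a
gene's significant set (tested). The cutoffs are placeholders in the sense
that hit-calling thresholds are screen-specific; they are exposed
everywhere.

# The simulator

The generator emulates the screen's structure end to end: a uniform-random
genome (TTAA occurs at the expected ~1/256 density; one is injected into
any gene body that lacks it), non-overlapping gene spans, ten pools of
10,000 mutants, integrations at uniformly drawn internal TTAAs (piggyBac's
defining target site, enforced so positions are checkable), a 5% two-copy
fraction (the deposited libraries contain roughly twice as many
integrations as founding colonies), and barcodes drawn with replacement
from a finite pool of 10⁶ (collisions at the birthday rate, emulating the
plasmid pool's limited complexity).

Selection is deterministic exponential growth with multiplicative
lognormal noise: $N_\text{final} = N_0 \cdot 2^{g f} \cdot e^{\mathcal N(0,\sigma)}$.
Defaults: $g = 8$ doublings over the eight-day selection (one per day —
the effective generation count is not observable from the data, so this is
a free parameter), wild-type drug fitness $f = 1 + \log_2(0.5)/g$ so that
a neutral mutant survives the drug arm at 50% of its vehicle abundance
(the screen's stated dose criterion), founding abundance 200 cells per
mutant (2×10⁶ cells per 10⁴-mutant pool), σ = 0.3 (which, after
multinomial read sampling at 2×10⁶ reads/sample, yields NB-like
overdispersion with φ ≈ 0.1 — consistent with the dispersion the null
calibration assumes), and a 1% per-base substitution error in emitted
reads. A gamma PCR-jackpot multiplier is available but off by default.
Reads carry truth ids in their names for test traceability only; no parser
relies on them.

What the simulator does **not** model: restriction-fragment structure of
the inverse PCR (digest choice is wet-lab scope), platform-specific
homopolymer/flowgram errors, quality-score variation (constant Q), chimeric
reads, and index hopping. Passing the end-to-end tests therefore
demonstrates correctness of the deconvolution logic under a clean
generative model, not robustness to every artefact of real libraries —
the rpm filter, flank-mismatch budget and edit-distance radius are the
knobs a real screen would tune.

# Numerical and design choices

* Distances: Levenshtein for barcodes (default radius 2), Hamming for
  fixed-window flank matching.
* Exact-test comparisons use a relative 10⁻¹² tolerance when collecting
  the minimal-likelihood tail; probabilities are normalised by the summed
  conditional mass to absorb lchoose rounding.
* Golden-section tolerance 10⁻⁸ on log φ; search bounds [10⁻⁶, 10].
* Zero counts map to zero pseudo-counts (a zero carries no fractional
  quantile information).
* Merge ties (equal read support) resolve to the smallest position;
  canonical-barcode ties resolve lexicographically; both make reruns
  byte-identical, which the pipeline test asserts via file comparison.
* Problem sizes in the shipped tests (e.g. 500-mutant end-to-end screens,
  4×200 kb genomes, 20-seed calibration loops) were chosen as the smallest
  sizes at which the statistical assertions are stable; the simulator
  scales to the full 10-pool screen.

# Known limitations

* The common-dispersion model has no tagwise/trended component; strongly
  abundance-dependent overdispersion would miscalibrate extreme-abundance
  barcodes.
* The built-in mapper is ungapped; junctions spanning indels relative to
  the reference must come through SAM import.
* Ambiguous (multi-site) barcodes are excluded from gene evidence rather
  than fractionally assigned.
* Gene assignment is by gene-body overlap only — no promoter windows, no
  orientation requirement for the gene-trap cassette.
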