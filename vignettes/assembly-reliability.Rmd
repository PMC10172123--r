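---
title: "Flagging assembly reliability from read depth"
author: "asmflag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging assembly reliability from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmflag)
```

## The problem

A phased diploid assembly represents both haplotypes of a genome. When the
long reads that produced it are mapped back to the combined
maternal+paternal assembly in a haplotype-aware way, every correctly
assembled base should be covered at roughly the sequencing depth μ, with
each read placed on its haplotype of origin. Departures from that depth
are diagnostic:

| depth regime | interpretation | flag |
|---|---|---|
| ≈ 0 | no read support: erroneous sequence | `Err` |
| ≈ μ/2 | reads split across a falsely duplicated copy | `Dup` |
| ≈ μ | reliable haploid sequence | `Hap` |
| ≈ kμ, k ≥ 2 | k genomic copies collapsed into one | `Col` |
| contested | could not be assigned to one component | `Unk` |

`asmflag` fits a mixture over the depth histogram, labels every base, and
emits five-label BED intervals with summary statistics.

## The mixture model

Over integer depth $d$ the model is

$$P(d) \;=\; w_e\,\mathrm{Pois}(d;\lambda)
  \;+\; w_d\,\mathcal N\!\left(d;\tfrac{\mu}{2},\sigma_d\right)
  \;+\; w_h\,\mathcal N(d;\mu,\sigma_h)
  \;+\; \sum_{k=2}^{K+1} w_k\,\mathcal N(d;k\mu,\sigma_k).$$

Constraints, all enforced exactly rather than encouraged:

* the duplicated mean is **derived** as μ/2 and the k-th collapsed mean as
  kμ — they are never free parameters, so they cannot drift;
* λ is clamped to [0, 10] reads and its M-step uses only the
  responsibilities at depths below 10, so the erroneous component cannot
  wander up into genuine coverage;
* mixing weights are renormalised after every M-step;
* each Gaussian standard deviation is floored at 0.5 reads to rule out
  zero-variance spikes on quantised histograms.

The tied haploid mean is re-estimated each M-step by weighted least
squares across the whole Gaussian family: with responsibilities $r_{jd}$,
mean multipliers $c_j \in \{1/2, 1, 2, \dots, K+1\}$ and base counts
$n_d$,

$$\hat\mu = \frac{\sum_j (c_j/\sigma_j^2) \sum_d n_d r_{jd}\, d}
                 {\sum_j (c_j^2/\sigma_j^2) \sum_d n_d r_{jd}},$$

followed by the usual variance updates. This is coordinate ascent on the
EM objective, so the log-likelihood is non-decreasing (asserted in the
test-suite across 100 random histograms, with 1e-8 slack for the
restricted λ step).

The statement that the erroneous mode "uses only coverages below 10" is
ambiguous between truncating its likelihood and restricting its M-step; we
chose the restricted M-step (λ estimated from responsibilities at depths
0–9, density still evaluated everywhere in the E-step) as the simpler
reading, and the clamp makes the two nearly indistinguishable in
practice.

Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `init_coverage` | histogram mean | EM start for μ; the one knob worth exposing |
| `n_collapsed` | 4 (means 2μ…5μ) | plausible copy counts without overparameterising |
| initial weights | 0.05 / 0.05 / 0.80 / 0.10 split | most of a real assembly is haploid |
| initial σ | `init_coverage / 8` | ≈ Poisson scale at typical HiFi coverage |
| convergence | rel. ΔlogL < 1e-6, ≤ 300 iterations | histograms are small; fits take milliseconds |
| `min_mass` | 1e4 bases | below this a single-depth histogram is degenerate |

Gaussian densities are evaluated at the integer depths without a
continuity correction: the model is an approximation over counts and the
correction is immaterial at the depths involved.

Labelling picks, for each depth 0…max, the label with the highest weighted
density, with collapsed sub-components pooled into `Col`. Exact ties are
broken deterministically in the order `Hap` > `Dup` > `Col` > `Err` — ties
occur on integer depths, and when in doubt the safer call is the one that
does not flag.

## Windowed fitting

Coverage drifts regionally, so one genome-wide threshold set misclassifies
locally. Contigs longer than 5 Mb are tiled into 5 Mb windows (the final
window stands alone even when short) and a distinct model is fitted per
window; shorter contigs, windows with fewer than 1e4 covered bases, and
windows whose fit degenerates fall back to the whole-genome model. Every
fit starts at the genome-wide mean coverage — a common, well-informed
starting point from which each window's EM adapts to local structure.

## Corrections

**Satellite biases.** HiFi coverage drops systematically on HSat1 and
rises on HSat2/3 for platform reasons unrelated to assembly quality, which
pushes those arrays into the duplicated or collapsed components. For each
annotated class the mixture is refitted on that class's own histogram with
the EM starting coverage set to 0.75× (HSat1) or 1.25× (HSat2/3) of the
genome-wide mean depth, and labels inside the regions are replaced by the
refit's assignment. The multipliers scale the *average sequencing
coverage*, not the region's own mean — a biased region's mean is exactly
what cannot be trusted.

**High-MAPQ rescue.** A genuine false duplication leaves reads mapping
ambiguously between the two copies, so almost none align with MAPQ > 20.
A `Dup` block whose high-quality depth exceeds 5 reads *throughout* is
therefore relabelled `Hap`. Using the block minimum rather than the mean
is the conservative aggregation: a single unsupported stretch blocks the
rescue.

The order of operations is fixed: windowed labelling → satellite
correction → high-MAPQ correction → merging.

## Merging and the unknown label

For each label independently, blocks separated by gaps strictly smaller
than 1,000 bases are merged, the gap being absorbed. Any base claimed by
two or more labels' merged spans afterwards becomes `Unk` — it could not
be assigned to a single component. Two choices make this well-behaved:
conflicts go to `Unk` regardless of how many labels contest, and `Unk`
itself never absorbs gaps (it marks conflicts, it does not spread), which
makes the operation idempotent. When three labels interleave within the
merge distance the contested span still resolves to a single `Unk` block;
behaviour in that corner is documented here precisely because it is a
design choice, not a forced move.

One known failure mode is inherited from the method itself: a strong
satellite coverage rise can distort the fit of the *neighbouring* window
and mis-flag flanking sequence as collapsed. No automatic repair is
attempted; the satellite annotation boundaries are the user's lever.

## Alignment hygiene

The depth signal is only as clean as the alignments, so the package
implements the upstream filters:

* **chimeric reads** — any read carrying a supplementary alignment (flag
  0x800) is removed wholesale; the split placement is itself evidence of
  trouble. "Chimeric" has no universal operational definition; this is
  ours.
* **short alignments** — reference span < 2,000 bases. The reference span
  (not the read span) is used because the depth signal lives on the
  assembly.
* **divergent alignments** — gap-compressed mismatch ratio > 1%, defined
  as (mismatches + gap openings) / (matches + mismatches + gap openings),
  each contiguous indel run counting once. The name is standard, the
  formula rarely written down; this one is fixed by tests.
* **no MAPQ filter** — over homozygous regions of a diploid assembly reads
  legitimately map with MAPQ 0; filtering on it would hollow out exactly
  the regions being evaluated.
* **alt-read removal** — alignments whose aligned base equals the
  alternative allele at any high-confidence biallelic SNP (PASS, VAF ≥
  0.3, GQ ≥ 10) are removed. A deletion spanning the SNP leaves no base to
  compare and does not count: the rule targets substitutions.

**Marker-based re-ranking.** In near-homozygous regions the aligner can
pick the wrong haplotype as primary. For every read whose best secondary
scores at least 0.99× the primary (the published pipeline's exact gate is
not stated; 0.99 is our configurable default), the candidates are compared
column-by-column in read coordinates. Read bases mismatched in at least
one but not all candidates are *single-nucleotide markers*; each
candidate's consistency score is $-\sum q_i$ over the markers it
mismatches, with $q_i$ the phred base quality. The best score wins, ties
keep the original primary, and a promoted secondary replaces the read's
other alignments. Construction details: extended `=`/`X` CIGARs are
required (so no assembly FASTA is needed to detect mismatches); read
insertions and soft-clipped bases count as mismatches for that candidate;
deletions consume no read base and contribute no marker; reverse-strand
profiles and qualities are flipped into original-read orientation; the
aligner's `AS` tag is used when present, else a column score (matches −
mismatches − gap openings).

## The simulator: what it emulates, and what it does not

Per-base HiFi depth is strongly autocorrelated: a 15 kb read covers 15,000
consecutive bases, so depth changes only at read boundaries. The generator
therefore works at the resolution of autocorrelation blocks (default
25 kb): for a block of $B$ bases with local mean $m$ it draws the number
of overlapping reads $N \sim \mathrm{Pois}\!\big(m\,(B+L)/L\big)$ and sets
the block depth to $\mathrm{round}(N\,L/(B+L))$, giving block-level
variance $\approx m\,L/(B+L)$ — the variance of block-averaged coverage —
rather than the much larger per-base Poisson variance $m$. A negative
binomial option (`noise = "nb"`) adds overdispersion. Planted regions
scale the local mean (defaults: `Err` 0.025, `Dup` 0.5, `Col` 2) and
satellite plants multiply it (defaults 0.75 / 1.25 / 1.25, the directions
seen for HiFi). Defaults of 40× haploid depth and 15 kb reads match the
scale of a typical HiFi assembly project. Everything is reproducible from
a single seed, which is restored afterwards so the generator never
perturbs the caller's RNG stream.

What the simulator does **not** emulate: sub-block depth excursions (each
block gets one draw, so within-block variance is zero), mappability
structure, read-length variation, sequence-dependent coverage waves, or
sequence-level read errors for the coverage track. Consequently the
end-to-end tests demonstrate that the windowed fitting, assignment,
correction and merging logic recover regional planted truth under
realistic block-scale noise — they do not bound base-resolution accuracy
on real data, where boundary effects and fine-scale excursions will blur
block edges.

The read-alignment fixture generator is sequence-level but deliberately
simple: two homologous contigs differing at planted substitution sites,
exact-substring reads from haplotype 1 with Poisson-thinned substitution
errors, and one candidate alignment per haplotype at shared coordinates.
That is exactly the structure the marker logic needs; it does not model
indels or clippings, which the production code handles but the oracle
tests cover with constructed CIGARs instead.

## Degenerate inputs and numerical corners

* A histogram with a single distinct depth and fewer than `min_mass` bases
  raises a classed error (`asmflag_degenerate_fit`); windowed flagging
  catches it and falls back to the whole-genome model with a logged count.
* An all-zero-coverage histogram with sufficient mass fits cleanly: the
  erroneous weight converges to 1 (the haploid mean is floored at 1 read
  so the Gaussians cannot collapse onto depth 0).
* E-step arithmetic is done in log space with per-depth max-shifting;
  components with exactly zero weight contribute −∞ and can never
  resurrect, which is standard EM behaviour and keeps posteriors exact.
* Depths are validated as integers ≤ 2³¹−1; coordinates are 0-based
  half-open everywhere internally, converting at the samtools-depth
  (1-based) and `.cov` (1-based inclusive) boundaries only.

## Problem sizes used by the test-suite

The shipped tests exercise parameter recovery on 10⁶-base histograms
(recovering the haploid mean within 2% and every weight within ±0.01),
end-to-end flagging on a 50 Mb simulated diploid with 2% planted
misassemblies (≥95% of planted bases recover their planted label, ≤0.5%
of clean bases flagged), oracle equivalence of the assignment table and
marker scores against brute-force recomputation, the exact boundary
behaviour of every pipeline constant, and EM monotonicity over 100 random
histograms. These sizes were chosen so the full suite runs in about two
minutes on a single core while leaving each statistical check comfortably
powered.

## Limitations

* Depth is the only signal: inversions, local misjoins that preserve copy
  number, and consensus errors without coverage consequences are
  invisible.
* Collapsed copy number is capped at `n_collapsed + 1` (default 5);
  higher-copy collapses land in the last component.
* Satellite correction depends entirely on the supplied annotation; an
  unannotated biased array will be mis-flagged, and a strong rise can
  distort the neighbouring window's fit (see above).
* The marker re-ranking assumes candidates share the read's full length;
  hard-clipped candidate sets are rejected rather than reconciled.
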