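---
title: "Models and conventions behind vcbench"
author: "vcbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind vcbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcbench)
```

## What the package computes

`vcbench` evaluates small-variant callsets (SNVs, short insertions, short
deletions) against a high-confidence truth set, combines many callsets, and
quantifies how sample contamination erodes detection power. Three ideas carry
the whole package:

1. **Representation regularization.** The same physical indel can be written
   at several VCF coordinates when it falls in repetitive sequence. All
   records are rewritten in a canonical form — alleles trimmed, indels
   shifted to the lowest genomic coordinate among all placements producing
   the same edited sequence — before any comparison.
2. **Key matching.** Two variants are the same call iff they have the same
   type and the same start and end coordinate. Allele identity is not part
   of the default rule (a `strict` mode adds it); genotype (het/hom)
   concordance is out of scope.
3. **Region restriction.** False-positive and false-negative rates are only
   meaningful where the truth set is complete, so calls are restricted to
   confident regions, and the false-negative denominator is additionally
   restricted to transcript regions when the calls derive from exome data.

## Regularization

For a trimmed deletion removing bases $[d, d+L-1]$, the placement one base to
the left yields the same edited sequence iff the base at $d-1$ equals the
base at $d+L-1$; iterating this test walks the deletion to its lowest
coordinate. Insertions walk analogously, rotating the inserted sequence as
they move. Both directions of this argument give the standard result that the
equivalent placements of a simple indel form one contiguous run, which is
what `equivalent_placements()` enumerates by brute force (every candidate
placement is applied to the reference and compared byte-for-byte). The
regularizer is tested against that brute-force enumeration: on repeat-rich
synthetic references the returned placement is the enumerated minimum in
every case, and the operation is idempotent.

Two boundary conventions matter. Trimming removes shared suffix bases before
shared prefix bases, keeping at least one base per allele, which preserves
the VCF anchor-base form; allele pairs that still are not a single-base
substitution or a simple insertion/deletion (e.g. the MNV `AT>GC`) are
rejected and counted rather than force-decomposed, since the analyses here
are defined over the three simple classes only. Second, a left shift that
reaches the boundary of a truncated reference window is an error asking for
a larger window rather than a silently non-minimal placement.

Matching keys make the conventions concrete: an SNV at `pos` has span
`[pos, pos]`; a deletion of $L$ bases anchored at `pos` spans the deleted
bases `[pos+1, pos+L]`; an insertion collapses to its anchor `[pos, pos]`.
A deletion key therefore literally covers what is missing, and containment
in a confident region means the whole affected span lies inside one
interval — a variant straddling a region boundary is excluded.

## Quality filtering

Calls with phred QUAL strictly below the threshold (default 40) are removed;
a call at exactly the threshold survives. Records with absent QUAL fail any
positive threshold — a conservative choice, counted and reported, since an
unscored call cannot demonstrate that it meets the bar. Genotype quality
comes from the sample column's GQX field when the caller provides it
(the minimum of the genotype quality assuming a variant and a non-variant
locus), else GQ; it drives the ROC sweep, not the filter.

## Comparison and combination

For a callset $C$ and truth $T$, both regularized, restricted and reduced to
unique keys: $\mathrm{FP} = |C \setminus T|$, $\mathrm{fp\_rate} =
\mathrm{FP}/|C|$ over the confident regions, and $\mathrm{fn\_rate} =
|T' \setminus C| / |T'|$ where $T'$ is the truth restricted to the
false-negative denominator regions. Empty denominators yield flagged zero
rates instead of errors. A truth key counts at most once however many source
records collapse onto it.

Combination works at key level. The union keeps, for each key, the record
with the highest genotype quality (ties broken by the lexicographically
smallest source label) — sources are never merged field-by-field. Detection
frequency counts, for every union key, how many callsets contain it; the
bins are *intersection* (all $n$ sources), *middle* (2 to $n-1$),
*singleton* (exactly 1), reported with each bin's percentage share of the
union at two decimals. All percentage reporting uses half-up rounding
(`round_half_up()`), matching how such tables are conventionally printed;
`percent_excess()` rounds to a whole percentage the same way.

The ROC sweep orders the distinct genotype-quality values descending and
reports, at each threshold, the true-positive rate against the eligible
truth count and the false-positive rate against the callset's total
false-positive count. The FPR denominator is classification-style because
genome-wide "negative positions" are not a well-defined population for
variant calling; the curve is monotone by construction and is cross-checked
against an independent ROC implementation in the tests.

## Contamination model

The read-level mixing experiment is deliberately re-implemented at the level
of per-site read observations: at total coverage kept constant (default
150X), each read originates from the sample with probability $1-c$ and from
a reference-homozygous contaminant with probability $c$. A sample read from
a heterozygous site carries the alternate allele with probability $1/2$;
carried alleles are miscalled with probability $e$ (alt to ref) or $e/3$
(ref to the specific alt, uniform over the three non-reference bases). The
marginal alt probability of one read is therefore

$$p(g, c, e) = (1-c)\,p_g + c\,\tfrac{e}{3}, \qquad
  p_{\mathrm{ref}} = \tfrac{e}{3},\;
  p_{\mathrm{het}} = \tfrac{1-e}{2} + \tfrac{e}{6},\;
  p_{\mathrm{hom}} = 1-e,$$

and the alt count at a site of depth $D$ is $\mathrm{Binomial}(D, p)$. The
quantity of interest — detection power versus contaminant fraction at
constant coverage — is a function of this allele-fraction dilution, which
the site model captures without simulating read sequences or alignment.
What the site model does *not* capture is alignment artefacts, so the
false-positive columns of a read-level experiment are not claimed to be
reproduced; simulated false-positive rates here reflect only sequencing
error against the caller.

Calling uses a generic diploid genotype-likelihood model:
$\Pr(k \mid g) = \mathrm{Binomial}(D, p_g)$ evaluated at the observed alt
count, a prior of $1-\pi$ on the reference genotype and $\pi/2$ on each
variant genotype (default $\pi = 0.001$, surfaced in the configuration so
stricter or looser callers can be emulated), and call quality
$Q = -10\log_{10} \Pr(\mathrm{ref} \mid k)$. A site is called variant iff
$Q \ge 40$, anchoring the simulator to the same phred-40 bar as the VCF
quality filter. Likelihoods are combined in log space.

Two implementation choices make the simulator testable rather than merely
plausible. First, the sampler draws, per read, one uniform for origin and
one for the alt observation, with the contaminant's alt probability never
exceeding the sample's; re-seeding the identical stream at every
contamination level (common random numbers) then makes a read's alt
observation pointwise non-increasing in $c$, so the monotonicity of the
false-negative curve is a structural fact the tests assert exactly, not a
statistical tendency. Second, `analytic_detection_power()` computes the
exact power at fixed depth as
$\sum_k \mathrm{Binomial}(k; D, p)\,\mathbb{1}[Q(k, D) \ge 40]$, an oracle
fully independent of the sampling path; the Monte-Carlo experiment in
fixed-depth mode must agree with it within three standard errors at every
contamination level. Default site counts (10&thinsp;000 heterozygous,
2&thinsp;000 homozygous-alt, with the package default scaled to
4&thinsp;000/2&thinsp;000/4&thinsp;000 for routine runs) keep the standard
error of a power estimate below half a percentage point while the whole
grid runs in seconds.

At 150X with $e = 0.01$ and threshold 40, power for heterozygous sites is
effectively 1 up to 50% contamination, drops through roughly one third at
75%, and is effectively 0 at 99% — the steep collapse past three-quarters
contamination that motivates depth compensation when tumour purity is low.

## Clinical overlap

Clinical records carry a coordinate, an optional dbSNP id, a significance
label and a phenotype. Significance filtering is substring-based and
case-insensitive with accepted labels `pathogenic` and `risk factor`,
because curated significance strings are frequently compound
(`Pathogenic/Likely_pathogenic` must match `pathogenic`). A record is
detected by a callset when some matching-key span covers the record's
position — records carry no allele, so position coverage is the defensible
criterion, and a deletion spanning the coordinate counts. An alternative
dbSNP-id mode matches identifier sets instead, for tables where ids are
more trustworthy than coordinates. The unanimity summary reports, of the
records overlapped by at least one callset, the share detected by all,
at one decimal.

## Synthetic data: what it emulates, what it does not

The generator produces every input the pipeline consumes, deterministically
per seed:

* **Reference** (`generate_reference()`): i.i.d. uniform bases with tandem
  repeat blocks (unit 2-4 bp, 3-10 copies) covering a target fraction
  (default 20%) — enough repetitive structure that indels genuinely have
  ambiguous placements.
* **Truth set** (`generate_truth_set()`): well-separated variant positions;
  a configurable share of indels (default 40%, at least 30% realized)
  inserts or deletes one repeat unit inside a repeat block so that
  regularization is exercised non-trivially; records are emitted already
  canonical with pairwise distinct keys.
* **Callsets** (`generate_callset()`, `generate_callsets()`): each truth
  variant is emitted with probability `sensitivity`; false calls arrive as
  Poisson counts at positions away from the truth; QUAL/GQ are drawn from
  zero-truncated normal distributions per class; emitted indels are
  re-expressed at a random equivalent non-left-aligned placement with
  probability `indel_jitter` (default 0.3), which regularization must undo
  exactly. For multi-tool studies, false calls come from three pools —
  per-tool independent (70%), correlated with inclusion probability 0.6
  (25%), and universal (5%) — because real tools share part of their
  systematic errors; this structure is what makes the singleton bin's
  false-positive rate exceed the middle bin's, which in turn exceeds the
  intersection's, the ordering the detection-frequency analysis exists to
  show. The nine-callset preset uses sensitivities evenly spaced over
  0.90-0.98, a realistic spread for mature short-read pipelines on SNVs.
* **Regions** (`generate_regions()`): random 200-1000 bp segments kept with
  the target probability and merged, giving confident (default 90%) and
  transcript (default 50-60%) region sets.
* **Clinical table** (`generate_clinical_table()`): truth positions with
  pathogenic / risk-factor / benign labels and synthetic rs ids.

What the generator does **not** emulate: alignment error, systematic
context-dependent caller biases, genotype errors, multi-allelic sites,
structural variants, and coverage variation along the genome. Passing tests
therefore demonstrate that the machinery is correct under the stated
observation models — they do not certify performance of any real aligner or
caller on real data, which depends on exactly the effects abstracted away.

## Numerical and design choices

* Percentages: two decimals half-up in tables, one decimal for the clinical
  summary, whole percentages for percent-excess — the conventions of the
  tables this machinery reproduces. Exact arithmetic is reported even where
  a published table differs in the last digit from its own inputs.
* Union record ties: highest GQ, then smallest label — deterministic, and
  favouring the best evidence for downstream ROC sweeps.
* Coordinates: 1-based inclusive internally (VCF convention); BED files are
  converted from 0-based half-open at the parser boundary and back on
  write.
* Duplicate keys within a callset collapse to the highest-GQ record, with
  the collapse counted.
* Degenerate inputs: empty callsets and empty denominators flow through as
  flagged zero-rate results; an empty truth set makes every call a false
  positive with a warning; a zero-depth site is a no-call with quality 0.
* Problem sizes in the shipped tests and acceptance script — 10,000-variant
  truth sets, nine callsets, 1,000 jittered repeat indels, 10,000 simulated
  heterozygous sites per contamination level — were chosen so each suite
  section completes in seconds to a couple of minutes while leaving Monte
  Carlo error well below the assertion tolerances (three binomial standard
  errors throughout).
* Seeds: every generator takes an explicit seed and derives separate
  streams for sub-tasks; identical configuration reproduces byte-identical
  reports, which the pipeline test asserts.

## Known limitations

* Matching is coordinate+type; haplotype-aware comparison (normalizing
  across representation differences that span multiple records) is not
  attempted and is a known gap relative to modern benchmarking comparators.
* Genotype concordance is not assessed.
* The contamination model is site-level by design; its false-positive
  behaviour under alignment artefacts is explicitly out of scope.
* The regularizer requires the reference window to extend far enough
  upstream of each indel (1 kb is ample in practice); it errors rather than
  guesses when the window is exhausted.
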