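---
title: "Methods: the nif screen and the 15N fixation estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nif screen and the 15N fixation estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mucinif implements two analyses around biological nitrogen fixation (BNF)
in plant-associated microbial communities: a phylogenetically anchored
screen for nitrogenase (*nif*) gene homologs in metagenomic reads, and the
classical isotope-dilution estimators of the percentage of plant nitrogen
derived from the atmosphere (%Ndfa). This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not establish.

## The nif screen

A community is called *fixation-capable* when homologs of all six core
nitrogenase genes — *nifH*, *nifD*, *nifK* (structural subunits) and
*nifE*, *nifN*, *nifB* (FeMo-cofactor biosynthesis) — are detected;
*anfG*/*vnfG* mark the alternative iron-only and vanadium nitrogenases.
The screen proceeds in four stages.

**1. Translated search.** Every read is translated in all six frames
(`six_frame_translate()`; standard genetic code, stops kept in frame as
`*`, codons containing `N` as `X`) and aligned against every reference
peptide of every family by exact Smith–Waterman local alignment
(BLOSUM62, affine gaps open 11 / extend 1). Raw scores are converted to
bit scores with the standard gapped-BLOSUM62 Karlin–Altschul constants
(lambda = 0.267, K = 0.041) and to E-values as `E = m n 2^-bit`, with `m`
the translated query length and `n` the total residue count of the
family's references (no length correction — a declared simplification).
Per read and family only the best hit survives (lowest E-value, ties
broken by raw score then reference ID, so outputs are bit-reproducible),
and only below the threshold `E < 1e-3`. The original analysis used a
heuristic BLAST search at the same threshold; the exact aligner is a
deliberate substitution that keeps the decision semantics while removing
heuristic nondeterminism, and neither the BLAST flavor nor its gap
parameters were stated, so the scheme above is this package's own choice.
The stop character scores −4 against everything (including another stop):
synthetic data is frameshift-free, so penalizing in-frame stops and
splitting on them are never distinguished here, and penalizing is simpler.

**2. Projection into the reference alignment.** Each retained hit segment
is aligned globally with free end gaps to its best-scoring ungapped
reference row and threaded through that row's gap pattern into the
reference coordinate system (`align_hit_to_reference()`). Insertions
relative to the reference are dropped; the projected row always has the
alignment's column count. Hits that align with non-positive score to every
row are rejected as unalignable.

**3. One joint tree per family.** Pairwise distances over references plus
projected hits use the Kimura correction for protein p-distances,
`d = -ln(1 - p - 0.2 p^2)`, computed over shared ungapped columns. The
correction is undefined for `p >= 0.85`; such pairs, pairs sharing no
columns, and hit–hit pairs sharing fewer than 10 columns get a fixed cap
distance of 5.0 substitutions/site. The tree is built by neighbor joining
(`nj_tree()`), with any negative branch length clamped to zero and the
deficit moved to its sister branch (path lengths through the parent are
preserved). The source analysis used approximate-ML trees under the WAG
model; NJ on corrected distances was chosen for determinism and light
dependencies — the clade-membership *rule* below is unchanged, which is
what the screen's semantics rest on.

**4. The clade rule.** "Inside the clade of the references" needs a rooted
tree, and the original description never states a rooting. The package
adopts midpoint rooting (`midpoint_root()`) as a deterministic convention:
the root is placed halfway along the longest leaf-to-leaf path, which in
practice falls on the stem separating distant non-members from the family
radiation. A hit is assigned to the family iff its leaf descends from the
most recent common ancestor of the reference leaves
(`inside_reference_clade()`). Clade-confirmed counts per family are then
divided by the number of reads matching the single-copy marker *recA*
(`count_marker()`, same aligner at the stricter threshold `E < 1e-10`,
no clade step), giving per-genome-normalized abundances comparable across
libraries; the original used a profile HMM for *recA*, another documented
one-aligner substitution. A library with `recA = 0` yields undefined
normalized values, flagged explicitly — never zero or infinity.

A read that passes the clade test in several families is counted in each
(the source is silent on this case); the simulators never construct such
reads, so tests are unambiguous.

## The %Ndfa estimators

With `delta_ref` and `delta_fix` the delta-15N (permil) of a non-fixing
reference plant and the candidate fixer, natural abundance gives

    %Ndfa = 100 (delta_ref - delta_fix) / (delta_ref - B)

where `B` is the delta-15N of plant N derived entirely from air, taken as
0.0 permil by default. In enrichment mode, with atom% 15N excess =
measured atom% − 0.37 (air),

    %Ndfa = 100 (1 - excess_fix / excess_ref)

and the nitrogen-difference estimate is

    %Ndiff = 100 (N_fix - N_ref) / denominator      [shoot N, kg/ha]

The printed formula uses the *reference* shoot N as denominator, but the
published table values are consistent with a *fixer* denominator plus a
per-plot area adjustment whose numbers are not available; both modes are
implemented (`ndiff_denominator` in `bnf_config()`), with `"reference"`
(as printed) the default. Estimates are never clamped: negative reference
deltas (which occur in the published 2012 data) push %Ndfa above 100, and
such values are returned as-is with `out_of_range = TRUE` — transparency
over cosmetics. The enrichment table's isotope column is treated as atom%
*excess*: several printed values sit below the atmospheric 0.37, which is
impossible for raw atom%.

Group baselines are unweighted means over the reference varieties per
field/year/stage (`reference_mean()`). Statistics follow the source:
pooled-variance two-sample t tests (`group_compare()`, with the convention
t = 0, p = 1 when both groups are constant and equal),
single-degree-of-freedom contrasts of one test variety against the mean of
the reference-variety means with the error pooled across all groups
(`contrast_compare()`), and Pearson correlation between %Ndfa and %Ndiff
(`ndfa_ndiff_correlation()`). Reported percentages are rounded to one
decimal and delta values to two, using decimal half-up rounding
(`round_half_up()`) — the convention of the printed tables, not R's
round-half-even.

The printed enrichment table cannot be regenerated cell-exactly from its
own rounded entries (e.g. excesses 0.08/0.18 give 55.6 where 55.3 is
printed from unrounded plot data), so the packaged fixtures check formula
behavior and ranges rather than cell equality; the two quantities that
*are* exactly recomputable — the landrace mean delta-15N of 2.71 permil
from the per-field means, and the maximum %Ndiff of 82% — are asserted in
the test suite.

## The simulators: a stated world

`simulate_family()` draws a uniform-random root peptide (default 120
residues) and evolves it by Poisson substitution counts with uniform
replacement — no indels, so the reference alignment is trivially ungapped
and classification accuracy is isolated from aligner quality, and no
rate heterogeneity or realistic exchangeabilities (WAG), since the clade
test depends only on divergence separation. The guide tree is a random
coalescent over references plus held-out members, rescaled so every
root-to-tip path equals the member divergence; which tips become
references is itself random, so held-out members interleave with the
references rather than forming their own clade. Reads are always drawn
from the held-out members, never from the reference peptides — otherwise
the member-divergence parameter would be dead. Decoys model distant
homologs: a decoy root evolved from the family root at the decoy
divergence (default 1.5 substitutions/site), decoy sequences from it at
the member divergence. Defaults — 10 references, 5 held-out members, 4
decoys, member divergence 0.3 — reflect a modestly sampled curated family.

`simulate_metagenome()` samples reads from random windows of
reverse-translated member coding sequences (uniform synonymous codons,
uniform strand) with per-base substitution errors (default 1%, 150 nt
reads), plus uniform-random background for the abundance remainder. It
does not emulate quality-dependent error profiles, indels, GC skew (an
option exists, off by default), or community ecology — so a green
end-to-end test establishes that the screen's decision logic recovers
planted truth under idealized sequencing, not performance on real
libraries.

`simulate_field_trial()` produces a randomized complete block design
(default 5 blocks, matching the source trials; two reference and two
landrace varieties) where a fixer with true fraction `f*` measures
`(1 - f*) * soil + f* * B + noise` on the isotope scale of either mode,
and fixer shoot N is `reference / (1 - f*)` so the fixer-denominator
%Ndiff is exactly `100 f*`. Defaults `f* = 0.4`, soil delta-15N 6 permil,
plot noise 0.5 permil sit in the middle of the published estimates
(31–55% Ndfa) and typical tropical soil values. Noise-free runs recover
`f*` exactly in both modes, which pins the estimators' algebra; noisy
runs establish statistical recovery (mean over 20 seeds within 5 points),
not field realism.

All generators require a seed and are byte-reproducible given one.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; sequences are uppercased
  on input and `U` is mapped to `T`; FASTQ qualities are Phred-33 only and
  anything else is rejected loudly.
* The distance cap of 5.0 keeps the Kimura correction finite; it is far
  above any within-family distance at the default divergences, so capped
  pairs act as "very far" without dominating neighbor joining.
* Midpoint rooting of a 2-leaf tree is handled directly (root equidistant
  from both leaves); a tree whose branch lengths are all zero is rooted at
  the first edge with a warning.
* Tie-breaks in the screen (E-value, then raw score, then lexicographic
  reference ID) and sorted hit order inside `classify_hits()` make every
  pipeline output order-invariant and reproducible.
* `estimate_bnf()` computes estimates from variety means within groups (the
  scale on which the published tables print), and contrast p-values from
  plot-level replicates whenever the table carries them.

## Known limitations

* E-values use raw sequence lengths without edge or composition
  corrections; absolute E-values are therefore conservative approximations,
  although threshold *decisions* match standard practice.
* The clade rule depends on the rooting convention; an explicit outgroup is
  not currently supported.
* No indel or frameshift handling anywhere in the screen — real reads with
  indel errors would translate out of frame and be lost, deflating counts.
* The %Ndiff area adjustment used for the published table is exposed only
  as a user-supplied scaling of shoot N, since its values are not public.
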