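---
title: "Methods: PSI trifurcation, moderated differential splicing and GC metagene profiles"
author: "trisplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSI trifurcation, moderated differential splicing and GC metagene profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisplice)
```

`trisplice` quantifies how splicing modulators shift splicing outcomes
between intron retention (IR) and exon skipping (ES), and how resistance
genotypes redirect that shift. This vignette documents the models and
procedures, the parameters that matter, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable reading existed.

## Coordinates and strand conventions

All coordinates are 1-based and inclusive internally; BED input (0-based,
half-open) is shifted at the I/O boundary only. For an intron, the donor
is its 5′ end on the transcript strand and the acceptor its 3′ end: on
`+` the donor is the first and the acceptor the last intronic base; on
`-` the roles swap. Junctions of undetermined strand (strand code 0 in
the junction-table dialect) are retained for plain per-junction PSI but
excluded from every analysis that needs the 3′-splice-site identity
(trifurcation, GC profiles), since that identity is strand-dependent.
Only uniquely-mapping read counts are used; the multi-mapping column of
the junction dialect is ignored as the conservative default.

## PSI and the 3′-splice-site trifurcation

The PSI of a junction at a site is its read count over the summed counts
of all junctions sharing that site; donor-side and acceptor-side groups
are kept separate, and downstream IR/ES analyses use the acceptor side,
where the three-way outcome is defined. At a shared acceptor, reads fall
into three classes — ES (the junction that skips the cassette exon),
exon inclusion (the intron's own junction) and IR (reads crossing the
exon–intron boundary, supplied as boundary counts) — and the three PSIs
are the class counts as fractions of their sum. A zero total leaves all
three undefined (`NA`), never silently 0/0, and such sites are excluded
downstream with logged counts. Replicate averaging takes the arithmetic
mean of per-sample PSIs over samples where the PSI is defined, not
pooled counts, and reports how many samples contributed. No minimum
read-count filter is applied by default; the threshold exists and is 0.

How boundary-crossing reads are extracted from alignments (in
particular the minimum overhang for a read to count as crossing) is
upstream of this package: boundary counts are taken as given input.

## Moderated-t differential PSI

For each event, the two groups' defined PSI values give a difference of
means `delta_psi` and a pooled residual variance *s*² on d = n₁+n₂−2
degrees of freedom. Across events, variances are modelled as
*s*² ~ *s₀*² F(d, d₀); on the log scale this model has

- mean log *s*² = log *s₀*² + ψ(d/2) − log(d/2) − ψ(d₀/2) + log(d₀/2),
- var log *s*² = ψ′(d/2) + ψ′(d₀/2),

with ψ, ψ′ the digamma and trigamma functions, so matching the observed
mean and variance of log *s*² gives closed-form estimates of (d₀,
*s₀*²); the trigamma inverse is solved by Newton iteration. When the
observed spread of log *s*² does not exceed what a common variance would
produce, the prior is degenerate: d₀ = ∞ and *s₀*² the mean sample
variance. The moderated statistic uses the posterior variance
(d₀ *s₀*² + d *s*²)/(d₀ + d) and is referred to a t distribution with
d + d₀ degrees of freedom; at d₀ = ∞ the normal limit is used, and at
d₀ = 0 the procedure reduces exactly to the classic pooled-variance
two-sample t-test — both limits are asserted in the test suite, and the
finite-d₀ path is cross-checked against an independent implementation
(limma) on shared data.

Events with fewer than `min_samples` (default 2) defined values in
either group are reported as untestable rather than imputed: imputation
would fabricate variance. P-values are corrected by the
Benjamini–Hochberg step-up (delegated to `stats::p.adjust`, with ties
resolved by the stable sorted order), and q ≤ 0.05 is the default
significance threshold.

Category summaries report counts and fractions of significant events
per class, and the distribution of log₂((PSI₂ + ε)/(PSI₁ + ε)) with
quartiles and 1.5×IQR whisker bounds. The pseudocount ε (default 0.01,
configurable) makes the fold change defined at PSI = 0; defining the
fold change on PSI rather than raw counts is this package's documented
choice — the underlying quantity is genuinely ambiguous in this kind of
figure, and the PSI ratio is the reproducible option.

Event classification is a total function over {canonical, ES, alt5,
alt3, IR, other}: exact annotated introns are canonical; a junction
joining the donor of intron *i* to the acceptor of intron *i+1* of one
transcript is ES; a junction sharing only the annotated donor is alt3
and only the annotated acceptor alt5; boundary events at annotated
acceptors are IR; everything else is other. The extra classes exist so
that classification never fails on real junction tables.

## GC metagene profiles

Foreground sets:

- **IR pairs** — significant IR sites reduced to those whose intron has
  length ≥ 100 and which border an exon of length ≥ 50 at the intron's
  3′ end; when several transcripts offer a qualifying downstream exon,
  one is chosen at random under the run seed (reproducible). The exon
  length filter is read as "at least 50": the ES selection states "at
  least" explicitly, and the harmonized reading keeps the two filters
  consistent.
- **ES triplets** — significant ES junctions whose two flanking introns
  both have length ≥ 100 and are supported as exon-inclusion events in
  the untreated samples at q < 0.05, and whose intervening sequence is a
  single annotated exon of length ≥ 50 (junctions skipping several
  exons never match and drop out). In the pipeline, the untreated
  inclusion evidence is the site-level inclusion differential applied to
  both flanking introns, since both junctions carry the inclusion
  isoform.

Each intron is rescaled to 100 bins and each exon to 50, ordered 5′→3′
along the transcript. Bin boundaries are `floor(k·L/n)`, so bin sizes
differ by at most one base — a deterministic, order-preserving remainder
rule ("equal length" leaves the remainder unspecified). A bin's GC is
(#G+#C)/(length−#N): ambiguous bases count toward neither numerator nor
denominator, because counting N as non-GC would bias profiles toward 0;
an all-N bin is undefined and excluded from that bin's mean. Profiles
report the per-bin mean over pairs with a 95% percentile interval from
100 bootstraps resampling whole pairs (never individual bins);
percentile rather than normal-approximation intervals are used because
GC fractions near 0 or 1 are not symmetric. The background is 10,000
annotation pairs passing exactly the same filters as the foreground
selector (filter parity is property-tested), drawn without replacement
when the qualifying universe allows and with replacement (logged)
otherwise; one background is drawn per run under the run seed and
reused across panels, which keeps panels comparable.

## ES/IR switch analysis

For each significant ES site of condition A, the replicate-averaged
trifurcation PSIs of conditions A and B are tabulated side by side. A
site switches when condition B shows strictly lower ES PSI **and**
strictly higher IR PSI; exact ties do not count, the conservative
reading of "reduced … and increased". Sites with undefined trifurcation
PSI in either condition are excluded from both numerator and
denominator with logged counts — a 0/0 site carries no evidence either
way. The waterfall ordering sorts descending ES PSI in the chosen
condition with ties broken on the site key, and both conditions are
reported in that single shared order; the switch fraction is invariant
to the ordering.

## Resistant-clone variant filter

Variants are kept when the gene is on the curated list, the allele
frequency is strictly above 0.2 (the floor itself is excluded), and the
effect class is one of {missense, nonsense, frameshift, inframe_indel,
splice_site}; synonymous and unclassifiable effects are dropped. Free
text effects map through a documented synonym table (e.g. `stop_gained`
→ nonsense), with unknown strings mapping to `other` (and hence
dropped). Recurrence counts distinct clones per gene — a clone with two
variants in one gene counts once, and a clone carrying two driver
populations contributes one clone to each gene — and genes in at least
3 clones are reported with per-treatment-arm breakdowns. The curated
gene list is input: the package ships no fixed list and accepts any
one-symbol-per-line file.

## The synthetic-data generator

Each locus is a five-feature cassette gene (flank exon — upstream intron
— cassette exon — downstream intron — flank exon); the downstream
intron's acceptor is the shared 3′ splice site carrying all three read
classes. Gene strands alternate so both orientations are exercised.
Sequences are sampled base-by-base at per-feature GC targets: exons at
0.60, introns at 0.40 for unresponsive loci and 0.55 for responsive
ones — this two-level coupling encodes the observation the pipeline is
meant to recover, that GC-rich introns are the modulator-responsive
substrates. Small fractions of loci (3% each) deliberately violate the
metagene length filters to exercise the selectors' drop paths.

The design is 2 genotypes × 2 treatments × 6 replicates — hexaplicate,
matching the study design the generator emulates. Baseline trifurcation
is (ES, inclusion, IR) = (0.05, 0.90, 0.05). Locus labels and planted
effects, all moving probability mass out of the inclusion class:

| label | treated wild type | treated mutant |
|---|---|---|
| null (65%) | baseline | baseline |
| ir (10%) | IR +0.40 | IR +0.10 (attenuated) |
| es_switch (16%) | IR +0.40 | ES +0.40 |
| es_noswitch (9%) | ES +0.47, IR −0.04 | ES +0.40 |

Among ES-responsive loci the switch fraction is therefore 0.16/0.25 =
64%, the headline proportion this analysis is designed around. The
non-switch loci respond at least as strongly in the wild type (ES
slightly higher, IR slightly lower) so that their planted state is
decisively "not a switch" rather than a coin-flip tie under replicate
noise; with hexaplicate averaging at depth 200 the per-condition mean
PSI has a standard error near 0.02, well below every planted gap.

Counts: per locus and sample, the total informative read count is
negative binomial (mean 200, size 60, ~15% CV); the three-way split is
Dirichlet-multinomial around the condition's trifurcation probabilities
(concentration 300), because biological replicates overdisperse relative
to a pure multinomial and the moderated-t stage should be exercised
under realistic variance heterogeneity. The inclusion count is also
written to the upstream intron's junction, which the inclusion isoform
crosses. A single master seed derives per-stage child seeds through a
fixed documented scheme, so any stage can be regenerated alone.

What the generator does **not** emulate: read-level artefacts
(mappability, positional bias, overhang filters), expression-level
confounding between loci, annotation incompleteness, multi-isoform
genes beyond one cassette event, and correlated effects between
neighbouring loci. Passing recovery tests on this generator therefore
demonstrates the correctness of the estimators and selection logic, not
robustness to alignment-level artefacts in real RNA-seq.

Clone variants: two planted recurrent drivers (7 and 5 clones across
two 6-clone treatment arms, echoing a two-compound resistance screen)
over a Poisson background (rate 3/clone) of passenger variants with
AF ~ U(0.05, 1) and mixed effect classes.

## Problem sizes and runtime choices

The default generator scale is 2,000 loci × 24 samples, which gives
stable statistics for every stage while keeping a full end-to-end run
around a minute on one core. The test suite validates the estimators at
the scales its property checks need (10,000 fuzzed trifurcations, 1,000
pooled-t reductions, 2,000 simulated variances for prior recovery,
5,000-event null calibration, a 3,883-site switch cohort, and one full
2,000-locus end-to-end run); the acceptance script repeats the headline
computations from scratch under a caller-supplied seed.

## Known limitations

- Junction PSI groups are per-site (donor and acceptor separately);
  pooling both sides into one denominator is a variant definition the
  package deliberately does not implement.
- The trifurcation assumes one cassette event per acceptor; nested or
  overlapping events at the same acceptor are not modelled.
- The untestable-event policy (report, don't impute) means events
  defined in only one condition never reach the significant set, which
  can undercount categories in sparse data.
- Boundary counts are trusted input; no overhang or mismatch filtering
  is applied within the package.
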