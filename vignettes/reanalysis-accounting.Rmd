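---
title: "Re-evaluating an exome screening cohort: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-evaluating an exome screening cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomereval)
```

# The problem

A research exome cohort published years ago carries three kinds of decay.
Variant classifications drift as guidelines and population databases evolve;
gene–disease associations (GDAs) that once looked solid can fail to
replicate, while others accumulate enough reports to become established; and
the original filtering inevitably missed variants that a modern annotation
pass would surface. `exomereval` implements the computational stages of a
systematic revisit of such a cohort — here a consanguineous
neurodevelopmental-disorder (NDD) screening study of 152 families — as
testable, reusable functions. It deliberately stops at the annotation layer:
alignment, variant calling, copy-number and run-of-homozygosity detection
from reads are upstream of this package and enter only as annotations on the
variant table.

# Variant classification

## Evidence codes and parsing

The 28 ACMG/AMP evidence codes (PVS1, PS1–PS4, PM1–PM6, PP1–PP5, BA1,
BS1–BS4, BP1–BP7) each have a fixed direction and a default strength given
by their prefix. Curation tables apply codes at modified strengths
(`PM3_Supporting`, `PVS1_Moderate`), and real tables are typographically
messy: the same table can print `PS4_supporting` and `PS4_Supporting`, and
may embed free-text comments directly in the criteria cell
(`PP3(accordingtounpublisheddata)`). The parser therefore matches modifiers
case-insensitively, accepts a modifier of any level for any code (curators
do both up- and down-grade across several levels), and strips parenthetical
comments into an `annotation` field that never influences classification.
Two deliberate restrictions: tokens must use the underscore-joined CamelCase
dialect after case-folding (no spaced `"_Very Strong"` spelling), and a code
may appear at most once per set.

## Two engines

The package provides both classification systems in current use and treats
neither as a reimplementation of the other:

* **Points engine** (default for pipelines): Supporting/Moderate/Strong/Very
  strong score 1/2/4/8, negated for benign-direction codes; the total maps
  onto P ≥ +10, LP +6..+9, VUS 0..+5, LB −6..−1, B ≤ −7. These bounds
  partition the integers with no gaps.
* **Rules engine**: the published 2015 evidence-combination rules evaluated
  at *effective* strengths, plus the two-very-strong pathogenic combination
  from later best-practice guidance.

Both engines reproduce all 26 printed tiers of the study's two variant
tables (checked in the test suite), but they are not equivalent in general —
`PVS1,PM2` reaches 10 points (P) yet only the likely-pathogenic rule
combination:

```{r}
classify_points(parse_criteria("PVS1,PM2"))
classify_rules(parse_criteria("PVS1,PM2"))
```

Two resolution choices were genuinely open and are fixed as follows. `BA1`
is stand-alone and short-circuits to benign in both engines regardless of
other evidence. Sets mixing pathogenic- and benign-direction evidence are
never averaged by the rules engine: they resolve to VUS with the conflict
flag set. The second choice matters in practice — a set like
`PVS1_Strong,PM2,BS3` would otherwise satisfy a likely-pathogenic
combination while carrying strong benign evidence; resolving to VUS is the
conservative reading and matches how such conflicted variants are reported.

# Gene–disease validity

The validity rule is intentionally simple (the study predates an agreed
community standard): an association is **established** with at least three
reported families from at least two independent research groups in separate
publications. Functional data — wet-lab work interrogating the gene
product's function, including animal models but excluding bare expression
assays — compensates when the count evidence is thinner. We implement the
compensation clause as *functional data plus at least one published family*.
A stricter reading ("exactly two families, or exactly one group") is
non-monotone: a gene with one family, one group and functional data would be
established, then lose that status when a second independent group reports —
an absurdity for a validity measure. The monotone reading reproduces every
printed gene classification, including the one association judged below
threshold (three families but a single reporting group and no functional
data). Counts printed as lower bounds (`">14"`) are taken at the bound,
which suffices for threshold rules.

# The 3-step triage screen

Full manual re-analysis of every case does not scale, so the screen reduces
re-analysis to three cheap rules over an annotated variant table: (a) rare
likely loss-of-function variants, (b) variants known pathogenic in a
knowledge base, (c) rare missense variants at a protein position already
carrying a pathogenic missense variant. Design parameters, all configurable
in `screen_config()`:

* *Rarity*: the source procedure says only "rare". Defaults are conventional
  rare-disease cutoffs — popmax allele frequency < 0.1% for heterozygous
  candidates, < 1% with zero reference homozygotes for homozygous or
  hemizygous candidates. A missing frequency counts as zero.
* *Loss of function*: stop-gain, frameshift, canonical splice and start-loss
  (a start-loss diagnosis in the study is treated as disruptive).
* *Knowledge base*: ClinVar/HGMD membership is abstracted into an explicit
  snapshot (`knowledge_base()`), keyed by exact variant key after whitespace
  normalisation and by gene + protein position — no live database, no allele
  normalisation, no liftover. Rule (c) matches the position only, exactly as
  the screen is worded.
* *Quality*: variants failing the caller's quality flag are excluded but
  tallied, since one true diagnostic variant in the study was lost to a
  quality threshold.

The packaged knowledge snapshot is synthetic and assumption-flagged: the
study reports that 10 of its 12 novel (likely) pathogenic variants would
have been caught (83%) but not which two escape. The snapshot encodes the
one assignment we consider best supported — the two misses are the missense
variants described as resting on unpublished data or in a gene whose
variants are predominantly of uncertain significance — and the fixture
headers say so.

# Cohort accounting

Family-level conclusions use a five-level scale (pathogenic >
likely_pathogenic > VUS > candidate_gene > negative) with one gating rule:
a family is *diagnosed* only by a P/LP variant in an established gene. A
P/LP variant in a non-established gene is a candidate-gene finding; this is
what makes a GDA downgrade clinically relevant even when the variant-level
classification is untouched. Percentages are rounded half-up to integers.
One reported share in the source (35/37 = 94.6% printed as 94%) is a
truncation rather than a rounding; the package asserts the counts and
reports half-up percentages.

The per-family composition behind the study's yield arithmetic (37% → 30% →
41%) is not printed anywhere; the packaged 152-family table is a documented
*reconstruction*: 56 families diagnosed at publication (37 pathogenic
variants in 36 families plus 20 likely-pathogenic families), 11 of them
losing the diagnosis to downgrades (10 variant-level, 1 GDA-level), and 17
gaining one (12 novel diagnoses, 5 newly established GDAs). It reproduces
every printed marginal simultaneously but is one consistent assignment, not
a unique solution — its header and `load_fixture()`'s documentation flag
this. The 28 change families are disjoint in this table; overlapping events
in one family (a downgraded VUS plus a novel diagnosis) are exercised by the
variant-level fixture and unit tests instead.

# The synthetic generator

`generate_cohort()` and `generate_variant_table()` emulate the features of
the real cohort that the analysis depends on:

* strata 44/79/24/5 (simplex through four-plus affected), 63% male affected,
  all consanguineous;
* a platform-quality mix (default 35% low-quality, reflecting the roughly
  one-third SOLiD share of usable sequencing files in the study) driving the
  background count of rare homozygous calls surviving filtering: negative
  binomial with the mean calibrated numerically so the distribution median
  sits at the configured target (28.5 low-quality vs 10 high-quality;
  dispersion 8 is an artifact choice, configurable);
* planted causal variants in a configurable fraction of families (default
  0.41, the corrected diagnostic yield) with a profile mix 5:4:1:2 over
  rule-A / rule-B / rule-C / screen-undetectable, mirroring how the 12 novel
  variants distribute over the screen's rules; each profile carries a
  criteria template classifying P or LP, the undetectable profile being a de
  novo missense absent from databases — causal but invisible to the screen.

What the generator does **not** emulate: genomic coordinates and real gene
symbols, linkage/RoH segment structure, compound heterozygosity, caller
artifact spectra beyond a Poisson heterozygous add-on, and any correlation
between family structure and causal-variant class. Background variants are
constructed to be screen-negative (no loss-of-function consequences,
positions disjoint from the knowledge base), so recovery tests measure the
plumbing exactly: passing them shows the screen recovers what it is promised
and nothing else under this noise model — not that it would achieve 83%
sensitivity on real data, which depends entirely on the knowledge snapshot.

Determinism: all generators take explicit seeds, save and restore the
global RNG state, and are byte-identical across runs for a fixed seed.

# Problem sizes and numerical choices

The test suite exercises the generators at 1000 families for the
median-calibration check (sample median within ±2 of the target) and at
100–152 families elsewhere; the end-to-end causal-fraction recovery is
asserted within three binomial standard errors at n = 152. The negative
binomial mean for a target median is found by root-solving
`P(X ≤ floor(m)) = 0.5` in the mean, which is continuous and monotone even
though the quantile is a step function. Evidence points and tier bounds are
exact integer arithmetic; ties cannot occur.

# Limitations

* Criteria are consumed as applied; nothing derives which codes a variant
  deserves from raw evidence (no PVS1 decision tree, no PS1/PM5 lookup).
* Rule (b/c) matching is string- and position-exact; representation
  differences between variant descriptions are out of scope.
* The GDA rule is binary-ish by design and coarser than semi-quantitative
  gene-validity frameworks.
* The 152-family reconstruction and the knowledge snapshot are consistent
  assignments, not ground truth; conclusions that depend on *which* families
  or variants fill the margins should not be drawn from them.
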