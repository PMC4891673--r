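---
title: "epigraft: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epigraft: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigraft)
```

This vignette is the package's own account of the statistics it computes,
the conventions it fixes where the field leaves room, and what its
synthetic-data tests do and do not establish.

## The MSAP state model

MSAP scores a CCGG locus in two digests. *Hpa*II is blocked by full
methylation of either cytosine and cuts hemimethylated external-C sites;
*Msp*I cuts regardless of internal-C (CG) methylation but is blocked by
external-C (CHG) methylation. The joint presence pattern therefore encodes
four states: (1,1) unmethylated (I), (1,0) CHG methylation (II), (0,1) CG
methylation (III), (0,0) methylation at both contexts (IV). The mapping is
a bijection, which the tests verify by round-tripping. Missing band calls
are represented explicitly as unscored (`NA`), never as absence: an
unscored locus leaves both the numerator and the denominator of every
ratio. This matches gel practice, where unstable gel regions are simply
not scored.

Methylation *levels* are band ratios over scored loci: total methylated
(II + III + IV) and fully methylated (III + IV), each over
(I + II + III + IV). Reported percentages are rounded **half away from
zero** to 2 decimals, because that is the convention published MSAP tables
follow (base R's banker's rounding would differ on exact halves); all
downstream computation uses the unrounded values, which are kept in the
result object.

### Comparing levels between samples

The source analyses cite an external protocol for the level comparison
without restating it. We fix the test to **Fisher's exact test** on the
2 × 2 table (methylated vs unmethylated) × (sample A vs sample B), with
chi-square available behind a flag. Rationale: exact at any count, no
distributional assumption, and at ~900 loci the two agree closely anyway.
The unit tests check the Fisher route against an independently coded
hypergeometric tail sum.

## Transition classes and the DMF partition

States are partially ordered by methylation load: IV > {II, III} > I.
A reference → sample change toward I is demethylation, away from I is
methylation, equality is no change. The two incomparable transitions
II ↔ III (a CHG/CG context swap visible as a band-pattern exchange) cannot
be called a gain or a loss; they get a separate INTERCHANGE class and are
excluded from hyper-/hypomethylation percentages. Enumerating the 16
ordered pairs yields 4 no-change, 5 demethylation, 5 methylation and 2
interchange transitions — exactly the published 14-letter taxonomy
(A–D, E–I, J–N) plus the two interchanges. Which letter names which pair
is typographically unknowable from the source table (it survives only as
an image), so letters are treated as display labels; the identity of a
subclass is its ordered state pair.

A locus is a **DMF** when at least one scored individual differs from the
reference; it is **uniform** when *every* scored individual differs and
all share one state, **distinctive** otherwise. Note the strict reading:
a locus where all individuals changed but to different states is
distinctive, as is a locus changed in only some individuals. Percentage
denominators for pattern frequencies are all scored loci, following the
published convention of dividing by the total band count.

## Inheritance tracking

The inheritance ratio of a later generation at a uDMF locus is
(individuals carrying the GS1 variant state) / (all assayed individuals
of that generation). Two conventions are fixed here:

* **Unconditional denominators.** Later-generation individuals are not
  conditioned on whether their parent retained the variant; the printed
  denominators of the source table equal the stated panel sizes
  (15/15/10/10), which settles the reading.
* **Exact retention.** "Retained" means the state equals the GS1 variant
  exactly; reversion to the reference and change to any third state both
  count as not retained.

Verdicts: STABLE iff every generation's ratio is 100%; LOST iff the
variant is absent from every individual of the *final* generation (so a
locus that disappears and reappears is REVERTING, and dropping
intermediate generations cannot change a LOST verdict); REVERTING
otherwise.

The bundled printed inheritance table is shipped as a plain-text fixture.
One cell of the source prints a denominator inconsistent with its own
percentage and with the stated panel size (a 15 where the generation has
10 plants); the fixture carries the corrected denominator, noted in its
header, and the parser enforces pct = retained/n so such inconsistencies
cannot pass silently.

## Bisulfite clone calling

Contexts (CG, CHG, CHH with H ∈ {A, C, T}) are assigned from the
*reference* amplicon only — clone bases never influence context. A
cytosine within two bases of the 3' end whose context cannot be resolved
is flagged indeterminate and excluded from calling.

Clones are treated as reads of the amplicon's top strand (bisulfite PCR
primers select a strand), so no reverse-strand symmetric-CpG aggregation
is attempted. Alignment is global pairwise with affine gaps
(Biostrings), with a conversion-aware substitution matrix in which clone
T opposite reference C scores as a match — a fully converted unmethylated
clone aligns as a perfect match. Clones below 90% conversion-aware
identity are rejected; columns where the clone reads N are excluded from
the identity denominator (an N is missing evidence, not a mismatch).
Calls: C at a reference-C position is METHYLATED, T is UNMETHYLATED,
anything else (gap, N, other base) AMBIGUOUS; ambiguous calls leave both
numerator and denominator. Percentages are pooled over clones (total
methylated calls / total scored calls), the standard clone-counting
convention, rather than averaging per-clone percentages. Coordinates are
1-based in all outputs.

Conversion efficiency is estimated from contexts the caller designates as
assumed-unmethylated (default CHH, rarely methylated in plants):
T calls / scored calls there. When true CHH methylation is nonzero this
is an underestimate, which is why the recovery tests that target the
conversion rate simulate with `p_chh = 0`.

## siRNA differential expression

The original analysis used a published count-based DE package on pooled
replicate libraries. At desk scale we emulate its null directly: under no
differential expression, a sequence's pooled count splits between the two
groups in proportion to their library sizes. The test is the two-sided
exact binomial test of the group-A pooled count against that proportion;
multiplicity is handled by Benjamini–Hochberg (the source's "adjusted
g-value" is read as the adjusted p/q-value). Fold changes are computed on
pooled counts-per-million with a 0.5-cpm pseudocount applied to the ratio
only — never to the test — to keep log2FC finite. "|fold change| ≥ 1" is
read as |log2FC| ≥ 1, since the source states fold change was computed as
a log2 ratio. Calls require both |log2FC| ≥ 1 and adjusted p < 0.05.

Matching differential siRNAs to DMF sequences is exact substring search,
both strands, U ≡ T, all occurrences reported; a mismatch-tolerance flag
(default 0) exists for exploration. Exact matching is the verifiable core
— every reported match is re-checkable by direct substring comparison,
which the tests do.

## Synthetic data: the stated world

Generator defaults are the study's scales: 926 loci, 7 first-generation
individuals, reference state frequencies equal to the published parent
profile (489/140/292/5 over 926), an induced-change rate of 76/926, a
uniform fraction of 32/76, generation panels of 15/15/10/10, ≥ 10
bisulfite clones, 18–30-nt siRNAs with a length distribution peaked at 21
and 24 nt and ~10^6-read libraries.

Two modelling choices deserve explanation:

* **Direction-conditioned change rates.** Demethylation can only happen
  at loci that are methylated. If changed loci were drawn uniformly and
  only then assigned a direction, demethylation could never exceed ~47%
  of events with the parent's state mix, contradicting the observed
  predominance of demethylation after grafting. The generator therefore
  solves two per-locus event rates (demethylation on states II–IV,
  methylation on I–III) from `change_rate` and `demeth_odds` so that the
  expected changed fraction and the expected demethylation : methylation
  event ratio (default 1.6 : 1, the middle of the published 2.92–4.21%
  vs 1.62–2.81% ranges) are both honored.
* **Independent per-individual reversion.** In the generation simulator
  each individual of each generation reverts each variant locus
  independently with probability *r*; a locus's truth verdict is STABLE
  iff no reversion was sampled anywhere. With panels totalling 50
  individuals this gives the closed form P(stable) = (1 − r)^50, which
  the acceptance suite verifies by Monte Carlo. This is deliberately not
  a pedigree model: the source does not record which later-generation
  individuals descend from reverted parents, and the unconditional
  denominators make the panel-wise Bernoulli model the matching one.

Determinism: each generator takes one seed and derives a fixed sub-seed
per internal stage (R's RNG has no counter mode), so identical seeds give
byte-identical outputs and revising one stage does not shift another's
draws; the pre-existing RNG state of the session is restored afterwards.

What a green synthetic test establishes: that each analysis stage
recovers exactly (band states, DMF partition, verdicts) or within
binomial/Monte-Carlo error (context percentages, type-I rate, stable
fraction) the parameters of the generating model. What it does not
establish: robustness to gel artefacts, scoring errors, PCR bias in clone
libraries, or overdispersion structure beyond the negative-binomial — the
generators deliberately do not model band-calling noise or
sequencing-error processes other than bisulfite conversion.

## Numerical and degenerate-input conventions

* Rounding half away from zero, 2 decimals, at the reporting boundary
  only; a 1e-9 guard absorbs floating-point representation of exact
  halves.
* Empty profiles, all-unscored columns, empty ratio series and zero
  library sizes are errors, not NA results; a context with zero scored
  calls reports NA and propagates NA through region differences.
* Replicate consensus is per-cell majority with ties unscored — with the
  study's three technical replicates ties only arise through missing
  data.
* All thresholds (α = 0.05, |log2FC| ≥ 1, 90% clone identity, 0.5-cpm
  pseudocount) live in `default_config()`; stage code takes them as
  arguments.

## Known limitations

MSAP sees only CCGG sites, so "genome-wide" levels are relative to that
site class; hemimethylation and full CHG methylation are not
distinguishable beyond the four-state code. The DE emulation tests the
proportional-split null, not a replicate-variance model: with strong
biological overdispersion between replicates its p-values are
anticonservative, which is why replicates are pooled (as the source did)
and the null-calibration guarantee is stated for the binomial sampling
model. Sequence annotation of DMFs (transposon/exon classification) and
read-level small-RNA preprocessing are out of scope.
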