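---
title: "The ucicross transmission model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ucicross transmission model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucicross)
```

## The model and its assumptions

Unilateral cross-incompatibility (UCI) in maize is modeled here as a
pair of boolean determinant flags per haplotype at each UCI locus: P
(male determinant, pollen-expressed) and F (female determinant,
silk-expressed).  The four flag combinations map onto the field's
nomenclature — S (both), M (P only), wildtype (neither), and the
hypothetical F-only class, which `classify_haplotype()` represents but
flags: a natural F-only line would be self-incompatible, and none has
been observed.  F-only haplotypes do exist artificially, as
female-determinant transgene insertions, which is the reason the type
admits them.

Three rules generate every prediction in the package:

1. **Sporophytic, dose-dependent female barrier.** A silk expresses a
   barrier at a locus iff its diploid allele dose of F at that locus
   reaches `female_dose_threshold` (default 2).  The single dose rule
   reproduces both the recessive behaviour of the heterozygote (an
   S/wt F1 silk accepts wildtype pollen) and the inertness of a
   *hemizygous* female-determinant transgene, while a homozygous
   transgene raises a working barrier.  The threshold is configurable
   to 1 for hypothesis comparison only.
2. **Per-system barrier matching.** Each locus belongs to a *system*
   (Ga1, Ga2, ...; default: its own id).  The dose is counted per
   locus, but an active barrier is indexed by system, and pollen
   rescue likewise: the transgene copy of the Ga2 female determinant
   (registered in system "Ga2") raises a barrier that pollen carrying
   the *native* Ga2 male determinant passes.  A literal per-locus
   rescue rule would wrongly reject M-haplotype pollen on transgenic
   silks; the per-system rule is the only reading consistent with the
   transgenic validation crosses, and it generalizes cleanly to the
   pyramided two-system genotypes, whose silks demand P in *both*
   systems from every grain.
3. **Gametophytic male action.** Each pollen grain is judged by its own
   haploid content.  This is what makes a half-compatible heterozygous
   donor give a *full* ear on a barrier silk while shifting the
   offspring genotype distribution (complete transmission distortion):
   selection happens among grains, not among plants.  A
   sporophytic-male variant (the donor plant's diploid genotype decides
   for all its grains) is selectable solely for architecture
   comparison.

Offspring distributions are exact enumerations: maternal gametes are
never selected, paternal gametes are filtered and renormalized, and
genotypes aggregate as unordered pairs of multi-locus haplotypes (phase
is kept internally because linked-gamete enumeration needs it; no
parent-of-origin effects are modeled).  A fully incompatible pollen
pool yields an *empty distribution with rejected fraction 1* — a barren
ear is a phenotype class, not an exception, so pipelines can count it.

### The female side of the architecture comparison

The "gametophytic female" variant moves selection to the ovule: a
maternal gamete carrying F accepts only pollen carrying P of the same
system.  Run over the full female-test pedigree this reproduces the
classical counterfactual exactly — the backcross population would
contain only wildtype homozygotes and *every* test-pollinated plant
would set full seed — which is what lets sample sizes near 190 reject
the gametophytic hypothesis decisively.  The dose-1 variant turns out
to be even more sharply discriminated than a ratio shift: it predicts
the heterozygous F1 silk already carries a barrier, so the female
backcross that was actually made could not have existed
(`predict()` returns a `barren-pedigree` outcome rather than a ratio).

## Seed set and kernel readouts

Ears are phenotyped in the field as binary: full versus essentially
barren ("fewer than ~5 seeds").  The engine therefore uses a
pollen-excess saturation model: with ovule number N (default 300), any
nonzero compatible pollen fraction fills the ear; a fully rejected pool
leaves only stray contaminant seeds, N x `contamination`.  The default
classification threshold of 5 seeds, with a contamination rate of 1%
and N = 300, places a contaminated barren ear at ~3 expected seeds —
inside the "low" class, which is precisely why the <5-seed field
convention is robust.  Intermediate seed set (partial barrier
penetrance) is deliberately out of scope: the modeled experiments
report complete exclusion.

Kernel color is a dominant auxiliary marker (purple over yellow) scored
on the offspring genotype.  Mixed pollination is modeled as
grain-competition: a component's contribution is its pool proportion
times its surviving fraction.  Sequential pollination (first one
donor, then another) is modeled as per-component selection followed by
weighted mixing with `sequential_weights`, default 0.5/0.5.  The mixed
ears of the validation experiments show both colors but no printed
proportions, so these weights are free parameters of the stated world,
fixed once at equality.

## The design catalog

The sixteen cataloged experiments (D1–D13 plus the hemizygous and
control variants D10h/D11c) are *data*, not code: a JSON fixture lists
each pedigree as cross/self steps over named founder genotypes, the
readout type, the ordered phenotype classes, and the published sample
size and counts where they were printed.  Founder genotypes are fixed
as: the S-haplotype tester 511L; wildtype lines W22, B104, Zheng58,
Chang7-2 and the purple-kernel ZYM1; the M-haplotype line Mo17; the
Ga1-S line SDGa25; the pyramided double homozygote; and transgenic
stocks for both determinants.

One deliberate modeling convention: compatibility-matrix designs (the
transgenic male validation, the field-isolation panel, and the
pyramiding matrix) expose a class-probability vector as the fraction
of matrix cells per outcome, with uniform cell weight.  This keeps
every catalog design samplable by the synthetic generator and testable
by the same convergence machinery.

The female test deserves its own note.  Exact enumeration under the
package's default architecture gives a no-seed probability of 1/8 —
a **7:1** ratio — for the female BC1F2 test: the backcross segregates
1:1, selfing the heterozygous half contributes 1/4 barrier homozygotes,
and pooling gives 1/8.  The ratio historically attached to this
experiment is 8:1.  The catalog stores the enumerated 7:1 as the model
prediction and carries 8:1 as the reported claim; the statistics module
tests the observed 167:21 against *both* (neither is rejected,
exact p = 0.66 and 1.00) and quantifies their indistinguishability:
the exact-enumeration power to reject 8:1 when 7:1 is true at n = 188
is about 0.10.  The package reproduces conclusions, not printed test
statistics — the published chi-square values for these tables do not
match the standard Pearson statistic under any ratio we tried, so they
are recorded in the project notes and never emulated.

## Statistics: conventions and numerical choices

* `chi2_gof()` is the standard Pearson statistic with df = k − 1;
  Yates continuity correction is optional and two-class only.
* `exact_test()` is two-sided by the "at least as extreme in
  probability" convention — the p-value sums the null probabilities of
  all outcomes no more probable than the observed one.  Conventions
  differ across software, so this is stated explicitly; a relative
  tolerance of 1e−7 guards the ≤ comparison against floating-point
  ties.  Two classes use the binomial at any n; k > 2 enumerates the
  full multinomial space subject to a budget (default 2e6 outcomes)
  and directs the user to Monte Carlo power methods beyond it.
* `ratio_power()` enumerates the exact-test rejection region under the
  null and sums true-distribution mass over it.  Because the test is
  discrete, achieved size is at most alpha (0.035 at n = 100 for 1:1),
  and power is monotone in n only up to discreteness jitter.
* alpha defaults to 0.05, matching the "P > 0.05" reporting style of
  the experiments.  No multiple-testing machinery is provided, since
  the modeled analyses performed none.

## The mapping simulator's stated world

The experiments report physical interval sizes only (1.21 Mb and
1.7 Mb).  The default marker panel therefore *invents* plausible
physical positions for M1..M11 — anchored so that M8−M5 = 1.21 Mb and
M8−M3 = 1.70 Mb, with the male determinant between M5 and M8 and the
female determinant between M3 and M8 — and converts them to map
positions with a local rate of 0.2 cM/Mb.  The rate is a fixture
assumption, justified qualitatively by the paucity of recombinants
recovered in a sixteen-thousand-seed screen near this interval, and is
configuration, never hardcoded: all logic consumes the panel object.
Breakpoints fall uniformly within marker intervals (Haldane model, no
chiasma interference).

Interval narrowing (`localize()`) treats each single-crossover
recombinant as a half-line constraint: a determinant-carrying
recombinant places the determinant on its donor-allele side of the
breakpoint, a non-carrier on the other side, and the refined interval
is the intersection.  Which phenotype call marks a carrier depends on
the screen: "C" (cross-compatible) in the pollen screen, where
survivors carry the male determinant, but "CI" in the female screen,
where the *incompatible* plant is the barrier homozygote; screen
objects carry their own convention.  Multi-crossover gametes are
counted and set aside rather than parsed.  Contradictory constraints
raise an error naming both offending individuals — in real data that
pattern signals a genotyping or phenotyping error, and silently
intersecting it would fabricate an interval.

The backcross simulator implements single-seed descent with foreground
selection: the donor segment is held heterozygous while each unlinked
background donor allele survives a generation with probability 1/2,
giving the closed-form expectation (1/2)^(g+1) ≈ 0.2% donor background
after eight generations, and homozygous fixation with probability 1/4
at the final selfing.

## What the synthetic generator does and does not emulate

`gen_counts()`, `gen_marker_table()`, and `gen_ear_dataset()` draw
finite samples from the exact model distributions, with three
independent noise channels: seed-set **misclassification** (acts on
the scored class label, mirroring how ears are misread in the field —
never on the latent genotype), pollen **contamination** (stray
compatible grains on otherwise barren ears), and per-marker
**genotyping error**.  All default to zero: the stated world of the
modeled experiments is clean scoring, and with zero noise the
generated data are exactly model-distributed (the test suite verifies
size calibration of the exact test and convergence of empirical
frequencies at n = 1e5 within three binomial standard errors).

A green test against synthetic data therefore establishes that the
pipeline is a correct realization of *this* model — it cannot
establish field realities the model excludes: partial barrier
penetrance, pollen-tube growth kinetics, flowering-time confounding of
sequential pollination, segregation distorters other than the UCI
loci, or marker ascertainment bias.  Seeds derive per-operation
substreams from one global seed and are echoed into every output
header, so any table is replayable byte-for-byte.

## Known limitations

* Compatibility is boolean; no molecular model of PME activity or
  determinant protein interaction is attempted.
* Kosambi distances between non-adjacent loci are computed through the
  map function on total cM, which is exact for Haldane (no
  interference) but an approximation under Kosambi.
* Sequential-pollination weights are unidentified free parameters
  (no printed kernel proportions exist to calibrate them).
* The catalog's compatibility matrices summarize cells with uniform
  weight; this is a reporting convention, not a biological claim.
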