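# ucicross

Exact cross prediction and simulation for maize unilateral
cross-incompatibility (UCI) loci.

## The problem

Certain maize genotypes hybridize in only one direction: pollen from a
wildtype plant is rejected on the silks of a *Ga2-S* (or *Ga1-S*,
*Tcb1-S*) plant, while the reciprocal cross succeeds.  Each UCI locus is
governed by a tightly linked determinant pair — a pollen-expressed
**male determinant** (P) that lets a pollen grain overcome the barrier,
and a silk-expressed **female determinant** (F) that raises it — giving
three haplotype classes: **S** (P and F), **M** (P only), and wildtype
(neither).  Crosses involving such loci show non-Mendelian segregation:
pollen selection distorts transmission ratios, and the barrier phenotype
segregates by rules that differ between the male side (gametophytic:
each grain judged by its own haploid genotype) and the female side
(sporophytic and recessive: the diploid silk needs two F doses).

`ucicross` turns this transmission model into a computable engine for
geneticists and breeders: every segregation ratio, transmission test,
transgenic-validation readout, and locus-pyramiding outcome in the
classical *Ga2* experimental repertoire is an exact, testable prediction
rather than a narrative claim.

## The model

For a silk genotype *g* and locus *l* with dose threshold *t* (default
2), the barrier is active iff

    dose_F(g, l) >= t            (sporophytic female rule)

Barriers and rescue are matched per *system* (so a transgene copy of the
Ga2 female determinant raises a barrier that native Ga2 male-determinant
pollen can pass).  A pollen grain with haploid allele set *a* is
compatible iff for every system *s* with an active barrier

    exists locus l in s : P(a[l]) = TRUE      (gametophytic male rule)

Offspring distributions are exact: maternal gametes segregate freely,
paternal gametes are filtered and renormalized, and linked loci
recombine under Haldane's (or Kosambi's) map function.  Seed set follows
a pollen-excess saturation model (any nonzero compatible fraction fills
the ear; ears with at most 5 expected seeds are classed "low").
Goodness-of-fit uses the standard Pearson statistic and a two-sided
exact multinomial test with power calculations by exact enumeration.

## Worked example

```r
library(ucicross)
reg      <- ga2_registry()            # gametophytic male, sporophytic dose-2 female
founders <- uci_founders(reg)

# the selection backcross: 511L females x (W22 x 511L) F1 pollen
f1 <- cross(reg, founders$W22, pollen_pool(founders$`511L`))$genotypes[[1]]
cross(reg, founders$`511L`, pollen_pool(f1))
#> <offspring distribution> 1 genotype(s), rejected pollen fraction 0.5
#>                                         genotype probability
#>  Ga2-S,ga1,-,-,r1-yellow|Ga2-S,ga1,-,-,r1-yellow           1
```

Half the pollen (the `ga2` grains) is rejected and every survivor is
`Ga2-S/Ga2-S`: the homogeneous population that makes phenotype-free fine
mapping possible.

```r
predict_design("D7", registry = reg)   # sporophytic-female test at n = 188
#> <expected_outcome> D7: full:none = 7:1
#>  class probability
#>   full       0.875
#>   none       0.125

obs <- read_counts_tsv()               # the printed field counts
exact_test(obs$D7, "7:1")
#> <gof> method = exact_multinomial, statistic = 0.07864, p = 0.6595

ratio_power("8:1", "7:1", n = 188)
#> <power> n = 188, alpha = 0.05, power = 0.1004 (exact_enumeration)
```

The model's exact prediction for the female BC1F2 test is **7:1**
(no-seed probability 1/8); the observed 167:21 is consistent with it
(exact p = 0.66) and also with the historically reported 8:1 — and the
power calculation shows why: at n = 188 a test of 8:1 against a true 7:1
rejects only ~10% of the time, so the printed data cannot separate the
two.

Other entry points: `design_catalog()` (all 16 cataloged experiments),
`compare_architectures()` (gametophytic vs sporophytic hypotheses),
`simulate_screen()` / `localize()` (fine-mapping screens),
`gen_counts()` / `gen_marker_table()` / `gen_ear_dataset()` (seeded
synthetic data), `reproduce_paper()` (one-shot consolidated report), and
the `exec/ucicross` command line (`predict`, `gof`, `power`, `simulate`,
`mapsim`, `reproduce-paper`).

## Further reading

The methods vignette (`vignettes/uci-model.Rmd`) documents the model
assumptions, the fixture choices behind the marker panel and noise
model, numerical conventions, and known limitations.
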