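---
title: "Models and methods behind kinnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinnet)
```

kinnet reconstructs kinship structure in small, partially sampled wild
populations typed at codominant microsatellite loci. It was designed around
the analysis chain used for small coastal shark populations — a few tens of
adults, a few dozen juveniles caught in nurseries, 14–16 microsatellites —
but nothing in the code is taxon-specific. This vignette describes the
models, the tunable parameters, the numerical choices, and what the
simulation-based tests do and do not demonstrate.

## Data model

A `genotype_table` stores one unordered diploid genotype per individual and
locus; allele codes are opaque positive integers (typically fragment sizes).
A cell is either fully typed or fully missing: half-calls are rejected at
parse time because every downstream likelihood conditions on a complete
two-allele observation. Genotypes arrive in GenePop (2- or 3-digit) or a
two-column-per-locus CSV dialect; both round-trip losslessly.

Individual metadata (sex, total length, maturity stage, residency group,
site, cohort year) travel in a separate table. Stage is cross-checked
against length: juvenile < 100 cm, immature 100–199 cm, mature ≥ 200 cm.

## Marker quality control

Allele frequencies are plain counts over typed gene copies. Expected
heterozygosity uses the small-sample correction `He = 2n/(2n−1) · (1 − Σp²)`
because the intended sample sizes are tens of individuals. `Fis` is
`1 − Ho/He` where `He > 0`.

The Hardy–Weinberg test is the conditional exact test given allele counts,
ordering genotype configurations by their conditional probability. The full
configuration space is enumerated when it is small; the default bound is
2×10^5 configurations, chosen so that the enumeration stays interactive in
pure R, with a cheap combinatorial overcount used to skip hopeless cases.
Beyond the bound a Monte-Carlo version shuffles gene copies and uses the
add-one rule `p = (b+1)/(m+1)`, which never reports `p = 0`.

Null-allele screening reports two heterozygote-deficit estimators —
Chakraborty's `(He−Ho)/(He+Ho)` and Brookfield's first estimator
`(He−Ho)/(1+He)` — plus a one-sided homozygote-excess test built on the same
conditional machinery (statistic: number of homozygotes). Flags in
`locus_summary()` are raised after Holm (sequential Bonferroni) adjustment
across loci, the same multiple-testing rule exposed as
`sequential_bonferroni()`. The homozygote-excess decision is per locus, not
per allele-size class; with a dozen-to-hundred individuals the per-class
refinement adds nothing but noise.

Linkage disequilibrium between two loci is tested with a genotypic
log-likelihood-ratio statistic on the two-locus contingency table, with the
null obtained by permuting one locus' genotype column.

Duplicate-genotype screening compares all pairs at the loci typed in both;
pairs sharing fewer than `min_shared` typed loci (default 5) are reported as
incomparable rather than silently passed.

## Pairwise relatedness

The relatedness model is the standard Cotterman parameterisation: a dyad
shares 0, 1 or 2 alleles identical by descent at a locus with probabilities
`(k0, k1, k2)`, and `r = k1/2 + k2`. The single-locus likelihood of a
genotype pair is `k0·P0 + k1·P1 + k2·P2`, with `P0` the product of the HWE
genotype probabilities, `P2` the probability of the shared genotype, and
`P1` built from the transmission probability that one gene copy of the
first genotype, chosen uniformly, is completed by an independent draw from
the allele frequencies. The implementation is checked against a brute-force
enumeration over ordered gene copies and IBD configurations to 1e-12.

`ml_k_estimate()` maximises the multilocus log-likelihood over the
2-simplex restricted to the region attainable by non-inbred dyads
(`k1² ≥ 4·k0·k2`), exactly as the classical categorical ML classifiers do.
The optimiser is deterministic: a fixed lattice of step 0.02 (plus the four
category vertices), polished by Nelder–Mead. `classify_relationship()`
evaluates the four fixed hypotheses U = (1,0,0), HS = (0.5,0.5,0),
FS = (0.25,0.5,0.25), PO = (0,1,0) and picks the maximum, breaking exact
ties toward the less related category (U before HS before FS before PO) so
that first-order edge counts are conservative. Missing loci are dropped
pairwise. Genotyping error is deliberately ignored at this stage; the error
model enters only in parentage and sibship, where single-locus exclusions
would otherwise be fatal.

Two estimator properties matter for interpretation:

* for truly unrelated dyads the estimate is truncated at `r = 0`, so the
  *mean* estimate over many unrelated dyads sits slightly above zero
  (≈ 0.04 at 14 loci with 10 equifrequent alleles). This is a well-known
  boundary effect of ML relatedness, not a bug; tests assert the documented
  behaviour.
* roughly one in ten truly unrelated dyads has HS as its best category at
  this marker information. A network built from best categories alone
  therefore contains false first-order edges; the parametric-bootstrap
  significance test (`relationship_significance()`) is exposed for
  filtering, but its Monte-Carlo p-value floor of `1/(n_sim+1)` limits how
  far family-wise corrections can push specificity.

`relationship_significance()` simulates genotype pairs under the null
category at the observed typing pattern and compares log-likelihood-ratio
statistics (add-one rule).

## Genetic network and group tests

The network has one node per individual (isolated nodes are kept) and one
edge per dyad whose best category is PO, FS or HS, weighted by `r_hat`.
Only degree-based summaries are computed; layout is presentation, not
analysis, and exports (GraphML / edge CSV) carry no coordinates.

`group_relatedness_test()` compares mean within-group and between-group
relatedness with a label-permutation null (default 20,000 permutations, so
a two-sided add-one p-value can fall below 0.001). Sex differences are the
same test with sex as the label. Groups with fewer than two members cannot
contribute within-group dyads and are dropped from the within mean with a
warning.

## Parentage assignment

The candidate LOD is the log-ratio of the probability of the offspring
genotype given the candidate as one parent (the other drawn from the allele
frequencies) to its unconditional HWE probability, summed over shared typed
loci. The genotyping-error model replaces an observed genotype with an
independent HWE draw with probability `e` per individual per locus, giving
the per-locus ratio `(1−e)²·T/P(g) + 1−(1−e)²`; with `e = 0` a Mendelian
mismatch is a hard exclusion (`−Inf`).

Assignment confidence is calibrated by simulation (`delta_criticals()`):
offspring are simulated with the true parent present in the candidate pool
with probability `prop_parents_sampled`, and the critical value is the
smallest threshold on delta (best minus second-best LOD) at which the
required fraction (default 95%) of assignments made above it are correct.
An assignment additionally requires a positive LOD — the candidate must
explain the offspring better than an arbitrary individual — which is what
keeps the false-assignment rate for offspring with no sampled parent around
1% rather than the ≈5% implied by the delta rule alone.

## Sibship reconstruction

`sibship_reconstruct()` searches over configurations that give every
offspring a mother reference and a father reference, each either a sampled
candidate or a latent (reconstructed) parent. Polygamy is allowed for both
sexes, so maternal and paternal families intersect freely and half-sib
structure arises naturally.

The configuration likelihood is computed exactly, per locus, on the factor
graph whose variables are latent parent genotypes:

* each latent parent's genotype domain is reduced to the alleles observed
  in its own offspring plus one pooled "any other allele" class. The
  pooling is exact because alleles a parent never needs to transmit to a
  scored offspring are likelihood-equivalent.
* a sampled parent typed at every locus is an observed variable; it
  d-separates the families it heads, which keeps components small.
* within a component, latent parents are summed out by message passing on
  the couple graph (leaf peeling); components with mating cycles fall back
  to generic variable elimination. Both paths agree to numerical precision
  and are tested against each other.
* the observation-error model applies to offspring genotypes (probability
  `e` of replacement by an HWE draw); sampled-parent genotypes are taken as
  observed.
* the prior probability that an offspring's true parent is among the
  sampled candidates (defaults 0.25 for mothers, 0.5 for fathers) enters
  once per offspring. Attaching it per offspring rather than per family
  keeps family merges and splits decided by the genotype likelihood alone;
  a per-family term would subsidise merging latent families.

The maximiser is simulated annealing with geometric cooling (default chain
length `8·n²` moves for `n` offspring, temperature 3 → 0.05) over three
move types: reassign one offspring's parent, merge a family into another
parent, split a family. Replicate runs (default 3, different derived seeds)
are compared by the fraction of offspring pairs on which their full-sib
partitions agree; the best-likelihood replicate is reported, and the best
configuration can never fall below the annealer's own initialisation
because the best state is tracked explicitly. An exhaustive search over all
pairs of maternal and paternal set partitions (`sibship_exhaustive()`)
serves as an exact oracle for up to ~7 offspring; the routine test uses 5
offspring (2,704 configurations), where the annealer reproduces the oracle
likelihood exactly.

Latent parent genotypes are reconstructed per locus as exact marginal
posteriors given the family's offspring and any sampled co-parents, with
ties within a relative tolerance reported as ambiguity sets
(`reconstruct_parent_genotypes()`). Breeder counts
(`count_breeders()`) sum distinct sampled parents with assigned offspring
and distinct latent parents; `litter_table()` groups offspring by mother
reference and cohort year and derives the polyandry fraction among
multi-young litters, per-father litter counts, and repeat-breeding
summaries, with unknown-cohort offspring listed separately.

A capability limit worth stating plainly: with ~14 microsatellites, the
maximum-likelihood configuration tends to merge latent half-sib families
that are truly distinct — on the bundled study-shaped fixture the merged
configuration genuinely has higher likelihood than the true pedigree, so
the reconstructed breeder total comes out around 33–34 where 41 parents
were planted. More loci, not more search, is the only cure; the tests
document this rather than hide it.

## Internal relatedness and the inbreeding null

Internal relatedness is `IR = (2H − Σf) / (2N − Σf)`, where `H` counts
homozygous typed loci, `N` the typed polymorphic loci used, and `Σf` sums
the population frequencies of the `2N` carried gene copies. It is −1 ≤ IR ≤ 1,
equals 1 exactly for a fully homozygous multilocus genotype, and its mean
over simulated offspring tracks the pedigree inbreeding coefficient F
(within ±0.02 at 20 loci × 10 equifrequent alleles in the test suite).
Note that an IR of 0.25 corresponds to offspring of matings between
first-degree relatives (parental relatedness r = 0.5, offspring F = 0.25);
offspring of half-sibling matings expect F = 0.125. The implementation
keeps the standard definition and does not rescale.

The random-mating null (`ir_random_mating_null()`) draws mating pairs
uniformly with replacement from the supplied males and females, produces
one Mendelian offspring per pair, and compares the observed mean IR with
the distribution of simulated means (default 1,000 iterations; one-sided
toward elevated IR, add-one rule; two-sided by flag). Loci untyped in
either parent are skipped per offspring with `N` adjusted. The gene pool
for frequencies defaults to all genotyped individuals and can be restricted
via the `ids` argument of `allele_frequencies()`.

`ir_locus_subset()` recomputes IR on loci with at least `min_alleles`
alleles (default 5) as a robustness check against low-diversity bias, and
`ir_covariate_summary()` provides the plain least-squares regression of IR
on body length and one-way ANOVAs across maturity stages and cohorts.

## The pedigree simulator

`pedigree_spec()` fixes the study conditions the generator emulates: 16
loci with 2–15 alleles (uneven, gamma-weighted frequencies by default), a
closed adult pool, four breeding seasons, biennial females (with optional
exceptions), litters of 1–13 pups dominated by singletons, 1–3 sires per
litter with every sire fathering at least one pup, male mating weights
drawn from a gamma distribution whose shape parameter concentrates
paternity (default 0.5, giving the strong skew reported for such
populations), four nursery sites with 0.85 female site fidelity, a 1%
genotyping error rate, optional null alleles at designated loci, and 2%
missing data. Null alleles are real alleles in the pedigree (code 999):
heterozygotes carrying one appear homozygous for the visible allele and
null homozygotes drop out as missing — which is exactly the signal the
QC stage is supposed to find.

`make_study_fixture()` produces a deterministic study-shaped dataset: 33
sampled adults (13 males, 20 females, four of them from an outgroup site
that never breeds), 52 sampled juveniles in 29 litters over the 2006–2009
cohorts, exactly 41 true breeders of whom 12 are sampled (4 mothers, 8
fathers), 9 multi-pup litters of which 7 are polyandrous, 10 fathers with
more than one litter, and null alleles (frequency 0.2) planted at loci
`LS15` and `Cli107`. The litter plan is fixed by design; only genotypes,
sites and sampling noise depend on the seed, and identical seeds reproduce
the output files byte for byte.

What the simulator does not model: population structure in the founder
pool, age- or size-dependent fecundity, mortality, allele-size mutation or
stutter artefacts, and spatial movement. Passing the end-to-end tests
therefore shows the pipeline recovers truth under its own generative
assumptions — clean HWE founders and independent loci — not that it is
robust to every field complication.

## Problem sizes and runtimes

The routine test suite uses 500 dyads per relatedness category, 500
simulated offspring for assignment accuracy, a 40-offspring/10-family
sibship problem, 200 replicate datasets per calibration check, and the
85-individual fixture; everything runs on one core in a few minutes. The
annealing chain length and replicate count are arguments, so larger
problems can buy accuracy with time.
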