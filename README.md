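# kinnet

Kinship networks, parentage and inbreeding for small microsatellite-typed
wild populations.

Small, closed animal populations — an island shark population of a few
dozen adults is the motivating case — pose a connected set of questions:
which markers are trustworthy, who is related to whom, how many animals
actually breed, do females mate with several males, and is the population
inbreeding despite its size? `kinnet` implements that full analysis chain
on codominant microsatellite genotypes:

* **Marker QC** — allele frequencies, observed and unbiased expected
  heterozygosity (`He = 2n/(2n−1)(1−Σp²)`), conditional exact
  Hardy–Weinberg tests (enumeration or Monte Carlo), genotypic
  linkage-disequilibrium permutation tests, null-allele diagnostics
  (Chakraborty `(He−Ho)/(He+Ho)` and Brookfield-1 `(He−Ho)/(1+He)`
  estimators with a homozygote-excess test), Holm sequential-Bonferroni
  correction, and duplicate-genotype screening.
* **Pairwise relatedness** — maximum-likelihood estimation of the
  Cotterman coefficients `(k0, k1, k2)` (probabilities of sharing 0/1/2
  alleles identical by descent; `r = k1/2 + k2`) and classification of each
  dyad as unrelated (U), half-sib (HS), full-sib (FS) or parent–offspring
  (PO), with a parametric-bootstrap significance test.
* **Genetic network** — a graph whose edges are first-order (PO/FS/HS)
  dyads weighted by `r`, degree summaries, and permutation tests of
  within- versus between-group relatedness.
* **Parentage and sibship** — CERVUS-style LOD assignment with simulated
  delta thresholds at strict 95% confidence, followed by COLONY-style
  full-likelihood sibship reconstruction by simulated annealing with exact
  latent-parent genotype integration, parental-genotype reconstruction,
  breeder counting and litter/polyandry tabulation.
* **Inbreeding** — internal relatedness `IR = (2H − Σf)/(2N − Σf)` per
  individual, a Monte-Carlo random-mating null for the mean IR of a cohort,
  a high-diversity locus-subset robustness check, and IR-versus-covariate
  summaries.
* **Simulator** — a ground-truthed pedigree and genotype generator
  (biennial females, polyandrous litters of 1–13 pups, skewed male success,
  nursery fidelity, genotyping error, null alleles, missing data) so every
  stage is testable against known truth.

## Worked example

Generate the bundled study-shaped dataset (33 sampled adults, 52 sampled
juveniles, 16 loci, two planted null-allele loci, 41 true breeders), run
QC, drop the bad markers, and reconstruct parentage:

```r
library(kinnet)

fx <- make_study_fixture(seed = 1)
fx$table
#> genotype_table: 85 individuals x 16 loci; 1338 typed calls, 22 missing

qc <- locus_summary(fx$table, n_mc = 4000, seed = 21)
qc$locus[qc$null_allele_suspect]
#> [1] "LS15"   "Cli107"

tab <- filter_loci(fx$table, c("LS15", "Cli107"))
af  <- allele_frequencies(tab)

juv     <- fx$meta$id[!is.na(fx$meta$cohort_year)]
mothers <- fx$meta$id[fx$meta$sex == "F" & is.na(fx$meta$cohort_year)]
fathers <- fx$meta$id[fx$meta$sex == "M" & is.na(fx$meta$cohort_year)]

cm  <- delta_criticals(af, length(mothers), 0.25, n_sim = 5000, seed = 22)
cf  <- delta_criticals(af, length(fathers), 0.50, n_sim = 5000, seed = 23)
asn <- assign_parents(tab, juv, mothers, fathers, af, 0.01, cm, cf)

known <- subset(data.frame(offspring_id = juv, mother_id = asn$mother_id,
                           father_id = asn$father_id),
                !is.na(mother_id) | !is.na(father_id))
sol <- sibship_reconstruct(tab, juv, af,
                           candidate_mothers = mothers,
                           candidate_fathers = fathers,
                           known = known, n_replicates = 3, seed = 24)
sol
#> sibship_solution: 52 offspring, 16 maternal / 17 paternal families, loglik -1374.65
#>   replicate pair agreement: 1.000

count_breeders(asn, sol)
#> breeders: 4 sampled + 12 reconstructed mothers; 8 sampled + 9 reconstructed fathers; total 33
```

The fixture plants 41 breeders; the reconstructed total of ~33 illustrates
the real information limit of 14 microsatellites for separating half-sib
families (the merged configuration has genuinely higher likelihood than the
truth — see the methods vignette). The full-sib partition itself is
recovered essentially perfectly, and the replicate runs agree.

Inbreeding assessment against a random-mating null:

```r
ir  <- ir_vector(tab, af, ids = juv)
res <- ir_random_mating_null(tab, males = fathers, females = mothers,
                             observed_ids = juv, freqs = af,
                             n_iter = 1000, seed = 31)
res
#> ir_result: observed mean IR = -0.0231 (95% CI -0.0580..0.0119), null mean = -0.0089, p = 0.7612 (1000 iterations)
```

A first-order genetic network with group comparisons:

```r
rm <- relatedness_matrix(tab, af)
g  <- build_network(rm$dyads, fx$meta)
degree_distribution(g)$mean
first_order_fraction(rm$dyads)
group_relatedness_test(rm$r, setNames(fx$meta$group, fx$meta$id),
                       n_perm = 20000, seed = 41)
```

A thin command-line wrapper over the same functions is provided in
`inst/cli/kinnet.R` (`qc`, `simulate`, `relate`, `inbreeding` subcommands).

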