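test_that("founder heterozygosity follows the closed form for the frequency profile", {
  spec <- pedigree_spec(n_loci = 6, alleles_per_locus = 10,
                        freq_profile = "equifrequent",
                        n_founder_males = 200, n_founder_females = 200)
  fnd <- simulate_founders(spec, seed = 63)
  ho <- mean(fnd$table$a1 != fnd$table$a2)
  expect_lt(abs(ho - 0.9), 0.02)                     # 1 - 1/k
  spec2 <- pedigree_spec(n_loci = 6, alleles_per_locus = 2,
                         freq_profile = "equifrequent",
                         n_founder_males = 200, n_founder_females = 200)
  fnd2 <- simulate_founders(spec2, seed = 64)
  expect_lt(abs(mean(fnd2$table$a1 != fnd2$table$a2) - 0.5), 0.03)
  # seed determinism
  again <- simulate_founders(spec, seed = 63)
  expect_identical(fnd$table$a1, again$table$a1)
})

test_that("gene dropping conserves parental alleles and respects Mendelian ratios", {
  spec <- pedigree_spec(n_loci = 1, alleles_per_locus = 2,
                        freq_profile = "equifrequent",
                        n_founder_males = 1, n_founder_females = 1)
  tab <- genotype_table(c("M01", "F01"), "L", a1 = matrix(c(1L, 1L)), a2 = matrix(c(2L, 2L)))
  set.seed(65)
  counts <- c(`11` = 0, `12` = 0, `22` = 0)
  for (i in 1:10000) {
    g <- kinnet:::gene_drop(tab, "F01", "M01")
    counts[paste0(g$a1, g$a2)] <- counts[paste0(g$a1, g$a2)] + 1
  }
  chi <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 1e-4)
})

test_that("pedigree simulation honours cycle and sire-count settings", {
  spec <- pedigree_spec(n_loci = 4, alleles_per_locus = 6, freq_profile = "equifrequent",
                        n_founder_males = 10, n_founder_females = 10,
                        n_breeding_years = 4, female_cycle = "biennial",
                        female_breed_prob = 1,
                        sires_per_litter_probs = c(1, 0, 0))
  fnd <- simulate_founders(spec, seed = 67)
  truth <- simulate_pedigree(spec, fnd, seed = 68)
  ped <- truth$pedigree
  # strict biennial: no female breeds in consecutive years
  for (mo in unique(ped$mother)) {
    yrs <- sort(unique(ped$cohort_year[ped$mother == mo]))
    if (length(yrs) > 1) expect_gte(min(diff(yrs)), 2)
  }
  # single sire per litter: polyandry fraction 0
  lit <- paste(ped$mother, ped$cohort_year)
  sires_per <- tapply(ped$father, lit, function(x) length(unique(x)))
  expect_true(all(sires_per == 1))
  # gene dropping conserves alleles (pre-error genotypes)
  for (i in seq_len(min(nrow(ped), 30))) {
    kid <- ped$id[i]
    im <- match(ped$mother[i], truth$genotypes$ids)
    ip <- match(ped$father[i], truth$genotypes$ids)
    ik <- match(kid, truth$genotypes$ids)
    for (l in seq_along(truth$genotypes$loci)) {
      par_alleles_m <- c(truth$genotypes$a1[im, l], truth$genotypes$a2[im, l])
      par_alleles_p <- c(truth$genotypes$a1[ip, l], truth$genotypes$a2[ip, l])
      kid_alleles <- c(truth$genotypes$a1[ik, l], truth$genotypes$a2[ik, l])
      expect_true(any(kid_alleles[1] %in% par_alleles_m | kid_alleles[1] %in% par_alleles_p))
      expect_true(any(kid_alleles[2] %in% par_alleles_m | kid_alleles[2] %in% par_alleles_p))
    }
  }
})

test_that("multi-sire litters are polyandrous by construction", {
  spec <- pedigree_spec(n_loci = 2, alleles_per_locus = 4, freq_profile = "equifrequent",
                        n_founder_males = 10, n_founder_females = 10,
                        n_breeding_years = 2, female_breed_prob = 1,
                        litter_size_probs = c(0, 0, 1, rep(0, 10)),   # always 3 pups
                        sires_per_litter_probs = c(0, 1, 0))          # always 2 sires
  fnd <- simulate_founders(spec, seed = 69)
  truth <- simulate_pedigree(spec, fnd, seed = 70)
  ped <- truth$pedigree
  lit <- paste(ped$mother, ped$cohort_year)
  sires_per <- tapply(ped$father, lit, function(x) length(unique(x)))
  expect_true(all(sires_per == 2))
})

test_that("the skew parameter concentrates paternity", {
  top_share <- function(skew, seed) {
    spec <- pedigree_spec(n_loci = 2, alleles_per_locus = 4, freq_profile = "equifrequent",
                          n_founder_males = 12, n_founder_females = 30,
                          n_breeding_years = 3, female_breed_prob = 1,
                          litter_size_probs = c(0, 0, 1, rep(0, 10)),
                          male_skew = skew)
    fnd <- simulate_founders(spec, seed = seed)
    truth <- simulate_pedigree(spec, fnd, seed = seed + 1)
    max(table(truth$pedigree$father)) / nrow(truth$pedigree)
  }
  skewed <- mean(vapply(1:5, function(s) top_share(0.1, 100 + s), 0))
  even <- mean(vapply(1:5, function(s) top_share(50, 200 + s), 0))
  expect_gt(skewed, even)
})

test_that("the observation model is the identity when error, nulls and missingness are off", {
  spec <- pedigree_spec(n_loci = 5, alleles_per_locus = 6, freq_profile = "equifrequent",
                        n_founder_males = 6, n_founder_females = 6,
                        error_rate = 0, missing_rate = 0,
                        adult_sampling_fraction = 1, juvenile_sampling_fraction = 1)
  fnd <- simulate_founders(spec, seed = 71)
  truth <- simulate_pedigree(spec, fnd, seed = 72)
  obs <- apply_observation_model(truth, spec, seed = 73)
  keep <- match(obs$table$ids, truth$genotypes$ids)
  expect_identical(unname(obs$table$a1), unname(truth$genotypes$a1[keep, ]))
  expect_identical(unname(obs$table$a2), unname(truth$genotypes$a2[keep, ]))
  expect_true(all(obs$meta$stage == stage_from_length(obs$meta$total_length_cm)))
})

test_that("planted null alleles produce a homozygote-excess signal downstream", {
  spec <- pedigree_spec(n_loci = 4, alleles_per_locus = 8, freq_profile = "equifrequent",
                        n_founder_males = 150, n_founder_females = 150,
                        error_rate = 0, missing_rate = 0,
                        null_allele_freq = c(Loc01 = 0.25))
  fnd <- simulate_founders(spec, seed = 75)
  truth <- simulate_pedigree(spec, fnd, seed = 76)
  obs <- apply_observation_model(truth, spec, seed = 77)
  lc <- kinnet:::locus_calls(obs$table, "Loc01")
  chk <- null_allele_check(lc$a1, lc$a2, n_mc = 1000, seed = 1)
  expect_true(chk$homozygote_excess_flag)
  expect_gt(chk$estimate_brookfield1, 0.1)
  lc2 <- kinnet:::locus_calls(obs$table, "Loc02")
  chk2 <- null_allele_check(lc2$a1, lc2$a2, n_mc = 1000, seed = 2)
  expect_false(chk2$homozygote_excess_flag)
})

test_that("the study fixture is deterministic and matches the planted design", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  fx1 <- make_study_fixture(seed = 4, dir = d1)
  fx2 <- make_study_fixture(seed = 4, dir = d2)
  expect_identical(readLines(file.path(d1, "genotypes.gen")),
                   readLines(file.path(d2, "genotypes.gen")))
  expect_identical(readLines(file.path(d1, "meta.csv")),
                   readLines(file.path(d2, "meta.csv")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  # planted shape
  expect_equal(sum(is.na(fx1$meta$cohort_year)), 33L)      # sampled adults
  expect_equal(sum(!is.na(fx1$meta$cohort_year)), 52L)     # sampled juveniles
  expect_equal(fx1$truth$n_breeders, 41L)
  expect_equal(length(fx1$truth$sampled_breeders$mothers), 4L)
  expect_equal(length(fx1$truth$sampled_breeders$fathers), 8L)
  expect_equal(length(fx1$table$loci), 16L)
  expect_setequal(fx1$truth$null_loci, c("LS15", "Cli107"))
  lits <- fx1$truth$litters
  expect_equal(nrow(lits), 29L)
  expect_equal(sum(lits$size), 52L)
  multi <- lits[lits$size >= 2, ]
  expect_equal(nrow(multi), 9L)
  expect_equal(sum(multi$n_sires >= 2), 7L)
  # a genotype file read back parses to the same table
  back <- read_genotypes(file.path(d1, "genotypes.gen"), "genepop")
  expect_identical(unname(back$a1), unname(fx1$table$a1))
})
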