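test_that("allele frequencies match hand counts and sum to one", {
  tab <- genotype_table(c("a", "b", "c"), "L",
                        a1 = matrix(c(1L, 1L, 2L)), a2 = matrix(c(1L, 2L, 2L)))
  af <- allele_frequencies(tab)
  expect_equal(unname(af$L$freq), c(0.5, 0.5))
  expect_equal(af$L$n_copies, 6L)
  one <- genotype_table("x", "L", a1 = matrix(1L), a2 = matrix(1L))
  expect_equal(unname(allele_frequencies(one)$L$freq), 1.0)
  het <- genotype_table("x", "L", a1 = matrix(1L), a2 = matrix(2L))
  expect_equal(unname(allele_frequencies(het)$L$freq), c(0.5, 0.5))
  # zero-typed locus is dropped with a warning
  tab2 <- genotype_table("x", c("L1", "L2"),
                         a1 = matrix(c(1L, NA), 1, 2), a2 = matrix(c(1L, NA), 1, 2))
  expect_warning(af2 <- allele_frequencies(tab2), "zero typed")
  expect_named(af2, "L1")
})

test_that("locus summary reproduces hand-computed Ho, He and Fis", {
  tab <- genotype_table(c("a", "b", "c"), "L",
                        a1 = matrix(c(1L, 1L, 2L)), a2 = matrix(c(1L, 2L, 2L)))
  s <- locus_summary(tab, n_mc = 200, seed = 1)
  expect_equal(s$Ho, 1 / 3)
  expect_equal(s$He, 0.6)                 # unbiased: (6/5) * 0.5
  expect_equal(s$Fis, 1 - (1 / 3) / 0.6)
  allhet <- genotype_table(letters[1:4], "L",
                           a1 = matrix(rep(1L, 4)), a2 = matrix(rep(2L, 4)))
  expect_equal(locus_summary(allhet, n_mc = 200, seed = 1)$Ho, 1.0)
  mono <- genotype_table(letters[1:3], "L", a1 = matrix(rep(1L, 3)),
                         a2 = matrix(rep(1L, 3)))
  sm <- locus_summary(mono, n_mc = 200, seed = 1)
  expect_equal(sm$He, 0)
  expect_true(is.na(sm$Fis))
  expect_equal(sm$hwe_p, 1.0)
})

test_that("many equifrequent alleles give He near 1 - 1/k", {
  set.seed(4)
  fr <- equifreq_table(1, 15)
  tab <- hwe_table(sprintf("i%03d", 1:400), fr)
  s <- locus_summary(tab, n_mc = 200, seed = 2)
  expect_equal(s$k, 15)
  expect_lt(abs(s$He - 14 / 15), 0.02)
})

test_that("HWE exact test handles degenerate margins and extreme excess", {
  # single heterozygote: only one configuration exists
  expect_equal(hwe_exact_test(1L, 2L), 1.0)
  # monomorphic locus
  expect_equal(hwe_exact_test(rep(1L, 5), rep(1L, 5)), 1.0)
  # 100 individuals all heterozygous: extreme heterozygote excess
  p <- hwe_exact_test(rep(1L, 100), rep(2L, 100), n_mc = 5000, seed = 1)
  expect_lt(p, 0.001)
})

test_that("Monte-Carlo HWE p agrees with complete enumeration within MC error", {
  set.seed(8)
  for (k in 2:3) {
    fr <- equifreq_table(1, k)
    tab <- hwe_table(sprintf("i%02d", 1:10), fr)
    a1 <- tab$a1[, 1]; a2 <- tab$a2[, 1]
    p_enum <- hwe_exact_test(a1, a2, enum_bound = 2e5)
    p_mc <- hwe_exact_test(a1, a2, n_mc = 20000, seed = 3, enum_bound = 0)
    se <- sqrt(p_enum * (1 - p_enum) / 20000)
    expect_lt(abs(p_mc - p_enum), 4 * se + 1e-4)
  }
})

test_that("null-allele estimators follow their closed forms", {
  # Ho == He gives 0 for both estimators
  set.seed(2)
  fr <- equifreq_table(1, 4)
  tab <- hwe_table(sprintf("i%02d", 1:40), fr)
  chk <- null_allele_check(tab$a1[, 1], tab$a2[, 1], n_mc = 500, seed = 1)
  expect_equal(chk$estimate_chakraborty, (chk$He - chk$Ho) / (chk$He + chk$Ho))
  expect_equal(chk$estimate_brookfield1, (chk$He - chk$Ho) / (1 + chk$He))
  # paper-range arithmetic: Ho = 0.365, He = 0.871
  expect_equal((0.871 - 0.365) / (0.871 + 0.365), 0.409, tolerance = 1e-3)
  expect_equal((0.871 - 0.365) / (1 + 0.871), 0.270, tolerance = 1e-2)
  # monomorphic: estimators undefined, no flag
  mono <- null_allele_check(rep(1L, 10), rep(1L, 10))
  expect_true(is.na(mono$estimate_chakraborty))
  expect_false(mono$homozygote_excess_flag)
})

test_that("Brookfield-1 recovers a planted null-allele frequency", {
  set.seed(11)
  k <- 8; null_f <- 0.2
  f <- c(rep((1 - null_f) / k, k), null_f)
  codes <- c(100 + seq_len(k), 999L)
  n <- 500
  a1 <- sample(codes, n, TRUE, f); a2 <- sample(codes, n, TRUE, f)
  # null-allele masking: het with null looks homozygous, null/null drops out
  vis <- !(a1 == 999L & a2 == 999L)
  a1v <- ifelse(a1 == 999L, a2, a1)[vis]
  a2v <- ifelse(a2 == 999L, a1, a2)[vis]
  chk <- null_allele_check(pmin(a1v, a2v), pmax(a1v, a2v), n_mc = 500, seed = 5)
  expect_lt(abs(chk$estimate_brookfield1 - null_f), 0.05)
  expect_true(chk$homozygote_excess_flag)
})

test_that("linkage-disequilibrium test detects duplicated loci and respects monomorphism", {
  set.seed(3)
  fr <- equifreq_table(1, 5)
  tab1 <- hwe_table(sprintf("i%02d", 1:20), fr)
  dup <- genotype_table(tab1$ids, c("A", "B"),
                        cbind(tab1$a1, tab1$a1), cbind(tab1$a2, tab1$a2))
  expect_lte(ld_test(dup, "A", "B", n_perm = 400, seed = 1), 0.01)
  mono <- genotype_table(tab1$ids, c("A", "B"),
                         cbind(tab1$a1, rep(1L, 20)), cbind(tab1$a2, rep(1L, 20)))
  expect_equal(ld_test(mono, "A", "B", n_perm = 100, seed = 1), 1.0)
})

test_that("Holm correction matches the hand example and dominates plain Bonferroni", {
  one <- sequential_bonferroni(0.04, alpha = 0.05)
  expect_true(one$reject)
  res <- sequential_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(res$p_adjusted, c(0.03, 0.06, 0.06))
  expect_equal(res$reject, c(TRUE, FALSE, FALSE))
  expect_false(any(sequential_bonferroni(rep(1, 5))$reject))
  expect_error(sequential_bonferroni(c(0.5, 1.2)), "0, 1")
  # Holm rejections are a superset of Bonferroni rejections
  set.seed(9)
  for (i in 1:20) {
    p <- runif(8)^2
    holm <- sequential_bonferroni(p)$reject
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(holm[bonf]))
  }
})

test_that("duplicate-genotype screening finds planted duplicates and reports incomparable pairs", {
  set.seed(6)
  fr <- equifreq_table(14, 6)
  tab <- hwe_table(sprintf("i%02d", 1:20), fr)
  # plant an exact duplicate of individual 1
  dup <- genotype_table(c(tab$ids, "copy1"), tab$loci,
                        rbind(tab$a1, tab$a1[1, , drop = FALSE]),
                        rbind(tab$a2, tab$a2[1, , drop = FALSE]))
  res <- find_duplicate_genotypes(dup)
  expect_equal(nrow(res$matches), 1L)
  expect_setequal(c(res$matches$id_a, res$matches$id_b), c("i01", "copy1"))
  # no duplicates among many unrelated individuals at informative loci
  set.seed(7)
  fr2 <- equifreq_table(14, 5)
  big <- hwe_table(sprintf("u%02d", 1:85), fr2)
  expect_equal(nrow(find_duplicate_genotypes(big)$matches), 0L)
  # a pair sharing no typed loci is incomparable
  tiny <- genotype_table(c("a", "b"), c("L1", "L2"),
                         a1 = matrix(c(1L, NA, NA, 1L), 2, 2),
                         a2 = matrix(c(1L, NA, NA, 1L), 2, 2))
  res2 <- find_duplicate_genotypes(tiny, min_shared = 1)
  expect_equal(nrow(res2$incomparable), 1L)
})
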