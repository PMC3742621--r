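test_that("internal relatedness matches hand computations and bounds", {
  f2 <- structure(list(L1 = list(freq = c("1" = 0.5, "2" = 0.5), n_copies = NA),
                       L2 = list(freq = c("1" = 0.5, "2" = 0.5), n_copies = NA)),
                  class = "allele_freq_table")
  # one heterozygous locus at p = 0.5: the minimum, IR = -1
  het <- genotype_table("h", "L1", a1 = matrix(1L), a2 = matrix(2L))
  expect_equal(internal_relatedness(het, "h",
                                    structure(f2["L1"], class = "allele_freq_table")), -1)
  # fully homozygous: IR = 1 regardless of frequencies
  hom <- genotype_table("h", c("L1", "L2"), a1 = matrix(c(1L, 2L), 1), a2 = matrix(c(1L, 2L), 1))
  expect_equal(internal_relatedness(hom, "h", f2), 1)
  # mixed example: {1,1} and {1,2} -> (2 - 2) / (4 - 2) = 0
  mix <- genotype_table("h", c("L1", "L2"), a1 = matrix(c(1L, 1L), 1), a2 = matrix(c(1L, 2L), 1))
  expect_equal(internal_relatedness(mix, "h", f2), 0)
  # bounds over random genotypes
  set.seed(51)
  fr <- equifreq_table(10, 4)
  tab <- hwe_table(sprintf("i%02d", 1:50), fr)
  ir <- ir_vector(tab, fr)
  expect_true(all(ir >= -1 - 1e-12 & ir <= 1 + 1e-12))
  full_hom <- vapply(seq_len(50), function(i) all(tab$a1[i, ] == tab$a2[i, ]), TRUE)
  expect_equal(unname(ir == 1), full_hom)
})

test_that("mean IR tracks the pedigree inbreeding coefficient", {
  set.seed(53)
  L <- 20; k <- 10; n <- 3000
  fr <- equifreq_table(L, k)
  sim_f <- function(Fcoef) {
    a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
    for (l in seq_len(L)) {
      x <- sample.int(k, n, TRUE); y <- sample.int(k, n, TRUE)
      ibd <- runif(n) < Fcoef
      y[ibd] <- x[ibd]
      a1[, l] <- pmin(x, y); a2[, l] <- pmax(x, y)
    }
    mean(kinnet:::ir_matrix(a1, a2, fr, names(fr)))
  }
  expect_lt(abs(sim_f(0) - 0), 0.02)
  expect_lt(abs(sim_f(0.125) - 0.125), 0.02)
  expect_lt(abs(sim_f(0.25) - 0.25), 0.02)
})

test_that("the random-mating null is deterministic given a seed and sane when degenerate", {
  set.seed(55)
  fr <- equifreq_table(10, 6)
  tab <- hwe_table(c(sprintf("m%d", 1:5), sprintf("f%d", 1:5), sprintf("o%d", 1:8)), fr)
  males <- sprintf("m%d", 1:5); females <- sprintf("f%d", 1:5)
  obs <- sprintf("o%d", 1:8)
  r1 <- ir_random_mating_null(tab, males, females, obs, fr, n_iter = 50, seed = 99)
  r2 <- ir_random_mating_null(tab, males, females, obs, fr, n_iter = 50, seed = 99)
  expect_identical(r1$null, r2$null)
  expect_gte(r1$p, 1 / 51)
  # n_iter = 1: add-one rule keeps p in {0.5, 1}
  r3 <- ir_random_mating_null(tab, males, females, obs, fr, n_iter = 1, seed = 1)
  expect_true(r3$p %in% c(0.5, 1))
  expect_error(ir_random_mating_null(tab, character(0), females, obs, fr), "at least one")
})

test_that("offspring of related parents are flagged against a random-mating null", {
  set.seed(57)
  fr <- equifreq_table(14, 10)
  hits <- replicate(10, {
    pool <- hwe_table(c(sprintf("m%02d", 1:13), sprintf("f%02d", 1:20)), fr)
    tab <- pool
    # inbred offspring: each from a father x his full-sister-equivalent mate
    # (mother's gametes drawn from the father's parents' genotypes)
    for (i in 1:30) {
      sire <- sprintf("m%02d", sample(13, 1))
      tab <- add_child(tab, sprintf("sib%02d", i), sire, sprintf("f%02d", sample(20, 1)))
      tab <- add_child(tab, sprintf("inb%02d", i), sire, sprintf("sib%02d", i))
    }
    res <- ir_random_mating_null(tab, sprintf("m%02d", 1:13), sprintf("f%02d", 1:20),
                                 sprintf("inb%02d", 1:30), fr, n_iter = 200, seed = i)
    res$p
  })
  expect_gte(mean(hits <= 0.05), 0.8)
})

test_that("locus-subset IR matches the full panel when nothing is excluded", {
  set.seed(59)
  fr <- equifreq_table(8, 6)      # every locus has 6 alleles
  tab <- hwe_table(sprintf("i%02d", 1:20), fr)
  sub <- ir_locus_subset(tab, fr, min_alleles = 5)
  expect_equal(sub$ir, ir_vector(tab, fr))
  expect_equal(length(sub$loci), 8L)
  # threshold 2 keeps all polymorphic loci
  expect_equal(length(ir_locus_subset(tab, fr, min_alleles = 2)$loci), 8L)
  expect_error(ir_locus_subset(tab, fr, min_alleles = 20), "no locus")
})

test_that("IR covariate summaries recover a planted slope and handle degenerate input", {
  set.seed(61)
  n <- 120
  len <- runif(n, 60, 310)
  ir <- -0.0005 * len + 0.078 + rnorm(n, 0, 0.05)
  names(ir) <- sprintf("i%03d", 1:n)
  meta <- data.frame(id = names(ir), sex = "F", total_length_cm = len,
                     stage = stage_from_length(len), group = "g", site = "s",
                     cohort_year = sample(2006:2009, n, TRUE),
                     stringsAsFactors = FALSE)
  out <- ir_covariate_summary(ir, meta)
  fit <- stats::lm(ir ~ len)
  ci <- stats::confint(fit)[2, ]
  expect_gte(-0.0005, ci[1]); expect_lte(-0.0005, ci[2])
  expect_equal(out$regression$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_false(is.na(out$stage_anova$p))
  expect_false(is.na(out$cohort_anova$p))
  # constant IR: slope 0; constant covariate: undefined
  flat <- stats::setNames(rep(0.1, n), names(ir))
  outf <- suppressWarnings(ir_covariate_summary(flat, meta))
  expect_equal(outf$regression$slope, 0, tolerance = 1e-12)
  meta$total_length_cm <- 100
  outc <- ir_covariate_summary(ir, meta)
  expect_true(is.na(outc$regression$slope))
})
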