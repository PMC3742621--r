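test_that("a lone offspring with latent parents scores its HWE probability", {
  set.seed(41)
  fr <- equifreq_table(8, 6)
  tab <- hwe_table("solo", fr)
  ctx <- kinnet:::sibship_context(tab, "solo", fr, 0.01, 0.25, 0.5)
  ll <- kinnet:::sibship_loglik(ctx, "#1", "*1")
  manual <- sum(vapply(names(fr), function(l) {
    f <- fr[[l]]$freq
    a <- tab$a1[1, l]; b <- tab$a2[1, l]
    pa <- as.numeric(f[as.character(a)]); pb <- as.numeric(f[as.character(b)])
    log(if (a == b) pa^2 else 2 * pa * pb)
  }, 0)) + log(1 - 0.25) + log(1 - 0.5)
  expect_equal(unname(ll), manual, tolerance = 1e-10)
  # degenerate single-offspring reconstruction does not crash
  sol <- sibship_reconstruct(tab, "solo", fr, n_replicates = 1, seed = 1, n_moves = 10)
  expect_equal(nrow(sol$assignment), 1L)
})

test_that("full-sib families are recovered and the annealer matches exhaustive search", {
  set.seed(43)
  fr <- equifreq_table(14, 10)
  pool <- hwe_table(c("m1", "m2", "d1", "d2"), fr)
  tab <- pool
  for (k in 1:3) tab <- add_child(tab, paste0("a", k), "m1", "d1")
  for (k in 1:2) tab <- add_child(tab, paste0("b", k), "m2", "d2")
  kids <- c("a1", "a2", "a3", "b1", "b2")
  sol <- sibship_reconstruct(tab, kids, fr, n_replicates = 2, seed = 5, n_moves = 1500)
  key <- paste(sol$assignment$mother_ref, sol$assignment$father_ref)
  expect_equal(length(unique(key[1:3])), 1L)
  expect_equal(length(unique(key[4:5])), 1L)
  expect_false(key[1] == key[4])
  ex <- sibship_exhaustive(tab, kids, fr)
  expect_equal(sol$loglik, ex$loglik, tolerance = 1e-8)
  # annealing never ends below its own initialisation (all singletons)
  ctx <- kinnet:::sibship_context(tab, kids, fr, 0.01, 0.25, 0.5)
  init_ll <- kinnet:::sibship_loglik(ctx, paste0("#", 1:5), paste0("*", 1:5))
  expect_gte(sol$loglik, init_ll)
})

test_that("peeling likelihood agrees with generic variable elimination on shared-parent components", {
  set.seed(44)
  fr <- equifreq_table(10, 8)
  pool <- hwe_table(c("m1", "m2", "d1"), fr)
  tab <- pool
  # one father shared by two mothers: a star component
  tab <- add_child(tab, "x1", "m1", "d1")
  tab <- add_child(tab, "x2", "m1", "d1")
  tab <- add_child(tab, "y1", "m2", "d1")
  ctx <- kinnet:::sibship_context(tab, c("x1", "x2", "y1"), fr, 0.01, 0.25, 0.5)
  couples <- list(list(mo = "#1", fa = "*1", off = 1:2),
                  list(mo = "#2", fa = "*1", off = 3L))
  parents <- c("#1", "#2", "*1")
  peel <- kinnet:::component_peel_loglik(ctx, parents, couples)
  gen <- 0
  for (locus in ctx$loci) {
    fb <- kinnet:::component_locus_factors(ctx, parents, couples, locus)
    res <- kinnet:::eliminate_all(fb$factors, parents, fb$dim_of)
    gen <- gen + res$logscale
  }
  expect_equal(peel, gen, tolerance = 1e-10)
})

test_that("known assignments are enforced and contradictions rejected", {
  set.seed(45)
  fr <- equifreq_table(10, 8)
  pool <- hwe_table(c("momA", "dadA"), fr)
  tab <- pool
  tab <- add_child(tab, "k1", "momA", "dadA")
  tab <- add_child(tab, "k2", "momA", "dadA")
  known <- data.frame(offspring_id = "k1", mother_id = "momA", father_id = NA,
                      stringsAsFactors = FALSE)
  sol <- sibship_reconstruct(tab, c("k1", "k2"), fr,
                             candidate_mothers = "momA", candidate_fathers = "dadA",
                             known = known, n_replicates = 1, seed = 7, n_moves = 600)
  expect_equal(sol$assignment$mother_ref[sol$assignment$offspring_id == "k1"], "momA")
  bad <- data.frame(offspring_id = c("k1", "k1"), mother_id = c("momA", "momB"),
                    father_id = NA, stringsAsFactors = FALSE)
  expect_error(sibship_reconstruct(tab, c("k1", "k2"), fr, known = bad),
               "contradictory")
})

test_that("latent parent genotypes are reconstructed from family evidence", {
  # four offspring all {1,2}; known co-parent {1,1}; allele 2 must come from
  # the latent parent
  f <- stats::setNames(c(0.45, 0.45, 0.10), 1:3)
  fr <- structure(list(L1 = list(freq = f, n_copies = NA)), class = "allele_freq_table")
  ids <- c("coparent", paste0("k", 1:4))
  tab <- genotype_table(ids, "L1",
                        a1 = matrix(c(1L, rep(1L, 4))), a2 = matrix(c(1L, rep(2L, 4))))
  known <- data.frame(offspring_id = paste0("k", 1:4), mother_id = "coparent",
                      father_id = NA, stringsAsFactors = FALSE)
  sol <- sibship_reconstruct(tab, paste0("k", 1:4), fr, candidate_mothers = "coparent",
                             known = known, n_replicates = 1, seed = 9, n_moves = 800)
  rec <- reconstruct_parent_genotypes(sol, tab, fr)
  lat <- rec[kinnet:::is_latent_parent(rec$parent), ]
  expect_true(all(2L %in% c(lat$allele1, lat$allele2)))
  # a single-offspring family is maximally ambiguous: the top genotype holds
  # only a small share of the posterior mass
  tab1 <- genotype_table(c("k"), "L1", a1 = matrix(1L), a2 = matrix(2L))
  sol1 <- sibship_reconstruct(tab1, "k", fr, n_replicates = 1, seed = 2, n_moves = 10)
  rec1 <- reconstruct_parent_genotypes(sol1, tab1, fr)
  expect_true(all(rec1$ambiguous))
  expect_true(all(rec1$posterior_max < 0.6))
})

test_that("breeder counting sums sampled and reconstructed parents", {
  asn <- data.frame(offspring_id = c("o1", "o2"),
                    mother_id = c("F1", NA), lod_mother = 1, delta_mother = 1,
                    mother_confidence = c("strict95", "unassigned"),
                    father_id = c("M1", "M2"), lod_father = 1, delta_father = 1,
                    father_confidence = c("strict95", "strict95"),
                    stringsAsFactors = FALSE)
  sol <- list(assignment = data.frame(
    offspring_id = c("o1", "o2", "o3"),
    mother_ref = c("F1", "#1", "#2"),
    father_ref = c("M1", "M2", "*1"), stringsAsFactors = FALSE))
  bc <- count_breeders(asn, sol)
  expect_equal(bc$mothers_sampled, 1L)
  expect_equal(bc$fathers_sampled, 2L)
  expect_equal(bc$mothers_reconstructed, 2L)
  expect_equal(bc$fathers_reconstructed, 1L)
  expect_equal(bc$total, 6L)
  # no offspring: all cells zero
  empty <- list(assignment = data.frame(offspring_id = character(0),
                                        mother_ref = character(0),
                                        father_ref = character(0)))
  expect_equal(count_breeders(NULL, empty)$total, 0L)
})

test_that("litter tabulation reproduces the polyandry and sire summaries", {
  # 9 multi-young litters, 7 polyandrous, plus singletons
  asn <- list()
  mk <- function(off, mo, fa, yr) data.frame(offspring_id = off, mother_ref = mo,
                                             father_ref = fa, cohort_year = yr,
                                             stringsAsFactors = FALSE)
  rows <- list()
  oid <- 0L
  addlit <- function(mo, yr, sires) {
    for (s in sires) { oid <<- oid + 1L
      rows[[length(rows) + 1L]] <<- mk(sprintf("o%02d", oid), mo, s, yr) }
  }
  for (i in 1:7) addlit(paste0("#", i), 2006L, c("*1", "*2"))       # polyandrous
  addlit("#8", 2007L, c("*3", "*3"))                                 # 2 pups 1 sire
  addlit("#9", 2007L, c("*4", "*4"))
  addlit("#10", 2008L, "*5")                                         # singleton
  df <- do.call(rbind, rows)
  sol <- list(assignment = df[, c("offspring_id", "mother_ref", "father_ref")])
  meta <- data.frame(id = df$offspring_id, cohort_year = df$cohort_year,
                     site = "nursery", stringsAsFactors = FALSE)
  lt <- litter_table(sol, meta)
  expect_equal(lt$summary$n_multi_young, 9L)
  expect_equal(lt$summary$n_polyandrous, 7L)
  expect_equal(lt$summary$polyandry_fraction, 7 / 9, tolerance = 1e-12)
  # all-singleton case: polyandry undefined, no crash
  solo <- list(assignment = data.frame(offspring_id = c("a", "b"),
                                       mother_ref = c("#1", "#2"),
                                       father_ref = c("*1", "*2")))
  meta2 <- data.frame(id = c("a", "b"), cohort_year = c(2006L, NA), site = "n")
  lt2 <- litter_table(solo, meta2)
  expect_true(is.na(lt2$summary$polyandry_fraction))
  expect_equal(nrow(lt2$unknown_year), 1L)
})

test_that("breeder totals agree with the distinct parents of the litter table", {
  sol <- list(assignment = data.frame(
    offspring_id = sprintf("o%d", 1:6),
    mother_ref = c("F1", "F1", "#1", "#1", "#2", "#2"),
    father_ref = c("M1", "*1", "*1", "*2", "*2", "*2"), stringsAsFactors = FALSE))
  meta <- data.frame(id = sprintf("o%d", 1:6),
                     cohort_year = c(2006L, 2006L, 2007L, 2007L, 2008L, 2008L),
                     site = "n")
  bc <- count_breeders(NULL, sol)
  lt <- litter_table(sol, meta)
  parents_in_litters <- unique(c(lt$litters$mother_ref,
                                 unlist(strsplit(lt$litters$sires, ";"))))
  expect_equal(bc$total, length(parents_in_litters))
})

test_that("father summaries count multi-litter sires", {
  sol <- list(assignment = data.frame(
    offspring_id = sprintf("o%d", 1:4),
    mother_ref = c("#1", "#2", "#3", "#4"),
    father_ref = c("*1", "*1", "*2", "*3"), stringsAsFactors = FALSE))
  meta <- data.frame(id = sprintf("o%d", 1:4),
                     cohort_year = c(2006L, 2007L, 2006L, 2006L), site = "n")
  lt <- litter_table(sol, meta)
  expect_equal(unname(lt$summary$father_litter_counts["*1"]), 2L)
  expect_equal(lt$summary$fraction_fathers_multiple_litters, 1 / 3)
})
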