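## Marker-level quality control: allele frequencies, heterozygosities,
## Hardy-Weinberg and linkage-disequilibrium tests, null-allele diagnostics,
## multiple-testing correction and duplicate-genotype screening.

#' Allele frequencies per locus
#'
#' Frequencies are allele counts over typed gene copies; missing calls are
#' excluded from numerator and denominator. Loci with zero typed calls in the
#' chosen subset are dropped with a warning.
#'
#' @param table A [genotype_table()].
#' @param ids Optional subset of individual IDs (default: all).
#' @return An `allele_freq_table`: a named list with one element per locus,
#'   each a list with `freq` (named numeric vector summing to 1) and
#'   `n_copies` (typed gene copies).
#' @export
allele_frequencies <- function(table, ids = NULL) {
  if (!is.null(ids)) table <- subset_genotypes(table, ids = ids)
  out <- list()
  dropped <- character(0)
  for (l in table$loci) {
    a <- c(table$a1[, l], table$a2[, l])
    a <- a[!is.na(a)]
    if (length(a) == 0L) { dropped <- c(dropped, l); next }
    tab <- table(a)
    f <- as.numeric(tab) / length(a)
    names(f) <- names(tab)
    out[[l]] <- list(freq = f, n_copies = length(a))
  }
  if (length(dropped))
    warning("locus with zero typed calls excluded: ", paste(dropped, collapse = ", "))
  structure(out, class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(x), "loci;",
      paste0(range(vapply(x, function(e) length(e$freq), 1L)), collapse = "-"),
      "alleles per locus\n")
  invisible(x)
}

# Typed allele vectors for one locus.
locus_calls <- function(table, locus) {
  a1 <- table$a1[, locus]; a2 <- table$a2[, locus]
  ok <- !is.na(a1)
  list(a1 = a1[ok], a2 = a2[ok], ids = table$ids[ok])
}

## ------------------------------------------------- HWE exact machinery

# Enumerate all genotype-count configurations compatible with the allele
# counts `m` (copies per allele). Returns data.frame(logp, n_hom) or NULL if
# the configuration space exceeds `bound`.
hwe_enumerate <- function(m, bound = 2e5) {
  k <- length(m)
  n_ind <- sum(m) / 2
  # cheap overcount (multisets of genotypes, ignoring margins): skip the
  # recursion entirely when the space cannot be below the bound
  G <- k * (k + 1) / 2
  if (lchoose(n_ind + G - 1, G - 1) > log(bound) + log(50)) return(NULL)
  const <- lfactorial(n_ind) + sum(lfactorial(m)) - lfactorial(sum(m))
  env <- new.env()
  env$logp <- numeric(1024); env$hom <- integer(1024)
  env$count <- 0L; env$over <- FALSE
  rec <- function(i, j, rem, het, slf, hom) {
    if (env$over) return()
    if (i > k) {
      env$count <- env$count + 1L
      if (env$count > bound) { env$over <- TRUE; return() }
      if (env$count > length(env$logp)) {
        length(env$logp) <- 2L * length(env$logp)
        length(env$hom) <- length(env$logp)
      }
      env$logp[env$count] <- const + het * log(2) - slf
      env$hom[env$count] <- hom
      return()
    }
    ni <- rem[i]
    if (i == j) {
      if (j == k) {                       # single-allele tail: all copies homozygous
        if (ni %% 2L != 0L) return()
        cnt <- ni %/% 2L
        rem[i] <- 0L
        rec(i + 1L, i + 1L, rem, het, slf + lfactorial(cnt), hom + cnt)
      } else {
        for (cnt in 0:(ni %/% 2L)) {
          rem2 <- rem; rem2[i] <- ni - 2L * cnt
          rec(i, j + 1L, rem2, het, slf + lfactorial(cnt), hom + cnt)
        }
      }
    } else {
      if (j == k) {                       # forced: remaining copies of i pair with k
        cnt <- ni
        if (rem[j] < cnt) return()
        rem2 <- rem; rem2[i] <- 0L; rem2[j] <- rem[j] - cnt
        rec(i + 1L, i + 1L, rem2, het + cnt, slf + lfactorial(cnt), hom)
      } else {
        for (cnt in 0:min(ni, rem[j])) {
          rem2 <- rem; rem2[i] <- ni - cnt; rem2[j] <- rem[j] - cnt
          rec(i, j + 1L, rem2, het + cnt, slf + lfactorial(cnt), hom)
        }
      }
    }
  }
  rec(1L, 1L, as.integer(m), 0L, 0, 0L)
  if (env$over) return(NULL)
  data.frame(logp = env$logp[seq_len(env$count)],
             n_hom = env$hom[seq_len(env$count)])
}

# Conditional log-probability and homozygote count of an observed genotype
# configuration, plus the pieces the Monte-Carlo shuffler needs.
hwe_observed_stats <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  k <- length(alleles)
  key <- pmin(i1, i2) * (k + 1L) + pmax(i1, i2)
  cnt <- table(key)
  m <- tabulate(c(i1, i2), nbins = k)
  n_ind <- length(a1)
  const <- lfactorial(n_ind) + sum(lfactorial(m)) - lfactorial(2 * n_ind)
  het <- sum(i1 != i2)
  logp <- const + het * log(2) - sum(lfactorial(as.integer(cnt)))
  list(alleles = alleles, m = m, k = k, const = const,
       logp = logp, n_hom = sum(i1 == i2))
}

# One shuffled configuration's (logp, n_hom) given pooled copies.
hwe_mc_draws <- function(stats, n_mc) {
  copies <- rep(seq_len(stats$k), stats$m)
  n_ind <- length(copies) %/% 2L
  k <- stats$k
  logp <- numeric(n_mc); hom <- integer(n_mc)
  for (r in seq_len(n_mc)) {
    perm <- sample(copies)
    x <- perm[seq_len(n_ind)]; y <- perm[n_ind + seq_len(n_ind)]
    key <- pmin(x, y) * (k + 1L) + pmax(x, y)
    cnt <- tabulate(match(key, unique(key)))
    het <- sum(x != y)
    logp[r] <- stats$const + het * log(2) - sum(lfactorial(cnt))
    hom[r] <- n_ind - het
  }
  data.frame(logp = logp, n_hom = hom)
}

#' Exact test for Hardy-Weinberg proportions at one locus
#'
#' Conditional exact test given the allele counts, ordering configurations by
#' their conditional probability. The full configuration space is enumerated
#' when it contains at most `enum_bound` genotype tables; otherwise a
#' Monte-Carlo version is used with the add-one rule `p = (b+1)/(m+1)`.
#'
#' @param a1,a2 Integer vectors with the two alleles of each typed individual
#'   (no missing values), as returned for one locus of a genotype table.
#' @param n_mc Number of Monte-Carlo shuffles when enumeration is infeasible.
#' @param seed Optional seed for the Monte-Carlo branch.
#' @param enum_bound Largest configuration space enumerated completely.
#' @return The p-value. Monomorphic loci (or margins admitting a single
#'   configuration) give `p = 1`.
#' @export
hwe_exact_test <- function(a1, a2, n_mc = 1e5, seed = NULL, enum_bound = 2e5) {
  stopifnot(length(a1) == length(a2))
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) < 1L) stop_kinnet("no typed genotypes")
  if (length(unique(c(a1, a2))) < 2L) return(1.0)
  st <- hwe_observed_stats(a1, a2)
  tol <- 1e-9
  cfg <- hwe_enumerate(st$m, bound = enum_bound)
  if (!is.null(cfg)) {
    p <- sum(exp(cfg$logp)[cfg$logp <= st$logp + tol])
    return(min(p, 1.0))
  }
  sims <- with_seed(seed, hwe_mc_draws(st, n_mc))
  mc_pvalue(sum(sims$logp <= st$logp + tol), n_mc)
}

# One-sided homozygote-excess test (null-allele signal): same conditional
# machinery, statistic = number of homozygotes, large values extreme.
homozygote_excess_test <- function(a1, a2, n_mc = 5000, seed = NULL,
                                   enum_bound = 2e5) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(unique(c(a1, a2))) < 2L) return(1.0)
  st <- hwe_observed_stats(a1, a2)
  cfg <- hwe_enumerate(st$m, bound = enum_bound)
  if (!is.null(cfg)) {
    return(min(sum(exp(cfg$logp)[cfg$n_hom >= st$n_hom]), 1.0))
  }
  sims <- with_seed(seed, hwe_mc_draws(st, n_mc))
  mc_pvalue(sum(sims$n_hom >= st$n_hom), n_mc)
}

## -------------------------------------------------------- null alleles

#' Null-allele diagnostics for one locus
#'
#' Two frequency estimators based on the heterozygote deficit, plus a
#' one-sided exact/Monte-Carlo homozygote-excess test.
#' The Chakraborty estimator is `(He - Ho) / (He + Ho)` and the Brookfield-1
#' estimator `(He - Ho) / (1 + He)`.
#'
#' @param a1,a2 Allele vectors for the typed individuals at one locus.
#' @param alpha Flagging level for the homozygote-excess test.
#' @param n_mc,seed,enum_bound Passed to the homozygote-excess test.
#' @return List with `estimate_chakraborty`, `estimate_brookfield1`,
#'   `homozygote_excess_flag`, `p_value`, `Ho`, `He`. Estimators are `NA`
#'   when `He = 0`.
#' @export
null_allele_check <- function(a1, a2, alpha = 0.05, n_mc = 5000, seed = NULL,
                              enum_bound = 2e5) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0L) stop_kinnet("no typed genotypes")
  Ho <- mean(a1 != a2)
  f <- table(c(a1, a2)) / (2 * n)
  He <- unbiased_He(as.numeric(f), 2 * n)
  if (He <= 0) {
    return(list(estimate_chakraborty = NA_real_, estimate_brookfield1 = NA_real_,
                homozygote_excess_flag = FALSE, p_value = 1.0, Ho = Ho, He = He))
  }
  p <- homozygote_excess_test(a1, a2, n_mc = n_mc, seed = seed,
                              enum_bound = enum_bound)
  list(estimate_chakraborty = (He - Ho) / (He + Ho),
       estimate_brookfield1 = (He - Ho) / (1 + He),
       homozygote_excess_flag = (p < alpha) && (He > Ho),
       p_value = p, Ho = Ho, He = He)
}

# Small-sample corrected expected heterozygosity.
unbiased_He <- function(freqs, n_copies) {
  if (n_copies < 2) return(NA_real_)
  (n_copies / (n_copies - 1)) * (1 - sum(freqs^2))
}

## ------------------------------------------------------------ summaries

#' Per-locus marker summary
#'
#' Observed and unbiased expected heterozygosity, allele count, Fis,
#' Hardy-Weinberg exact p-value and null-allele diagnostics, with flags after
#' Holm (sequential Bonferroni) correction across loci.
#'
#' @param table A [genotype_table()].
#' @param alpha Level for the flags (applied to Holm-adjusted p-values).
#' @param n_mc Monte-Carlo replicates for the exact tests.
#' @param seed Seed for the Monte-Carlo branches.
#' @param enum_bound Complete-enumeration bound for the exact tests.
#' @return A data.frame with one row per locus: `locus`, `n_typed`, `k`,
#'   `Ho`, `He`, `Fis`, `hwe_p`, `null_chakraborty`, `null_brookfield1`,
#'   `null_p`, `hwe_deviation`, `null_allele_suspect`.
#' @export
locus_summary <- function(table, alpha = 0.05, n_mc = 5000, seed = NULL,
                          enum_bound = 2e5) {
  if (length(table$loci) == 0L) stop_kinnet("empty genotype table")
  rows <- lapply(seq_along(table$loci), function(li) {
    l <- table$loci[li]
    lc <- locus_calls(table, l)
    n <- length(lc$a1)
    k <- length(unique(c(lc$a1, lc$a2)))
    Ho <- if (n > 0) mean(lc$a1 != lc$a2) else NA_real_
    f <- table(c(lc$a1, lc$a2)) / (2 * n)
    He <- if (k >= 2) unbiased_He(as.numeric(f), 2 * n) else 0
    Fis <- if (!is.na(He) && He > 0) 1 - Ho / He else NA_real_
    sd_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("hwe-", l))
    hwe_p <- hwe_exact_test(lc$a1, lc$a2, n_mc = n_mc, seed = sd_seed,
                            enum_bound = enum_bound)
    na_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("null-", l))
    nac <- null_allele_check(lc$a1, lc$a2, alpha = alpha, n_mc = n_mc,
                             seed = na_seed, enum_bound = enum_bound)
    data.frame(locus = l, n_typed = n, k = k, Ho = Ho, He = He, Fis = Fis,
               hwe_p = hwe_p,
               null_chakraborty = nac$estimate_chakraborty,
               null_brookfield1 = nac$estimate_brookfield1,
               null_p = nac$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  hwe_adj <- sequential_bonferroni(out$hwe_p, alpha = alpha)
  null_adj <- sequential_bonferroni(out$null_p, alpha = alpha)
  out$hwe_deviation <- hwe_adj$reject
  out$null_allele_suspect <- null_adj$reject & out$He > out$Ho
  out
}

#' Holm sequential-Bonferroni correction
#'
#' Step-down Holm adjustment; `reject` marks hypotheses significant at
#' `alpha` after adjustment. Holm rejects a superset of what the plain
#' Bonferroni correction rejects.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise level.
#' @return data.frame with `p`, `p_adjusted`, `reject`.
#' @export
sequential_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stop_kinnet("no p-values supplied")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_kinnet("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "holm")
  data.frame(p = pvalues, p_adjusted = adj, reject = adj <= alpha)
}

## -------------------------------------------------- linkage disequilibrium

#' Genotypic linkage-disequilibrium permutation test for a locus pair
#'
#' Log-likelihood-ratio (G) statistic on the two-locus genotype contingency
#' table over individuals typed at both loci; the null distribution comes
#' from permuting one locus' genotype column across individuals.
#'
#' @param table A [genotype_table()].
#' @param locus_a,locus_b Locus names.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return Permutation p-value with the add-one rule; 1.0 when either locus
#'   is monomorphic among the shared individuals.
#' @export
ld_test <- function(table, locus_a, locus_b, n_perm = 10000, seed = NULL) {
  if (!all(c(locus_a, locus_b) %in% table$loci)) stop_kinnet("unknown locus name")
  ok <- !is.na(table$a1[, locus_a]) & !is.na(table$a1[, locus_b])
  if (sum(ok) < 2L) stop_kinnet("fewer than 2 individuals typed at both loci")
  ga <- paste(table$a1[ok, locus_a], table$a2[ok, locus_a])
  gb <- paste(table$a1[ok, locus_b], table$a2[ok, locus_b])
  ia <- as.integer(factor(ga)); ib <- as.integer(factor(gb))
  na <- max(ia); nb <- max(ib)
  if (na < 2L || nb < 2L) return(1.0)
  g2 <- function(ia, ib) {
    o <- tabulate((ia - 1L) * nb + ib, nbins = na * nb)
    ra <- tabulate(ia, na); rb <- tabulate(ib, nb)
    e <- as.vector(outer(ra, rb)) / length(ia)
    nz <- o > 0
    2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  obs <- g2(ia, ib)
  with_seed(seed, {
    b <- 0L
    for (r in seq_len(n_perm)) {
      if (g2(ia, sample(ib)) >= obs - 1e-12) b <- b + 1L
    }
    mc_pvalue(b, n_perm)
  })
}

## ------------------------------------------------------------ duplicates

#' Screen for identical or near-identical multilocus genotypes
#'
#' Flags pairs of individuals whose genotypes disagree at no more than
#' `max_mismatch` of the loci typed in both; such pairs may be the same
#' animal sampled twice. Pairs sharing fewer than `min_shared` typed loci are
#' not comparable and are reported separately.
#'
#' @param table A [genotype_table()].
#' @param max_mismatch Maximum mismatching loci for a "duplicate" call.
#' @param min_shared Minimum shared typed loci for a pair to be comparable.
#' @return List with data.frames `matches` (`id_a`, `id_b`, `n_shared`,
#'   `n_mismatch`) and `incomparable` (`id_a`, `id_b`, `n_shared`).
#' @export
find_duplicate_genotypes <- function(table, max_mismatch = 0, min_shared = 5) {
  n <- length(table$ids)
  matches <- list(); incomp <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      shared <- !is.na(table$a1[i, ]) & !is.na(table$a1[j, ])
      ns <- sum(shared)
      if (ns < min_shared) {
        incomp[[length(incomp) + 1L]] <-
          data.frame(id_a = table$ids[i], id_b = table$ids[j], n_shared = ns,
                     stringsAsFactors = FALSE)
        next
      }
      mism <- sum(table$a1[i, shared] != table$a1[j, shared] |
                  table$a2[i, shared] != table$a2[j, shared])
      if (mism <= max_mismatch) {
        matches[[length(matches) + 1L]] <-
          data.frame(id_a = table$ids[i], id_b = table$ids[j], n_shared = ns,
                     n_mismatch = mism, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  list(matches = if (length(matches)) do.call(rbind, matches) else
         data.frame(id_a = character(0), id_b = character(0),
                    n_shared = integer(0), n_mismatch = integer(0)),
       incomparable = if (length(incomp)) do.call(rbind, incomp) else
         data.frame(id_a = character(0), id_b = character(0),
                    n_shared = integer(0)))
}
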