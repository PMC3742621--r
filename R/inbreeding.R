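## Internal relatedness (IR): allele-frequency-weighted homozygosity of a
## single individual, its random-mating Monte-Carlo null, a locus-subset
## robustness check and plain covariate summaries.

# Vectorised IR for rows of allele matrices (n x L), against `freqs`.
# Monomorphic and missing loci are excluded per individual.
ir_matrix <- function(a1, a2, freqs, loci) {
  n <- nrow(a1); L <- length(loci)
  poly <- vapply(loci, function(l) length(freqs[[l]]$freq) >= 2L, TRUE)
  f1 <- matrix(NA_real_, n, L); f2 <- matrix(NA_real_, n, L)
  for (li in seq_len(L)) {
    if (!poly[li]) next
    f <- freqs[[loci[li]]]$freq
    codes <- as.integer(names(f)); fv <- as.numeric(f)
    i1 <- match(a1[, li], codes); i2 <- match(a2[, li], codes)
    bad <- (!is.na(a1[, li]) & is.na(i1)) | (!is.na(a2[, li]) & is.na(i2))
    if (any(bad))
      stop_kinnet("allele absent from frequency table at locus ", loci[li])
    f1[, li] <- fv[i1]; f2[, li] <- fv[i2]
  }
  use <- !is.na(f1)
  H <- rowSums(use & a1 == a2, na.rm = TRUE)
  N <- rowSums(use)
  sumf <- rowSums(ifelse(use, f1 + f2, 0))
  den <- 2 * N - sumf
  out <- (2 * H - sumf) / den
  out[N == 0 | den <= 0] <- NA_real_
  out
}

# IR for one individual given allele vectors over used loci.
ir_value <- function(a1, a2, freqs, loci) {
  use <- !is.na(a1)
  # monomorphic loci carry no information and are excluded
  poly <- vapply(loci, function(l) length(freqs[[l]]$freq) >= 2L, TRUE)
  use <- use & poly
  if (!any(use)) return(NA_real_)
  H <- sum(a1[use] == a2[use])
  N <- sum(use)
  sumf <- 0
  for (l in which(use)) {
    f <- freqs[[loci[l]]]$freq
    codes <- as.integer(names(f))
    i1 <- match(a1[l], codes); i2 <- match(a2[l], codes)
    if (is.na(i1) || is.na(i2))
      stop_kinnet("allele absent from frequency table at locus ", loci[l])
    sumf <- sumf + as.numeric(f)[i1] + as.numeric(f)[i2]
  }
  den <- 2 * N - sumf
  if (den <= 0) return(NA_real_)
  (2 * H - sumf) / den
}

#' Internal relatedness of one individual
#'
#' `IR = (2H - sum(f)) / (2N - sum(f))`, where `H` is the number of
#' homozygous typed loci, `N` the number of typed polymorphic loci used and
#' `sum(f)` the summed population frequencies of the `2N` carried allele
#' copies. IR lies in `[-1, 1]`; it equals 1 exactly when the individual is
#' homozygous at every used locus, and is elevated in offspring of related
#' parents.
#'
#' @param table A [genotype_table()].
#' @param id Individual ID.
#' @param freqs An [allele_frequencies()] table defining the gene pool.
#' @return The IR value (`NA` if no usable locus).
#' @export
internal_relatedness <- function(table, id, freqs) {
  i <- match(id, table$ids)
  if (is.na(i)) stop_kinnet("unknown individual ID")
  loci <- intersect(table$loci, names(freqs))
  ir_value(table$a1[i, loci], table$a2[i, loci], freqs, loci)
}

#' Internal relatedness for every individual
#' @inheritParams internal_relatedness
#' @param ids Individuals to score (default: all).
#' @return Named numeric vector of IR values.
#' @export
ir_vector <- function(table, freqs, ids = table$ids) {
  i <- match(ids, table$ids)
  if (anyNA(i)) stop_kinnet("unknown individual ID")
  loci <- intersect(table$loci, names(freqs))
  out <- ir_matrix(table$a1[i, loci, drop = FALSE],
                   table$a2[i, loci, drop = FALSE], freqs, loci)
  stats::setNames(out, ids)
}

#' Monte-Carlo random-mating null for mean internal relatedness
#'
#' Each iteration draws mating pairs uniformly with replacement from the
#' supplied males and females, produces one simulated offspring per pair by
#' Mendelian sampling of the parental genotypes, scores each offspring's IR
#' against `freqs`, and records the iteration mean. The one-sided p-value
#' (elevated IR = inbreeding) is the add-one proportion of simulated means
#' at least as large as the observed mean.
#'
#' @param table A [genotype_table()] containing parents and observed
#'   offspring.
#' @param males,females IDs of the potential parents.
#' @param observed_ids IDs of the observed offspring whose mean IR is
#'   tested.
#' @param freqs An [allele_frequencies()] table (the gene pool).
#' @param n_iter Number of Monte-Carlo iterations.
#' @param n_offspring_per_iter Simulated offspring per iteration (default:
#'   the observed offspring count).
#' @param seed Optional seed.
#' @param two_sided If `TRUE`, doubles the smaller tail (default one-sided).
#' @return List of class `ir_result`: `ir` (named observed IR), `mean_ir`,
#'   `ci95` (normal-theory 95% CI of the observed mean), `null` (vector of
#'   simulated means), `null_mean`, `p`, `n_iter`.
#' @export
ir_random_mating_null <- function(table, males, females, observed_ids, freqs,
                                  n_iter = 1000, n_offspring_per_iter = NULL,
                                  seed = NULL, two_sided = FALSE) {
  if (length(males) < 1L || length(females) < 1L)
    stop_kinnet("need at least one male and one female")
  obs_ir <- ir_vector(table, freqs, observed_ids)
  obs_mean <- mean(obs_ir, na.rm = TRUE)
  n_off <- n_offspring_per_iter %||% length(observed_ids)
  loci <- intersect(table$loci, names(freqs))
  im <- match(males, table$ids); iv <- match(females, table$ids)
  if (anyNA(im) || anyNA(iv)) stop_kinnet("unknown parent ID")
  L <- length(loci)
  ma1 <- table$a1[im, loci, drop = FALSE]; ma2 <- table$a2[im, loci, drop = FALSE]
  fa1 <- table$a1[iv, loci, drop = FALSE]; fa2 <- table$a2[iv, loci, drop = FALSE]
  null_means <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      mi <- sample.int(length(males), n_off, replace = TRUE)
      fi <- sample.int(length(females), n_off, replace = TRUE)
      pick_m <- matrix(stats::runif(n_off * L) < 0.5, n_off, L)
      pick_f <- matrix(stats::runif(n_off * L) < 0.5, n_off, L)
      o1 <- ifelse(pick_m, ma1[mi, , drop = FALSE], ma2[mi, , drop = FALSE])
      o2 <- ifelse(pick_f, fa1[fi, , drop = FALSE], fa2[fi, , drop = FALSE])
      # locus skipped for an offspring when either parent is untyped there
      miss <- is.na(o1) | is.na(o2)
      o1[miss] <- NA_integer_; o2[miss] <- NA_integer_
      irs <- ir_matrix(pmin(o1, o2), pmax(o1, o2), freqs, loci)
      mean(irs, na.rm = TRUE)
    }, 0)
  })
  ge <- sum(null_means >= obs_mean - 1e-12)
  p <- mc_pvalue(ge, n_iter)
  if (two_sided) {
    le <- sum(null_means <= obs_mean + 1e-12)
    p <- min(1, 2 * min(mc_pvalue(ge, n_iter), mc_pvalue(le, n_iter)))
  }
  se <- stats::sd(obs_ir, na.rm = TRUE) / sqrt(sum(!is.na(obs_ir)))
  structure(list(ir = obs_ir, mean_ir = obs_mean,
                 ci95 = c(obs_mean - 1.96 * se, obs_mean + 1.96 * se),
                 null = null_means, null_mean = mean(null_means),
                 p = p, n_iter = n_iter),
            class = "ir_result")
}

#' @export
print.ir_result <- function(x, ...) {
  cat(sprintf("ir_result: observed mean IR = %.4f (95%% CI %.4f..%.4f), null mean = %.4f, p = %.4g (%d iterations)\n",
              x$mean_ir, x$ci95[1], x$ci95[2], x$null_mean, x$p, x$n_iter))
  invisible(x)
}

#' Internal relatedness on a high-diversity locus subset
#'
#' Recomputes IR using only loci with at least `min_alleles` alleles, a
#' robustness check against bias from low allelic diversity.
#'
#' @inheritParams ir_vector
#' @param min_alleles Minimum allele count for a locus to be kept.
#' @return List with `ir` (named vector on the restricted panel), `loci`
#'   (kept loci), `mean_subset`, `mean_full`.
#' @export
ir_locus_subset <- function(table, freqs, min_alleles = 5, ids = table$ids) {
  k <- vapply(names(freqs), function(l) length(freqs[[l]]$freq), 1L)
  keep <- names(freqs)[k >= min_alleles]
  if (length(keep) == 0L) stop_kinnet("no locus has >= ", min_alleles, " alleles")
  sub_tab <- subset_genotypes(table, loci = intersect(table$loci, keep))
  sub_freqs <- structure(freqs[keep], class = "allele_freq_table")
  list(ir = ir_vector(sub_tab, sub_freqs, ids),
       loci = keep,
       mean_subset = mean(ir_vector(sub_tab, sub_freqs, ids), na.rm = TRUE),
       mean_full = mean(ir_vector(table, freqs, ids), na.rm = TRUE))
}

#' IR against body size, maturity stage and cohort
#'
#' Ordinary least-squares regression of IR on total length, and one-way
#' ANOVAs of IR across maturity stages and across cohort years. These are
#' plain descriptive summaries.
#'
#' @param ir Named numeric vector of IR values (names = individual IDs).
#' @param meta Metadata data.frame covering the individuals.
#' @return List with `regression` (`slope`, `intercept`, `r_squared`, `p`),
#'   `stage_anova` (`F`, `df`, `p`), `cohort_anova` (`F`, `df`, `p`).
#'   Elements are `NA` when the covariate is constant or too sparse.
#' @export
ir_covariate_summary <- function(ir, meta) {
  m <- meta[match(names(ir), meta$id), ]
  out <- list(regression = list(slope = NA_real_, intercept = NA_real_,
                                r_squared = NA_real_, p = NA_real_),
              stage_anova = list(F = NA_real_, df = c(NA, NA), p = NA_real_),
              cohort_anova = list(F = NA_real_, df = c(NA, NA), p = NA_real_))
  ok <- !is.na(ir) & !is.na(m$total_length_cm)
  if (sum(ok) >= 3 && stats::sd(m$total_length_cm[ok]) > 0) {
    fit <- stats::lm(ir[ok] ~ m$total_length_cm[ok])
    s <- summary(fit)
    out$regression <- list(slope = unname(stats::coef(fit)[2]),
                           intercept = unname(stats::coef(fit)[1]),
                           r_squared = s$r.squared,
                           p = if (stats::sd(ir[ok]) > 0)
                             unname(s$coefficients[2, 4]) else NA_real_)
  }
  run_anova <- function(g) {
    ok <- !is.na(ir) & !is.na(g)
    g <- factor(g[ok])
    if (length(levels(g)) < 2 || sum(ok) < 3) return(list(F = NA_real_, df = c(NA, NA), p = NA_real_))
    a <- stats::anova(stats::aov(ir[ok] ~ g))
    list(F = a[1, "F value"], df = c(a[1, "Df"], a[2, "Df"]), p = a[1, "Pr(>F)"])
  }
  out$stage_anova <- run_anova(m$stage)
  out$cohort_anova <- run_anova(m$cohort_year)
  out
}
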