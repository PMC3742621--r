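## Likelihood-based parentage: candidate exclusion counts, parent-offspring
## LOD scores with a genotyping-error model, simulated delta confidence
## thresholds and strict-confidence assignment.

#' Count Mendelian mismatches between an offspring and a candidate parent
#'
#' Number of loci, typed in both individuals, at which the candidate shares
#' no allele with the offspring. A true parent shows 0 on error-free data.
#'
#' @param table A [genotype_table()].
#' @param offspring_id,candidate_id Individual IDs.
#' @return Integer count (loci missing in either individual are skipped).
#' @export
mendelian_mismatches <- function(table, offspring_id, candidate_id) {
  io <- match(offspring_id, table$ids); ic <- match(candidate_id, table$ids)
  if (is.na(io) || is.na(ic)) stop_kinnet("unknown individual ID")
  ok <- !is.na(table$a1[io, ]) & !is.na(table$a1[ic, ])
  if (!any(ok)) stop_kinnet("no shared typed loci")
  oa <- table$a1[io, ok]; ob <- table$a2[io, ok]
  ca <- table$a1[ic, ok]; cb <- table$a2[ic, ok]
  sum(!(ca == oa | ca == ob | cb == oa | cb == ob))
}

# Vectorised Mendelian transmission probability P(g_o | g_p, other parent
# drawn from f): one gene copy of the candidate (weight 1/2 each) plus an
# independent draw from the frequency table, over unordered arrangements.
transmission_prob <- function(pa, pb, oa, ob, f, codes = NULL, fv = NULL) {
  if (is.null(codes)) { codes <- as.integer(names(f)); fv <- as.numeric(f) }
  fo_a <- fv[match(oa, codes)]
  fo_b <- fv[match(ob, codes)]
  hom_o <- oa == ob
  contrib <- function(i) {
    ifelse(hom_o, (i == oa) * fo_a, (i == oa) * fo_b + (i == ob) * fo_a)
  }
  0.5 * contrib(pa) + 0.5 * contrib(pb)
}

# HWE genotype probability, vectorised.
hwe_genotype_prob <- function(oa, ob, f, codes = NULL, fv = NULL) {
  if (is.null(codes)) { codes <- as.integer(names(f)); fv <- as.numeric(f) }
  fa <- fv[match(oa, codes)]; fb <- fv[match(ob, codes)]
  ifelse(oa == ob, fa^2, 2 * fa * fb)
}

# Per-locus LOD ratio under the replacement error model: with probability e
# per individual per locus the observed genotype is an independent HWE draw,
# so the parental likelihood is (1-e)^2 T + (1-(1-e)^2) P(g_o) and the LOD
# ratio (1-e)^2 T / P(g_o) + 1 - (1-e)^2.
lod_ratio <- function(Tr, Pgo, error_rate) {
  keep <- (1 - error_rate)^2
  keep * Tr / Pgo + (1 - keep)
}

#' Parent-offspring LOD score
#'
#' Log-likelihood ratio, summed over shared typed loci, of the candidate
#' being a parent of the offspring (the other parent drawn from the
#' population allele frequencies) against both parents being random draws.
#' The genotyping-error model replaces an observed genotype with an
#' independent HWE draw with probability `error_rate` per individual per
#' locus; with `error_rate = 0` a single Mendelian mismatch gives `-Inf`.
#'
#' @param table A [genotype_table()].
#' @param offspring_id,candidate_id Individual IDs.
#' @param freqs An [allele_frequencies()] table.
#' @param error_rate Per-individual per-locus genotyping error probability.
#' @return The LOD score (natural log).
#' @export
parent_lod <- function(table, offspring_id, candidate_id, freqs,
                       error_rate = 0.01) {
  M <- lod_matrix(table, offspring_id, candidate_id, freqs, error_rate)
  as.numeric(M)
}

# LOD matrix offspring x candidates, vectorised per locus.
lod_matrix <- function(table, offspring_ids, candidate_ids, freqs,
                       error_rate = 0.01) {
  io <- match(offspring_ids, table$ids); ic <- match(candidate_ids, table$ids)
  if (anyNA(io) || anyNA(ic)) stop_kinnet("unknown individual ID")
  n_o <- length(io); n_c <- length(ic)
  out <- matrix(0, n_o, n_c, dimnames = list(offspring_ids, candidate_ids))
  loci <- intersect(table$loci, names(freqs))
  gi <- rep(seq_len(n_o), times = n_c)
  gj <- rep(seq_len(n_c), each = n_o)
  for (l in loci) {
    f <- freqs[[l]]$freq
    codes <- as.integer(names(f)); fv <- as.numeric(f)
    oa <- table$a1[io, l]; ob <- table$a2[io, l]
    ca <- table$a1[ic, l]; cb <- table$a2[ic, l]
    OA <- oa[gi]; OB <- ob[gi]; CA <- ca[gj]; CB <- cb[gj]
    use <- !is.na(OA) & !is.na(CA)
    if (!any(use)) next
    Tr <- transmission_prob(CA[use], CB[use], OA[use], OB[use], f, codes, fv)
    Pgo <- hwe_genotype_prob(OA[use], OB[use], f, codes, fv)
    inc <- numeric(length(OA))
    inc[use] <- log(lod_ratio(Tr, Pgo, error_rate))
    out <- out + matrix(inc, n_o, n_c)
  }
  out
}

#' Simulated critical delta for strict-confidence assignment
#'
#' Simulates parentage trials: a candidate pool is drawn from the allele
#' frequencies, the true parent is included in the pool with probability
#' `prop_parents_sampled`, the offspring is produced by Mendelian sampling
#' (with the genotyping-error model applied), and LOD scores are computed
#' for every candidate. Delta is the gap between the best and second-best
#' candidate LOD. The critical value is the smallest threshold at which at
#' least `confidence` of the simulated assignments made above it identify
#' the true parent.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param n_candidates Number of candidates per offspring.
#' @param prop_parents_sampled Probability that the true parent is in the
#'   candidate pool (in `(0, 1]`).
#' @param confidence Required assignment confidence (default 0.95).
#' @param n_sim Number of simulated offspring.
#' @param seed Optional seed.
#' @param error_rate Genotyping-error rate used both to perturb simulated
#'   genotypes and in the LOD scoring.
#' @return List with `critical`, `confidence`, `n_sim`,
#'   `assignment_rate` (share of sims with delta above the threshold).
#' @export
delta_criticals <- function(freqs, n_candidates, prop_parents_sampled,
                            confidence = 0.95, n_sim = 10000, seed = NULL,
                            error_rate = 0.01) {
  if (prop_parents_sampled <= 0 || prop_parents_sampled > 1)
    stop_kinnet("prop_parents_sampled must be in (0, 1]")
  loci <- names(freqs)
  with_seed(seed, {
    sampled <- stats::runif(n_sim) < prop_parents_sampled
    lod <- matrix(0, n_sim, n_candidates)
    for (l in loci) {
      f <- freqs[[l]]$freq
      codes <- as.integer(names(f)); fv <- as.numeric(f)
      draw <- function(n) sample(codes, n, replace = TRUE, prob = fv)
      ca <- matrix(draw(n_sim * n_candidates), n_sim, n_candidates)
      cb <- matrix(draw(n_sim * n_candidates), n_sim, n_candidates)
      tp1 <- ifelse(sampled, ca[, 1], draw(n_sim))
      tp2 <- ifelse(sampled, cb[, 1], draw(n_sim))
      m1 <- draw(n_sim); m2 <- draw(n_sim)
      of1 <- ifelse(stats::runif(n_sim) < 0.5, tp1, tp2)
      of2 <- ifelse(stats::runif(n_sim) < 0.5, m1, m2)
      err <- stats::runif(n_sim) < error_rate
      if (any(err)) { of1[err] <- draw(sum(err)); of2[err] <- draw(sum(err)) }
      oa <- pmin(of1, of2); ob <- pmax(of1, of2)
      Pgo <- hwe_genotype_prob(oa, ob, f, codes, fv)
      for (j in seq_len(n_candidates)) {
        Tr <- transmission_prob(ca[, j], cb[, j], oa, ob, f, codes, fv)
        lod[, j] <- lod[, j] + log(lod_ratio(Tr, Pgo, error_rate))
      }
    }
    best <- apply(lod, 1, max)
    arg <- apply(lod, 1, which.max)
    second <- vapply(seq_len(n_sim), function(i) max(lod[i, -arg[i]]), 0)
    delta <- best - second
    correct <- sampled & arg == 1L
    if (!any(correct))
      stop_kinnet("no correct assignments in simulation; increase n_sim")
    # an assignment additionally requires a positive LOD (the candidate must
    # be a better explanation than an arbitrary individual), mirroring
    # assign_parents()
    pos <- best > 0
    delta <- delta[pos]; correct <- correct[pos]
    m <- length(delta)
    ord <- order(delta, decreasing = TRUE)
    rate <- cumsum(correct[ord]) / seq_len(m)
    ok <- which(rate >= confidence)
    if (length(ok) == 0L) {
      warning("no threshold attains the requested confidence; returning Inf")
      return(list(critical = Inf, confidence = confidence, n_sim = n_sim,
                  assignment_rate = 0))
    }
    cut <- max(ok)
    # if even the smallest delta satisfies the confidence requirement no
    # gap is needed at all (also covers all-second-bests-excluded, where
    # every delta is infinite)
    crit <- if (cut == m) 0 else delta[ord][cut]
    if (!is.finite(crit)) crit <- max(delta[is.finite(delta)], 0) + 1
    list(critical = crit, confidence = confidence, n_sim = n_sim,
         assignment_rate = cut / n_sim)
  })
}

#' Assign offspring to candidate parents at strict confidence
#'
#' For each offspring and parental sex, the best candidate by LOD is
#' assigned when its LOD is positive (a better explanation than an arbitrary
#' individual) and its delta (gap to the second-best candidate) reaches the
#' simulated critical value. Mother-only, father-only and parent-pair
#' outcomes all occur.
#'
#' @param table A [genotype_table()].
#' @param offspring_ids Offspring to assign.
#' @param mother_ids,father_ids Candidate mothers / fathers (either may be
#'   empty, in which case that sex is left unassigned).
#' @param freqs An [allele_frequencies()] table.
#' @param error_rate Genotyping-error rate for the LOD model.
#' @param critical_mother,critical_father Critical delta values from
#'   [delta_criticals()] (or the lists it returns).
#' @return data.frame with one row per offspring: `offspring_id`,
#'   `mother_id`, `lod_mother`, `delta_mother`, `mother_confidence`,
#'   and the same for fathers. Unassigned slots are `NA` /
#'   `"unassigned"`; assigned slots are `"strict95"`.
#' @export
assign_parents <- function(table, offspring_ids, mother_ids, father_ids,
                           freqs, error_rate = 0.01,
                           critical_mother, critical_father) {
  crit_val <- function(x) if (is.list(x)) x$critical else x
  one_sex <- function(cands, critical) {
    n_o <- length(offspring_ids)
    res <- data.frame(id = rep(NA_character_, n_o), lod = NA_real_,
                      delta = NA_real_, confidence = "unassigned",
                      stringsAsFactors = FALSE)
    if (length(cands) == 0L) return(res)
    M <- lod_matrix(table, offspring_ids, cands, freqs, error_rate)
    for (i in seq_len(n_o)) {
      v <- M[i, ]
      j <- which.max(v)
      best <- v[j]
      second <- if (length(v) > 1L) max(v[-j]) else 0
      delta <- best - second
      res$lod[i] <- best
      res$delta[i] <- delta
      if (is.finite(best) && best > 0 && delta >= crit_val(critical)) {
        res$id[i] <- cands[j]
        res$confidence[i] <- "strict95"
      }
    }
    res
  }
  m <- one_sex(mother_ids, critical_mother)
  f <- one_sex(father_ids, critical_father)
  data.frame(offspring_id = offspring_ids,
             mother_id = m$id, lod_mother = m$lod, delta_mother = m$delta,
             mother_confidence = m$confidence,
             father_id = f$id, lod_father = f$lod, delta_father = f$delta,
             father_confidence = f$confidence,
             stringsAsFactors = FALSE)
}
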