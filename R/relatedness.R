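## Maximum-likelihood pairwise relatedness over the Cotterman k-coefficient
## simplex, and classification into the four standard relationship
## categories: unrelated (U), half-sibling (HS), full-sibling (FS) and
## parent-offspring (PO).

#' Cotterman k-coefficient vectors
#'
#' `(k0, k1, k2)` are the probabilities that a dyad shares 0, 1 or 2 alleles
#' identical by descent at a locus; the relatedness coefficient is
#' `r = k1/2 + k2`.
#'
#' @param k0,k1,k2 Non-negative probabilities summing to 1.
#' @return Named numeric vector of class `k_coefficients`.
#' @export
k_coefficients <- function(k0, k1, k2) {
  k <- c(k0 = k0, k1 = k1, k2 = k2)
  if (any(k < -1e-9)) stop_kinnet("k coefficients must be non-negative")
  if (abs(sum(k) - 1) > 1e-9) stop_kinnet("k coefficients must sum to 1")
  structure(pmax(k, 0), class = "k_coefficients")
}

#' Fixed k-vectors of the four relationship categories
#'
#' In tie-break order from least to most related: U = (1,0,0),
#' HS = (0.5,0.5,0), FS = (0.25,0.5,0.25), PO = (0,1,0).
#' @return A 4 x 3 matrix with rows U, HS, FS, PO.
#' @export
relationship_categories <- function() {
  rbind(U = c(1, 0, 0),
        HS = c(0.5, 0.5, 0),
        FS = c(0.25, 0.5, 0.25),
        PO = c(0, 1, 0))
}

#' Relatedness from k coefficients
#' @param k A `k_coefficients` vector or any length-3 vector `(k0,k1,k2)`.
#' @return `k1/2 + k2`.
#' @export
r_from_k <- function(k) {
  unname(k[2] / 2 + k[3])
}

# Vectorised per-locus probability components for many genotype pairs at one
# locus. (xa, xb) and (ya, yb) are the two genotypes (canonical order) as
# integer allele codes; f is the named frequency vector for the locus.
# Returns list(P0, P1, P2) with:
#   P0 = P(gx) P(gy) under HWE (0 alleles IBD),
#   P1 = P(gx) * P(gy | one allele of gy is a uniformly chosen gene copy of
#        gx, the other an independent draw from f),
#   P2 = P(gx) [gx == gy].
locus_prob_components <- function(xa, xb, ya, yb, f) {
  codes <- as.integer(names(f))
  fv <- as.numeric(f)
  look <- function(a) {
    i <- match(a, codes)
    if (anyNA(i[!is.na(a)]))
      stop_kinnet("allele absent from frequency table; estimate frequencies on a superset of the scored individuals")
    fv[i]
  }
  fxa <- look(xa); fxb <- look(xb); fya <- look(ya); fyb <- look(yb)
  hom_x <- xa == xb; hom_y <- ya == yb
  Pgx <- ifelse(hom_x, fxa^2, 2 * fxa * fxb)
  Pgy <- ifelse(hom_y, fya^2, 2 * fya * fyb)
  # transition: gene copy i of gx (weight 1/2 each) completes gy with a draw
  # from f
  contrib <- function(i) {
    ifelse(hom_y, (i == ya) * fya, (i == ya) * fyb + (i == yb) * fya)
  }
  Tr <- 0.5 * contrib(xa) + 0.5 * contrib(xb)
  list(P0 = Pgx * Pgy, P1 = Pgx * Tr, P2 = Pgx * (xa == ya & xb == yb))
}

#' Single-locus likelihood of a genotype pair under given k coefficients
#'
#' `k0 P0 + k1 P1 + k2 P2`, where the components condition on sharing 0, 1 or
#' 2 alleles identical by descent (see the package vignette for the model).
#'
#' @param g1,g2 Length-2 integer vectors (unordered genotypes).
#' @param freqs Named numeric vector of allele frequencies at the locus.
#' @param k A length-3 k-coefficient vector `(k0, k1, k2)`.
#' @return The likelihood (a probability).
#' @export
pair_locus_likelihood <- function(g1, g2, freqs, k) {
  if (abs(sum(k) - 1) > 1e-9 || any(k < -1e-9))
    stop_kinnet("invalid k coefficients")
  g1 <- sort(as.integer(g1)); g2 <- sort(as.integer(g2))
  pc <- locus_prob_components(g1[1], g1[2], g2[1], g2[2], freqs)
  unname(k[1] * pc$P0 + k[2] * pc$P1 + k[3] * pc$P2)
}

# Per-locus (P0, P1, P2) matrix (3 x L) for one pair across shared typed
# loci. Used by both the ML estimator and the fixed-category classifier.
pair_component_matrix <- function(table, id_a, id_b, freqs) {
  ia <- match(id_a, table$ids); ib <- match(id_b, table$ids)
  if (is.na(ia) || is.na(ib)) stop_kinnet("unknown individual ID")
  loci <- intersect(table$loci, names(freqs))
  shared <- loci[!is.na(table$a1[ia, loci]) & !is.na(table$a1[ib, loci])]
  if (length(shared) == 0L) stop_kinnet("pair shares no typed loci")
  V <- vapply(shared, function(l) {
    pc <- locus_prob_components(table$a1[ia, l], table$a2[ia, l],
                                table$a1[ib, l], table$a2[ib, l],
                                freqs[[l]]$freq)
    c(pc$P0, pc$P1, pc$P2)
  }, numeric(3))
  matrix(V, nrow = 3, dimnames = list(c("P0", "P1", "P2"), shared))
}

# Lattice over the 2-simplex (step 0.02) plus the four category vertices,
# restricted to the region attainable by outbred dyads (k1^2 >= 4 k0 k2).
k_lattice <- function(step = 0.02) {
  g <- seq(0, 1, by = step)
  pts <- expand.grid(k0 = g, k1 = g)
  pts <- pts[pts$k0 + pts$k1 <= 1 + 1e-12, ]
  K <- cbind(pts$k0, pts$k1, pmax(1 - pts$k0 - pts$k1, 0))
  K <- rbind(K, relationship_categories())
  K[K[, 2]^2 >= 4 * K[, 1] * K[, 3] - 1e-12, , drop = FALSE]
}

# Multilocus log-likelihood of k rows (m x 3) given component matrix (3 x L).
k_loglik <- function(K, V) {
  P <- K %*% V
  P[P < 0] <- 0
  rowSums(log(P))
}

#' Maximum-likelihood k coefficients for one pair
#'
#' Maximises the multilocus likelihood over the 2-simplex, restricted to the
#' region attainable by non-inbred dyads (`k1^2 >= 4 k0 k2`), by evaluating
#' a fixed lattice (step 0.02, plus the four category vertices) and
#' polishing the best point with a deterministic Nelder-Mead search. Loci
#' missing in either individual are dropped pairwise.
#'
#' @param table A [genotype_table()].
#' @param id_a,id_b Individual IDs.
#' @param freqs An [allele_frequencies()] table covering all scored alleles.
#' @return List with `k` (a [k_coefficients()] vector), `loglik`, `r_hat`
#'   and `n_loci_used`.
#' @export
ml_k_estimate <- function(table, id_a, id_b, freqs) {
  V <- pair_component_matrix(table, id_a, id_b, freqs)
  K <- k_lattice()
  ll <- k_loglik(K, V)
  best <- which.max(ll)
  k0 <- K[best, ]
  best_ll <- ll[best]
  # polish from a slightly interior start
  eps <- 1e-4
  start <- (k0 + eps) / (1 + 3 * eps)
  obj <- function(th) {
    k <- c(th, 1 - sum(th))
    if (any(k < 0) || k[2]^2 < 4 * k[1] * k[3]) return(Inf)
    P <- as.vector(k %*% V)
    if (any(P <= 0)) return(Inf)
    -sum(log(P))
  }
  opt <- try(stats::optim(start[1:2], obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(opt, "try-error")) opt <- list(value = Inf)
  if (-opt$value > best_ll) {
    k0 <- c(opt$par, 1 - sum(opt$par))
    best_ll <- -opt$value
  }
  k0 <- pmax(k0, 0); k0 <- k0 / sum(k0)
  list(k = k_coefficients(k0[1], k0[2], k0[3]),
       loglik = best_ll, r_hat = r_from_k(k0), n_loci_used = ncol(V))
}

#' Classify a pair into U / HS / FS / PO
#'
#' Evaluates the four fixed-k hypotheses and picks the category with the
#' greatest multilocus likelihood; exact ties are broken toward the less
#' related category in the order U, HS, FS, PO.
#'
#' @inheritParams ml_k_estimate
#' @return List of class `pair_relationship`: `id_a`, `id_b`, `ml_k`,
#'   `r_hat`, `loglik` (named vector over categories), `best_category`,
#'   `n_loci_used`.
#' @export
classify_relationship <- function(table, id_a, id_b, freqs) {
  V <- pair_component_matrix(table, id_a, id_b, freqs)
  cats <- relationship_categories()
  ll <- k_loglik(cats, V)
  names(ll) <- rownames(cats)
  best <- names(ll)[which.max(ll)]   # which.max returns the first maximum:
                                     # rows are ordered U, HS, FS, PO
  mk <- ml_k_estimate(table, id_a, id_b, freqs)
  structure(list(id_a = id_a, id_b = id_b, ml_k = mk$k, r_hat = mk$r_hat,
                 loglik = ll, best_category = best,
                 n_loci_used = ncol(V), significance_p = NULL),
            class = "pair_relationship")
}

#' @export
print.pair_relationship <- function(x, ...) {
  cat(sprintf("pair %s - %s: best %s, r_hat = %.3f (%d loci)\n",
              x$id_a, x$id_b, x$best_category, x$r_hat, x$n_loci_used))
  invisible(x)
}

# Simulate one genotype pair at the typed loci of `pattern` under k, given
# freqs. Returns a two-row genotype "mini table" (matrices a1, a2, 2 x L).
simulate_pair_under_k <- function(k, freqs, loci) {
  L <- length(loci)
  a1x <- a2x <- a1y <- a2y <- integer(L)
  z <- sample.int(3, L, replace = TRUE, prob = k) - 1L
  for (l in seq_len(L)) {
    f <- freqs[[loci[l]]]$freq
    codes <- as.integer(names(f))
    draw <- function(n) sample(codes, n, replace = TRUE, prob = as.numeric(f))
    gx <- draw(2)
    gy <- switch(as.character(z[l]),
                 "0" = draw(2),
                 "1" = c(gx[sample.int(2, 1)], draw(1)),
                 "2" = gx)
    gx <- sort(gx); gy <- sort(gy)
    a1x[l] <- gx[1]; a2x[l] <- gx[2]; a1y[l] <- gy[1]; a2y[l] <- gy[2]
  }
  genotype_table(c("x", "y"), loci, rbind(a1x, a1y), rbind(a2x, a2y))
}

#' Significance of one relationship category against another
#'
#' Parametric-bootstrap test: genotype pairs are simulated under the null
#' category at the pair's typed loci, the log-likelihood ratio
#' (alternative minus null) is computed for each, and the p-value is the
#' add-one proportion of simulated ratios at least as large as the observed
#' one.
#'
#' @inheritParams ml_k_estimate
#' @param null_category,alt_category Distinct category names among
#'   `"U"`, `"HS"`, `"FS"`, `"PO"`.
#' @param n_sim Number of simulated pairs.
#' @param seed Optional seed.
#' @return The p-value.
#' @export
relationship_significance <- function(table, id_a, id_b, freqs,
                                      null_category = "U", alt_category = "HS",
                                      n_sim = 5000, seed = NULL) {
  cats <- relationship_categories()
  if (!null_category %in% rownames(cats) || !alt_category %in% rownames(cats))
    stop_kinnet("unknown relationship category")
  if (null_category == alt_category) stop_kinnet("categories must be distinct")
  V <- pair_component_matrix(table, id_a, id_b, freqs)
  loci <- colnames(V)
  kn <- cats[null_category, ]; ka <- cats[alt_category, ]
  obs <- k_loglik(rbind(ka), V) - k_loglik(rbind(kn), V)
  with_seed(seed, {
    b <- 0L
    for (s in seq_len(n_sim)) {
      sim <- simulate_pair_under_k(kn, freqs, loci)
      Vs <- pair_component_matrix(sim, "x", "y", freqs)
      lr <- k_loglik(rbind(ka), Vs) - k_loglik(rbind(kn), Vs)
      if (lr >= obs - 1e-12) b <- b + 1L
    }
    mc_pvalue(b, n_sim)
  })
}

#' Pairwise relatedness matrix and category matrix
#'
#' Computes `r_hat` (from the ML k estimate) and the best fixed-category call
#' for every dyad among `ids`.
#'
#' @param table A [genotype_table()].
#' @param freqs An [allele_frequencies()] table.
#' @param ids Individuals to include (default: all in `table`).
#' @return List of class `relatedness_matrix` with `r` (symmetric numeric
#'   matrix, `NA` diagonal), `category` (character matrix), and `dyads`
#'   (data.frame `id_a`, `id_b`, `r_hat`, `k0`, `k1`, `k2`, `best_category`,
#'   per-category log-likelihoods, `n_loci_used`).
#' @export
relatedness_matrix <- function(table, freqs, ids = table$ids) {
  ids <- as.character(ids)
  if (length(ids) < 2L) stop_kinnet("need at least two individuals")
  n <- length(ids)
  r <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  cat_m <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  rows <- vector("list", n * (n - 1) / 2)
  idx <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pr <- classify_relationship(table, ids[i], ids[j], freqs)
      r[i, j] <- r[j, i] <- pr$r_hat
      cat_m[i, j] <- cat_m[j, i] <- pr$best_category
      idx <- idx + 1L
      rows[[idx]] <- data.frame(id_a = ids[i], id_b = ids[j],
                                r_hat = pr$r_hat,
                                k0 = pr$ml_k[1], k1 = pr$ml_k[2], k2 = pr$ml_k[3],
                                best_category = pr$best_category,
                                loglik_U = pr$loglik["U"], loglik_HS = pr$loglik["HS"],
                                loglik_FS = pr$loglik["FS"], loglik_PO = pr$loglik["PO"],
                                n_loci_used = pr$n_loci_used,
                                stringsAsFactors = FALSE)
    }
  }
  dyads <- do.call(rbind, rows)
  rownames(dyads) <- NULL
  structure(list(r = r, category = cat_m, dyads = dyads),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  s <- relatedness_summary(x)
  cat(sprintf("relatedness_matrix: %d individuals, %d dyads; mean R = %.3f (SD %.3f)\n",
              nrow(x$r), nrow(x$dyads), s$mean, s$sd))
  invisible(x)
}

#' Mean and SD of pairwise relatedness over off-diagonal dyads
#' @param x A `relatedness_matrix` (or plain symmetric matrix).
#' @param ids Optional subset of individuals.
#' @return List with `mean`, `sd`, `n_dyads`.
#' @export
relatedness_summary <- function(x, ids = NULL) {
  r <- if (inherits(x, "relatedness_matrix")) x$r else x
  if (!is.null(ids)) r <- r[ids, ids, drop = FALSE]
  v <- r[upper.tri(r)]
  v <- v[!is.na(v)]
  list(mean = mean(v), sd = stats::sd(v), n_dyads = length(v))
}
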