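## Full-likelihood sibship and parentage reconstruction.
##
## A configuration assigns every offspring a mother reference and a father
## reference; each reference is either a sampled individual or a latent
## (reconstructed) parent, labelled "#k" for mothers and "*k" for fathers.
## The configuration likelihood is, per locus, the probability of the
## offspring genotypes given the parent assignments, with latent (and
## untyped sampled) parent genotypes summed out exactly under HWE priors,
## an observation-error model on offspring genotypes, and per-parent prior
## terms for whether the true parent was sampled. The maximiser is a
## simulated-annealing search over family partitions; an exhaustive
## partition search is provided as an oracle for small problems.

is_latent_parent <- function(x) grepl("^[#*]", x)

# --- context: everything the likelihood needs, prebuilt once ---------------
sibship_context <- function(table, offspring_ids, freqs, error_rate,
                            prior_mother_sampled, prior_father_sampled) {
  loci <- intersect(table$loci, names(freqs))
  io <- match(offspring_ids, table$ids)
  if (anyNA(io)) stop_kinnet("unknown offspring ID")
  per_locus <- lapply(loci, function(l) {
    f <- freqs[[l]]$freq
    codes <- as.integer(names(f)); fv <- as.numeric(f)
    oa <- table$a1[io, l]; ob <- table$a2[io, l]
    list(codes = codes, fv = fv, oa = oa, ob = ob,
         pgo = hwe_genotype_prob(oa, ob, NULL, codes, fv))
  })
  names(per_locus) <- loci
  cache <- new.env(parent = emptyenv())
  cache$.n <- 0L
  # sampled individuals typed at every locus are observed variables in the
  # factor graph and do not connect couples into one component
  complete <- rowSums(is.na(table$a1[, loci, drop = FALSE])) == 0L
  names(complete) <- table$ids
  list(offspring = offspring_ids, loci = loci, per_locus = per_locus,
       table = table, e = error_rate,
       pm = prior_mother_sampled, pf = prior_father_sampled,
       complete = complete, incomplete = table$ids[!complete],
       cache = cache)
}

# Genotype of a (possibly sampled) parent at a locus; NA alleles if latent
# or untyped.
parent_alleles <- function(ctx, parent, locus) {
  if (is_latent_parent(parent)) return(c(NA_integer_, NA_integer_))
  i <- match(parent, ctx$table$ids)
  if (is.na(i)) stop_kinnet("sampled parent ", parent, " absent from genotype table")
  c(ctx$table$a1[i, locus], ctx$table$a2[i, locus])
}

# Memoised unordered genotype-pair index template for a domain of mA alleles.
pair_template_env <- new.env(parent = emptyenv())
pair_template <- function(mA) {
  key <- as.character(mA)
  t <- pair_template_env[[key]]
  if (is.null(t)) {
    g1 <- integer(0); g2 <- integer(0)
    for (i in seq_len(mA)) { g1 <- c(g1, seq_len(i)); g2 <- c(g2, rep.int(i, i)) }
    t <- list(g1 = g1, g2 = g2, nG = length(g1))
    pair_template_env[[key]] <- t
  }
  t
}

# --- tiny factor algebra (per-variable domain sizes) -----------------------
# A factor is list(vars = character, dims = integer (same length), val =
# array with dim = dims (or plain vector/scalar)).
factor_expand <- function(f, union_vars, dim_of) {
  k <- length(f$vars); m <- length(union_vars)
  if (k == m && all(f$vars == union_vars)) return(f$val)
  others <- setdiff(union_vars, f$vars)
  arr <- array(f$val, dim = c(if (k) f$dims else integer(0), dim_of[others]))
  cur <- c(f$vars, others)
  aperm(arr, match(union_vars, cur))
}

factor_product <- function(factors, dim_of) {
  union_vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  val <- factor_expand(factors[[1]], union_vars, dim_of)
  for (f in factors[-1]) val <- val * factor_expand(f, union_vars, dim_of)
  list(vars = union_vars, dims = unname(dim_of[union_vars]), val = val)
}

factor_sum_out <- function(f, var) {
  pos <- match(var, f$vars)
  m <- length(f$vars)
  if (m == 1L) return(list(vars = character(0), dims = integer(0), val = sum(f$val)))
  ap <- aperm(array(f$val, dim = f$dims), c(setdiff(seq_len(m), pos), pos))
  newdims <- f$dims[-pos]
  dim(ap) <- c(prod(newdims), f$dims[pos])
  list(vars = f$vars[-pos], dims = newdims,
       val = array(rowSums(ap), dim = newdims))
}

# Sum the product of all factors over all variables except `keep`.
# `dim_of` is a named integer vector of domain sizes per variable.
# Returns list(logscale, val over keep-vars) or logscale = -Inf when zero.
eliminate_all <- function(factors, vars, dim_of, keep = character(0)) {
  logscale <- 0
  elim <- setdiff(vars, keep)
  while (length(elim)) {
    # greedy: pick the variable whose joint factor is smallest
    costs <- vapply(elim, function(v) {
      inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
      u <- unique(unlist(lapply(factors[inv], `[[`, "vars")))
      sum(log(dim_of[u]))
    }, 1)
    v <- elim[which.min(costs)]
    inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
    joint <- factor_product(factors[inv], dim_of)
    red <- factor_sum_out(joint, v)
    s <- max(red$val)
    if (s <= 0) return(list(logscale = -Inf, val = NULL, vars = character(0)))
    red$val <- red$val / s
    logscale <- logscale + log(s)
    factors <- c(factors[!inv], list(red))
    elim <- setdiff(elim, v)
  }
  scalars <- vapply(factors, function(f) length(f$vars) == 0L, TRUE)
  for (f in factors[scalars]) {
    if (f$val <= 0) return(list(logscale = -Inf, val = NULL, vars = character(0)))
    logscale <- logscale + log(f$val)
  }
  rest <- factors[!scalars]
  if (length(rest) == 0L) return(list(logscale = logscale, val = NULL, vars = character(0)))
  joint <- factor_product(rest, dim_of)
  list(logscale = logscale, val = joint$val, vars = joint$vars)
}

# --- per-component, per-locus likelihood -----------------------------------
# couples: list of list(mo, fa, off = integer offspring indices).
# Each parent gets its own reduced genotype domain: the alleles observed in
# its own offspring (plus its own typed alleles for sampled parents) and a
# pooled "any other allele" class, coded 0. Pooling is exact: alleles a
# parent could carry but never needs to transmit to a scored offspring are
# likelihood-equivalent.
component_locus_factors <- function(ctx, parents, couples, locus) {
  ld <- ctx$per_locus[[locus]]
  e <- ctx$e
  typed <- !is.na(ld$oa)
  rel <- stats::setNames(vector("list", length(parents)), parents)
  for (cp in couples) {
    use <- cp$off[typed[cp$off]]
    als <- c(ld$oa[use], ld$ob[use])
    rel[[cp$mo]] <- c(rel[[cp$mo]], als)
    rel[[cp$fa]] <- c(rel[[cp$fa]], als)
  }
  geno <- list()
  dim_of <- integer(0)
  unary <- vector("list", length(parents))
  for (pi in seq_along(parents)) {
    p <- parents[pi]
    al <- parent_alleles(ctx, p, locus)
    R <- sort(unique(c(rel[[p]], al[!is.na(al)])))
    fR <- ld$fv[match(R, ld$codes)]
    if (anyNA(fR))
      stop_kinnet("allele absent from frequency table at locus ", locus)
    fz <- max(0, 1 - sum(fR))
    if (fz > 1e-12 || length(R) == 0L) { R <- c(R, 0L); fR <- c(fR, fz) }
    tpl <- pair_template(length(R))
    g1 <- tpl$g1; g2 <- tpl$g2; nG <- tpl$nG
    prior <- ifelse(g1 == g2, fR[g1]^2, 2 * fR[g1] * fR[g2])
    v <- if (!anyNA(al)) {
      i <- match(al, R)
      w <- numeric(nG); w[g1 == min(i) & g2 == max(i)] <- 1; w
    } else prior
    geno[[p]] <- list(A = R, g1 = g1, g2 = g2)
    dim_of[p] <- nG
    unary[[pi]] <- list(vars = p, dims = nG, val = v)
  }
  tvec <- function(p, a) {
    g <- geno[[p]]
    i <- match(a, g$A)
    ((g$g1 == i) + (g$g2 == i)) / 2
  }
  couple_factors <- lapply(couples, function(cp) {
    off <- cp$off[typed[cp$off]]
    M <- matrix(1, dim_of[cp$mo], dim_of[cp$fa])
    for (o in off) {
      x <- ld$oa[o]; y <- ld$ob[o]
      pgo <- ld$pgo[o]
      mend <- outer(tvec(cp$mo, x), tvec(cp$fa, y))
      if (x != y) mend <- mend + outer(tvec(cp$mo, y), tvec(cp$fa, x))
      M <- M * ((1 - e) * mend + e * pgo)
    }
    list(vars = c(cp$mo, cp$fa), dims = unname(dim_of[c(cp$mo, cp$fa)]), val = M)
  })
  list(factors = c(unary, couple_factors), dim_of = dim_of, geno = geno)
}

# Fast path for a component made of a single couple: direct
# um' M uf quadrature instead of generic variable elimination.
couple_loglik <- function(ctx, cp) {
  e <- ctx$e
  mo_lat <- is_latent_parent(cp$mo); fa_lat <- is_latent_parent(cp$fa)
  im <- if (mo_lat) NA_integer_ else match(cp$mo, ctx$table$ids)
  if_ <- if (fa_lat) NA_integer_ else match(cp$fa, ctx$table$ids)
  if ((!mo_lat && is.na(im)) || (!fa_lat && is.na(if_)))
    stop_kinnet("sampled parent absent from genotype table")
  ll <- 0
  for (li in seq_along(ctx$loci)) {
    ld <- ctx$per_locus[[li]]
    off <- cp$off[!is.na(ld$oa[cp$off])]
    if (length(off) == 0L) next
    l <- ctx$loci[li]
    mal <- if (mo_lat) NA_integer_ else c(ctx$table$a1[im, l], ctx$table$a2[im, l])
    fal <- if (fa_lat) NA_integer_ else c(ctx$table$a1[if_, l], ctx$table$a2[if_, l])
    pgo <- ld$pgo[off]
    if (length(off) == 1L && anyNA(mal) && anyNA(fal)) {
      # both parents integrated over HWE: marginal is the HWE probability
      ll <- ll + log(pgo)
      next
    }
    A <- sort.int(unique(c(ld$oa[off], ld$ob[off], mal[!is.na(mal)], fal[!is.na(fal)])))
    fA <- ld$fv[match(A, ld$codes)]
    if (anyNA(fA)) stop_kinnet("allele absent from frequency table")
    fz <- max(0, 1 - sum(fA))
    if (fz > 1e-12) { A <- c(A, 0L); fA <- c(fA, fz) }
    tpl <- pair_template(length(A))
    g1 <- tpl$g1; g2 <- tpl$g2; nG <- tpl$nG
    prior <- ifelse(g1 == g2, fA[g1]^2, 2 * fA[g1] * fA[g2])
    unary <- function(al) {
      if (anyNA(al)) return(prior)
      i <- match(al, A)
      v <- numeric(nG); v[g1 == min(i) & g2 == max(i)] <- 1
      v
    }
    um <- unary(mal); uf <- unary(fal)
    M <- NULL
    for (oi in seq_along(off)) {
      x <- match(ld$oa[off[oi]], A); y <- match(ld$ob[off[oi]], A)
      tx <- ((g1 == x) + (g2 == x)) / 2
      ty <- ((g1 == y) + (g2 == y)) / 2
      mend <- outer(tx, ty)
      if (x != y) mend <- mend + outer(ty, tx)
      Mo <- (1 - e) * mend + e * pgo[oi]
      M <- if (is.null(M)) Mo else M * Mo
    }
    lik <- as.numeric(um %*% M %*% uf)
    if (lik <= 0) return(-Inf)
    ll <- ll + log(lik)
  }
  ll
}

component_loglik <- function(ctx, parents, couples) {
  if (length(couples) == 1L) return(couple_loglik(ctx, couples[[1]]))
  component_peel_loglik(ctx, parents, couples)
}

# Multi-couple components: direct peeling of leaf parents (message passing
# on the couple tree); components with mating cycles fall back to generic
# variable elimination.
component_peel_loglik <- function(ctx, parents, couples) {
  e <- ctx$e
  np <- length(parents)
  lat <- is_latent_parent(parents)
  prow <- match(parents, ctx$table$ids)
  if (any(!lat & is.na(prow)))
    stop_kinnet("sampled parent absent from genotype table")
  moi <- match(vapply(couples, `[[`, "", "mo"), parents)
  fai <- match(vapply(couples, `[[`, "", "fa"), parents)
  ll <- 0
  for (li in seq_along(ctx$loci)) {
    ld <- ctx$per_locus[[li]]
    l <- ctx$loci[li]
    offl <- lapply(couples, function(cp) cp$off[!is.na(ld$oa[cp$off])])
    active <- which(lengths(offl) > 0L)
    if (length(active) == 0L) next
    # per-parent domains from its typed offspring (+ own typed alleles)
    relal <- vector("list", np)
    for (ci in active) {
      als <- c(ld$oa[offl[[ci]]], ld$ob[offl[[ci]]])
      relal[[moi[ci]]] <- c(relal[[moi[ci]]], als)
      relal[[fai[ci]]] <- c(relal[[fai[ci]]], als)
    }
    used <- sort.int(unique(c(moi[active], fai[active])))
    dom <- vector("list", np); un <- vector("list", np)
    for (pi in used) {
      own <- if (lat[pi]) NA_integer_ else
        c(ctx$table$a1[prow[pi], l], ctx$table$a2[prow[pi], l])
      A <- sort.int(unique(c(relal[[pi]], own[!is.na(own)])))
      fA <- ld$fv[match(A, ld$codes)]
      if (anyNA(fA)) stop_kinnet("allele absent from frequency table")
      fz <- max(0, 1 - sum(fA))
      if (fz > 1e-12 || length(A) == 0L) { A <- c(A, 0L); fA <- c(fA, fz) }
      tpl <- pair_template(length(A))
      dom[[pi]] <- list(A = A, g1 = tpl$g1, g2 = tpl$g2, nG = tpl$nG)
      un[[pi]] <- if (!anyNA(own)) {
        i <- match(own, A)
        v <- numeric(tpl$nG); v[tpl$g1 == min(i) & tpl$g2 == max(i)] <- 1; v
      } else ifelse(tpl$g1 == tpl$g2, fA[tpl$g1]^2, 2 * fA[tpl$g1] * fA[tpl$g2])
    }
    mk_couple_matrix <- function(ci) {
      dm <- dom[[moi[ci]]]; df <- dom[[fai[ci]]]
      M <- NULL
      for (o in offl[[ci]]) {
        x <- ld$oa[o]; y <- ld$ob[o]
        xm <- match(x, dm$A); ym <- match(y, dm$A)
        xf <- match(x, df$A); yf <- match(y, df$A)
        tmx <- ((dm$g1 == xm) + (dm$g2 == xm)) / 2
        tfy <- ((df$g1 == yf) + (df$g2 == yf)) / 2
        mend <- outer(tmx, tfy)
        if (x != y) {
          tmy <- ((dm$g1 == ym) + (dm$g2 == ym)) / 2
          tfx <- ((df$g1 == xf) + (df$g2 == xf)) / 2
          mend <- mend + outer(tmy, tfx)
        }
        Mo <- (1 - e) * mend + e * ld$pgo[o]
        M <- if (is.null(M)) Mo else M * Mo
      }
      M
    }
    Ms <- vector("list", length(couples))
    for (ci in active) Ms[[ci]] <- mk_couple_matrix(ci)
    cnt <- integer(np)
    for (ci in active) { cnt[moi[ci]] <- cnt[moi[ci]] + 1L; cnt[fai[ci]] <- cnt[fai[ci]] + 1L }
    logscale <- 0
    remaining <- active
    repeat {
      if (length(remaining) == 0L) break
      leaf <- NA_integer_; side <- ""
      for (ci in remaining) {
        if (cnt[moi[ci]] == 1L) { leaf <- ci; side <- "m"; break }
        if (cnt[fai[ci]] == 1L) { leaf <- ci; side <- "f"; break }
      }
      if (is.na(leaf)) {                   # mating cycle: generic elimination
        vars <- unique(c(moi[remaining], fai[remaining]))
        dims <- vapply(vars, function(pi) dom[[pi]]$nG, 1L)
        names(dims) <- as.character(vars)
        fs <- c(lapply(vars, function(pi)
          list(vars = as.character(pi), dims = dom[[pi]]$nG, val = un[[pi]])),
          lapply(remaining, function(ci)
            list(vars = as.character(c(moi[ci], fai[ci])),
                 dims = c(dom[[moi[ci]]]$nG, dom[[fai[ci]]]$nG), val = Ms[[ci]])))
        res <- eliminate_all(fs, as.character(vars), dims)
        if (!is.finite(res$logscale)) return(-Inf)
        logscale <- logscale + res$logscale
        remaining <- integer(0)
        break
      }
      if (side == "m") {
        p <- moi[leaf]; q <- fai[leaf]
        msg <- as.vector(un[[p]] %*% Ms[[leaf]])
      } else {
        p <- fai[leaf]; q <- moi[leaf]
        msg <- as.vector(Ms[[leaf]] %*% un[[p]])
      }
      un[[q]] <- un[[q]] * msg
      s <- max(un[[q]])
      if (s <= 0) return(-Inf)
      un[[q]] <- un[[q]] / s
      logscale <- logscale + log(s)
      cnt[p] <- cnt[p] - 1L; cnt[q] <- cnt[q] - 1L
      remaining <- remaining[remaining != leaf]
      if (cnt[q] == 0L) {
        sq <- sum(un[[q]])
        if (sq <= 0) return(-Inf)
        logscale <- logscale + log(sq)
      }
    }
    ll <- ll + logscale
  }
  ll
}

# Does this parent reference act as a latent variable (and hence connect
# couples into one component)?
parent_connects <- function(ctx, p) {
  if (is_latent_parent(p)) return(TRUE)
  !isTRUE(ctx$complete[p])
}

# Split couples into factor-graph components, connecting only through
# latent (or partially typed) parents.
couple_components <- function(ctx, couples) {
  moL <- vapply(couples, `[[`, "", "mo")
  faL <- vapply(couples, `[[`, "", "fa")
  parents <- unique(c(moL, faL))
  connects <- vapply(parents, function(p) parent_connects(ctx, p), TRUE)
  nC <- length(couples)
  pid <- seq_len(nC)                       # union-find over couples
  find <- function(x) { while (pid[x] != x) x <- pid[x]; x }
  for (p in parents[connects]) {
    inc <- which(moL == p | faL == p)
    if (length(inc) > 1L) {
      r <- find(inc[1])
      for (j in inc[-1]) { rj <- find(j); if (rj != r) pid[rj] <- r }
    }
  }
  roots <- vapply(seq_len(nC), find, 1L)
  split(seq_len(nC), roots)
}

# Full configuration log-likelihood for mother/father assignment vectors.
sibship_loglik <- function(ctx, mo, fa) {
  n <- length(ctx$offspring)
  ckey <- paste(mo, fa, sep = "\r")
  ug <- unique(ckey)
  cidx <- match(ckey, ug)
  fo <- match(ug, ckey)
  moL <- mo[fo]; faL <- fa[fo]
  offs <- split(seq_len(n), cidx)
  nC <- length(ug)
  # sampled-in-pool prior terms, one per offspring: the prior probability
  # that an offspring's true parent is among the sampled candidates. Keeping
  # the term per offspring (not per family) leaves family merges and splits
  # to the genotype likelihood alone.
  lat_m <- substr(mo, 1L, 1L) == "#"
  lat_f <- substr(fa, 1L, 1L) == "*"
  ll <- sum(lat_m) * log(1 - ctx$pm) + sum(!lat_m) * log(ctx$pm) +
    sum(lat_f) * log(1 - ctx$pf) + sum(!lat_f) * log(ctx$pf)
  # union-find over couples, connecting only through latent / partially
  # typed parents
  pid <- seq_len(nC)
  find <- function(x) { while (pid[x] != x) x <- pid[x]; x }
  both <- c(moL, faL)
  cpl <- rep(seq_len(nC), 2L)
  keep <- substr(both, 1L, 1L) %in% c("#", "*") | both %in% ctx$incomplete
  for (grp in split(cpl[keep], both[keep])) {
    if (length(grp) > 1L) {
      r <- find(grp[1])
      for (j in grp[-1]) { rj <- find(j); if (rj != r) pid[rj] <- r }
    }
  }
  roots <- vapply(seq_len(nC), find, 1L)
  offstr <- vapply(offs, function(v) paste(v, collapse = ","), "")
  # canonical keys: latent labels are interchangeable, so they are replaced
  # by "#"/"*" (single-couple components) or by within-component first-use
  # numbers (multi-couple components)
  mlat <- substr(moL, 1L, 1L) == "#"
  flat <- substr(faL, 1L, 1L) == "*"
  key1 <- paste(ifelse(mlat, "#", moL), ifelse(flat, "*", faL), offstr, sep = "|")
  for (comp in split(seq_len(nC), roots)) {
    if (length(comp) == 1L) {
      idx <- comp
      key <- key1[idx]
    } else {
      idx <- sort.int(comp)
      ml <- moL[idx]; fl <- faL[idx]
      mk <- ml; fk <- fl
      if (any(mlat[idx])) mk[mlat[idx]] <- match(ml[mlat[idx]], unique(ml[mlat[idx]]))
      if (any(flat[idx])) fk[flat[idx]] <- match(fl[flat[idx]], unique(fl[flat[idx]]))
      key <- paste(mk, fk, offstr[idx], sep = "|", collapse = ";")
    }
    cached <- ctx$cache[[key]]
    if (!is.null(cached)) { ll <- ll + cached; next }
    cc <- lapply(idx, function(i) list(mo = moL[i], fa = faL[i], off = offs[[i]]))
    cpar <- unique(c(moL[idx], faL[idx]))
    v <- component_loglik(ctx, cpar, cc)
    if (ctx$cache$.n > 200000L) {
      rm(list = setdiff(ls(ctx$cache), ".n"), envir = ctx$cache)
      ctx$cache$.n <- 0L
    }
    ctx$cache[[key]] <- v
    ctx$cache$.n <- ctx$cache$.n + 1L
    ll <- ll + v
  }
  ll
}

# --- annealer ---------------------------------------------------------------
anneal_sibship <- function(ctx, init_mo, init_fa, fixed_mo, fixed_fa,
                           cand_mothers, cand_fathers,
                           n_moves, t0 = 3, t_end = 0.05, verbose = FALSE) {
  n <- length(ctx$offspring)
  mo <- init_mo; fa <- init_fa
  counter <- new.env(); counter$m <- sum(is_latent_parent(mo));
  counter$f <- sum(is_latent_parent(fa))
  fresh <- function(sex) {
    if (sex == "m") { counter$m <- counter$m + 1L; paste0("#", counter$m + 1000L) }
    else { counter$f <- counter$f + 1L; paste0("*", counter$f + 1000L) }
  }
  cur_ll <- sibship_loglik(ctx, mo, fa)
  best_mo <- mo; best_fa <- fa; best_ll <- cur_ll
  if (n_moves < 1 || n < 2) {
    return(list(mo = mo, fa = fa, loglik = cur_ll))
  }
  alpha <- (t_end / t0)^(1 / n_moves)
  temp <- t0
  tick <- Sys.time()
  for (step in seq_len(n_moves)) {
    if (verbose && step %% 2000L == 0L) {
      cat(sprintf("    move %d/%d ll %.1f best %.1f cache %d (%.1fs)\n",
                  step, n_moves, cur_ll, best_ll, ctx$cache$.n,
                  as.numeric(Sys.time() - tick)))
      tick <- Sys.time()
    }
    new_mo <- mo; new_fa <- fa
    sex <- if (stats::runif(1) < 0.5) "m" else "f"
    vec <- if (sex == "m") mo else fa
    fixed <- if (sex == "m") fixed_mo else fixed_fa
    cands <- if (sex == "m") cand_mothers else cand_fathers
    movable <- which(!fixed)
    if (length(movable) == 0L) next
    type <- sample.int(3L, 1L, prob = c(0.6, 0.2, 0.2))
    if (type == 1L) {                       # reassign one offspring
      o <- movable[sample.int(length(movable), 1L)]
      pool <- setdiff(unique(c(vec, cands, fresh(sex))), vec[o])
      vec[o] <- pool[sample.int(length(pool), 1L)]
    } else if (type == 2L) {                # merge family into another parent
      fams <- unique(vec[movable])
      if (length(fams) < 1L) next
      src <- fams[sample.int(length(fams), 1L)]
      pool <- setdiff(unique(c(vec, cands)), src)
      if (length(pool) == 0L) next
      dst <- pool[sample.int(length(pool), 1L)]
      vec[vec == src & !fixed] <- dst
    } else {                                # split a family
      fams <- unique(vec[movable])
      sizes <- vapply(fams, function(x) sum(vec == x & !fixed), 1L)
      fams <- fams[sizes >= 2L]
      if (length(fams) == 0L) next
      src <- fams[sample.int(length(fams), 1L)]
      members <- which(vec == src & !fixed)
      take <- members[stats::runif(length(members)) < 0.5]
      if (length(take) == 0L || length(take) == length(members))
        take <- members[sample.int(length(members), 1L)]
      vec[take] <- fresh(sex)
    }
    if (sex == "m") new_mo <- vec else new_fa <- vec
    new_ll <- sibship_loglik(ctx, new_mo, new_fa)
    if (new_ll >= cur_ll || stats::runif(1) < exp((new_ll - cur_ll) / temp)) {
      mo <- new_mo; fa <- new_fa; cur_ll <- new_ll
      if (cur_ll > best_ll) { best_ll <- cur_ll; best_mo <- mo; best_fa <- fa }
    }
    temp <- temp * alpha
  }
  list(mo = best_mo, fa = best_fa, loglik = best_ll)
}

# Renumber latent labels in first-appearance order.
canonical_labels <- function(x, prefix) {
  lat <- unique(x[is_latent_parent(x)])
  map <- stats::setNames(paste0(prefix, seq_along(lat)), lat)
  ifelse(is_latent_parent(x), unname(map[x]), x)
}

#' Reconstruct sibship and parentage by full-likelihood annealing
#'
#' Partitions offspring into maternal and paternal families, each headed by
#' a sampled candidate or a latent (reconstructed) parent, by maximising the
#' full configuration likelihood with simulated annealing. Polygamy is
#' allowed for both sexes (maternal and paternal families intersect freely),
#' so half-sib groups arise naturally; a monogamy-style analysis can be
#' emulated by post-hoc inspection of the full-sib partition. Replicate runs
#' with different seeds are compared by pairwise full-sib partition
#' agreement.
#'
#' @param table A [genotype_table()] holding offspring and sampled adults.
#' @param offspring_ids Offspring to partition.
#' @param freqs An [allele_frequencies()] table.
#' @param candidate_mothers,candidate_fathers Sampled candidate parents.
#' @param known Optional data.frame (`offspring_id`, `mother_id`,
#'   `father_id`, `NA` allowed) of assignments treated as hard constraints,
#'   e.g. strict-confidence assignments from [assign_parents()].
#' @param error_rate Per-individual per-locus genotyping error probability.
#' @param prior_mother_sampled,prior_father_sampled Prior probability that a
#'   family's true mother (father) is among the sampled candidates.
#' @param n_replicates Number of annealing replicates (different seeds).
#' @param seed Base seed; replicate seeds are derived from it.
#' @param n_moves Annealing chain length (default `max(2000, 8 * n^2)` for
#'   `n` offspring).
#' @param t0,t_end Geometric cooling schedule endpoints.
#' @return List of class `sibship_solution`: `assignment` (data.frame
#'   `offspring_id`, `mother_ref`, `father_ref`; latent mothers `#k`,
#'   latent fathers `*k`), `loglik`, `replicates` (per-replicate
#'   assignments and log-likelihoods), `replicate_agreement` (mean pairwise
#'   fraction of offspring pairs on which the replicate full-sib partitions
#'   agree), `seed`.
#' @export
sibship_reconstruct <- function(table, offspring_ids, freqs,
                                candidate_mothers = character(0),
                                candidate_fathers = character(0),
                                known = NULL,
                                error_rate = 0.01,
                                prior_mother_sampled = 0.25,
                                prior_father_sampled = 0.5,
                                n_replicates = 3, seed = 1,
                                n_moves = NULL, t0 = 3, t_end = 0.05,
                                verbose = FALSE) {
  n <- length(offspring_ids)
  if (n < 1L) stop_kinnet("no offspring")
  ctx <- sibship_context(table, offspring_ids, freqs, error_rate,
                         prior_mother_sampled, prior_father_sampled)
  fixed_mo <- rep(FALSE, n); fixed_fa <- rep(FALSE, n)
  mo0 <- paste0("#", seq_len(n)); fa0 <- paste0("*", seq_len(n))
  if (!is.null(known)) {
    if (anyDuplicated(known$offspring_id))
      stop_kinnet("contradictory known assignments: an offspring appears twice")
    idx <- match(known$offspring_id, offspring_ids)
    if (anyNA(idx)) stop_kinnet("known assignment for unknown offspring")
    has_m <- !is.na(known$mother_id)
    has_f <- !is.na(known$father_id)
    mo0[idx[has_m]] <- known$mother_id[has_m]
    fa0[idx[has_f]] <- known$father_id[has_f]
    fixed_mo[idx[has_m]] <- TRUE
    fixed_fa[idx[has_f]] <- TRUE
  }
  if (is.null(n_moves)) n_moves <- max(2000L, as.integer(8 * n^2))
  reps <- lapply(seq_len(n_replicates), function(r) {
    res <- with_seed(derive_seed(seed, paste0("sibship-rep", r)),
                     anneal_sibship(ctx, mo0, fa0, fixed_mo, fixed_fa,
                                    candidate_mothers, candidate_fathers,
                                    n_moves, t0, t_end, verbose = verbose))
    list(assignment = data.frame(offspring_id = offspring_ids,
                                 mother_ref = canonical_labels(res$mo, "#"),
                                 father_ref = canonical_labels(res$fa, "*"),
                                 stringsAsFactors = FALSE),
         loglik = res$loglik, replicate = r)
  })
  lls <- vapply(reps, `[[`, 0, "loglik")
  best <- reps[[which.max(lls)]]
  agree <- NA_real_
  if (n_replicates >= 2 && n >= 2) {
    pair_key <- function(a) {
      paste(a$mother_ref, a$father_ref)
    }
    ut <- utils::combn(n, 2)
    same_mat <- vapply(reps, function(rp) {
      k <- pair_key(rp$assignment)
      k[ut[1, ]] == k[ut[2, ]]
    }, logical(ncol(ut)))
    pairs_of_reps <- utils::combn(n_replicates, 2)
    agree <- mean(vapply(seq_len(ncol(pairs_of_reps)), function(i) {
      mean(same_mat[, pairs_of_reps[1, i]] == same_mat[, pairs_of_reps[2, i]])
    }, 0))
  }
  structure(list(assignment = best$assignment, loglik = best$loglik,
                 replicates = reps, replicate_agreement = agree,
                 seed = seed, context = ctx),
            class = "sibship_solution")
}

#' @export
print.sibship_solution <- function(x, ...) {
  cat(sprintf("sibship_solution: %d offspring, %d maternal / %d paternal families, loglik %.2f\n",
              nrow(x$assignment), length(unique(x$assignment$mother_ref)),
              length(unique(x$assignment$father_ref)), x$loglik))
  if (!is.na(x$replicate_agreement))
    cat(sprintf("  replicate pair agreement: %.3f\n", x$replicate_agreement))
  invisible(x)
}

#' Exhaustive sibship search (oracle for small problems)
#'
#' Enumerates every pair of maternal and paternal set partitions of the
#' offspring (all parents latent) and returns the configuration with the
#' greatest likelihood under the same model as [sibship_reconstruct()].
#' Intended as an exact check for problems of at most ~7 offspring.
#'
#' @inheritParams sibship_reconstruct
#' @return List with `assignment`, `loglik`.
#' @export
sibship_exhaustive <- function(table, offspring_ids, freqs,
                               error_rate = 0.01,
                               prior_mother_sampled = 0.25,
                               prior_father_sampled = 0.5) {
  n <- length(offspring_ids)
  if (n > 8L) stop_kinnet("exhaustive search supports at most 8 offspring")
  ctx <- sibship_context(table, offspring_ids, freqs, error_rate,
                         prior_mother_sampled, prior_father_sampled)
  parts <- set_partitions(n)
  best_ll <- -Inf; best_mo <- NULL; best_fa <- NULL
  for (pm in parts) {
    mo <- paste0("#", pm)
    for (pf in parts) {
      fa <- paste0("*", pf)
      ll <- sibship_loglik(ctx, mo, fa)
      if (ll > best_ll) { best_ll <- ll; best_mo <- mo; best_fa <- fa }
    }
  }
  list(assignment = data.frame(offspring_id = offspring_ids,
                               mother_ref = canonical_labels(best_mo, "#"),
                               father_ref = canonical_labels(best_fa, "*"),
                               stringsAsFactors = FALSE),
       loglik = best_ll)
}

# All set partitions of n elements as block-index vectors (restricted growth
# strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxb) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

#' Reconstruct latent parent genotypes from a sibship solution
#'
#' For every latent parent and locus, computes the exact marginal posterior
#' over its genotype given the family's offspring, any sampled co-parents
#' and the allele frequencies (other latent parents in the same component
#' are summed out). Genotypes within a relative tolerance of the maximum
#' are reported as an ambiguity set; the pooled "any other allele" class is
#' reported as allele code `NA`.
#'
#' @param solution A `sibship_solution`.
#' @param table,freqs As in [sibship_reconstruct()].
#' @param error_rate Observation-error rate (defaults to the solution's).
#' @param tol Relative likelihood tolerance for calling a tie.
#' @param decisive Minimum share of the posterior mass the top genotype must
#'   carry for the call to be considered unambiguous.
#' @return data.frame with `parent`, `locus`, `allele1`, `allele2`
#'   (point estimate, `NA` = unresolved/other), `posterior_max` (share of
#'   the posterior mass on the top genotype), `ambiguous` (ties, pooled
#'   "other" alleles, or a top share below `decisive` — a one-offspring
#'   family is maximally ambiguous), `n_tied`, and `candidates`
#'   (semicolon-separated tied genotypes).
#' @export
reconstruct_parent_genotypes <- function(solution, table, freqs,
                                         error_rate = NULL, tol = 1e-6,
                                         decisive = 0.95) {
  ctx <- solution$context
  if (!is.null(error_rate)) ctx$e <- error_rate
  asn <- solution$assignment
  mo <- asn$mother_ref; fa <- asn$father_ref
  n <- nrow(asn)
  ckey <- paste(mo, fa, sep = "\r")
  groups <- split(seq_len(n), ckey)
  couples <- lapply(groups, function(idx)
    list(mo = mo[idx[1]], fa = fa[idx[1]], off = idx))
  comps <- couple_components(ctx, couples)
  rows <- list()
  for (ci in comps) {
    cc <- couples[ci]
    cpar <- unique(c(vapply(cc, `[[`, "", "mo"), vapply(cc, `[[`, "", "fa")))
    latents <- cpar[is_latent_parent(cpar)]
    for (target in latents) {
      for (locus in ctx$loci) {
        fb <- component_locus_factors(ctx, cpar, cc, locus)
        res <- eliminate_all(fb$factors, cpar, fb$dim_of, keep = target)
        if (is.null(res$val)) next
        post <- as.numeric(res$val)
        mx <- max(post)
        tied <- which(post >= mx * (1 - tol) - 1e-300)
        gp <- fb$geno[[target]]
        lab <- function(i) {
          a1 <- gp$A[gp$g1[i]]; a2 <- gp$A[gp$g2[i]]
          c(ifelse(a1 == 0L, NA_integer_, a1), ifelse(a2 == 0L, NA_integer_, a2))
        }
        top <- lab(tied[1])
        cand <- vapply(tied, function(i) paste(lab(i), collapse = "/"), "")
        share <- mx / sum(post)
        rows[[length(rows) + 1L]] <- data.frame(
          parent = target, locus = locus,
          allele1 = top[1], allele2 = top[2],
          posterior_max = share,
          ambiguous = length(tied) > 1L || anyNA(top) || share < decisive,
          n_tied = length(tied),
          candidates = paste(cand, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Count breeders from assignments and a sibship solution
#'
#' Distinct sampled mothers and fathers with at least one assigned
#' offspring, plus distinct latent (genotype-reconstructed) parents in the
#' sibship solution.
#'
#' @param assignments Optional data.frame from [assign_parents()].
#' @param solution A `sibship_solution` (its parent references may include
#'   sampled individuals).
#' @return List of class `breeder_count` with `mothers_sampled`,
#'   `fathers_sampled`, `mothers_reconstructed`, `fathers_reconstructed`,
#'   `total`.
#' @export
count_breeders <- function(assignments = NULL, solution) {
  mo <- solution$assignment$mother_ref
  fa <- solution$assignment$father_ref
  ms <- unique(mo[!is_latent_parent(mo)])
  fs <- unique(fa[!is_latent_parent(fa)])
  if (!is.null(assignments)) {
    ms <- unique(c(ms, assignments$mother_id[assignments$mother_confidence == "strict95"]))
    fs <- unique(c(fs, assignments$father_id[assignments$father_confidence == "strict95"]))
    ms <- ms[!is.na(ms)]; fs <- fs[!is.na(fs)]
  }
  mr <- unique(mo[is_latent_parent(mo)])
  fr <- unique(fa[is_latent_parent(fa)])
  out <- list(mothers_sampled = length(ms), fathers_sampled = length(fs),
              mothers_reconstructed = length(mr),
              fathers_reconstructed = length(fr),
              total = length(ms) + length(fs) + length(mr) + length(fr))
  structure(out, class = "breeder_count")
}

#' @export
print.breeder_count <- function(x, ...) {
  cat("breeders:", x$mothers_sampled, "sampled +", x$mothers_reconstructed,
      "reconstructed mothers;", x$fathers_sampled, "sampled +",
      x$fathers_reconstructed, "reconstructed fathers; total", x$total, "\n")
  invisible(x)
}

#' Tabulate litters and mating-system summaries
#'
#' A litter is the set of offspring sharing one mother reference and one
#' cohort year. Offspring with unknown cohort year stay in the sibship but
#' are listed separately and excluded from the per-year statistics.
#'
#' @param solution A `sibship_solution`.
#' @param meta Metadata data.frame covering the offspring (`id`,
#'   `cohort_year`, `site`).
#' @return List with `litters` (data.frame `mother_ref`, `cohort_year`,
#'   `n_offspring`, `offspring`, `sires`, `n_sires`, `sites`),
#'   `unknown_year` (same shape, year `NA`), and `summary`: `polyandry_fraction`
#'   (share of multi-young litters with >= 2 sires; `NA` when there are no
#'   multi-young litters), `n_multi_young`, `n_polyandrous`,
#'   `father_litter_counts`, `fraction_fathers_multiple_litters`,
#'   `mothers_multi_year` (data.frame of repeat breeders with their years,
#'   nursery repeat use and minimum inter-litter gap).
#' @export
litter_table <- function(solution, meta) {
  asn <- solution$assignment
  m <- meta[match(asn$offspring_id, meta$id), ]
  df <- data.frame(offspring_id = asn$offspring_id,
                   mother_ref = asn$mother_ref,
                   father_ref = asn$father_ref,
                   cohort_year = m$cohort_year,
                   site = m$site, stringsAsFactors = FALSE)
  known <- df[!is.na(df$cohort_year), , drop = FALSE]
  unknown <- df[is.na(df$cohort_year), , drop = FALSE]
  mk_litters <- function(d) {
    if (nrow(d) == 0L)
      return(data.frame(mother_ref = character(0), cohort_year = integer(0),
                        n_offspring = integer(0), offspring = character(0),
                        sires = character(0), n_sires = integer(0),
                        sites = character(0), stringsAsFactors = FALSE))
    key <- paste(d$mother_ref, d$cohort_year, sep = "\r")
    do.call(rbind, lapply(split(d, key), function(g) {
      data.frame(mother_ref = g$mother_ref[1], cohort_year = g$cohort_year[1],
                 n_offspring = nrow(g),
                 offspring = paste(sort(g$offspring_id), collapse = ";"),
                 sires = paste(sort(unique(g$father_ref)), collapse = ";"),
                 n_sires = length(unique(g$father_ref)),
                 sites = paste(sort(unique(g$site[!is.na(g$site)])), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }
  litters <- mk_litters(known)
  rownames(litters) <- NULL
  unknown_litters <- mk_litters(unknown)
  multi <- litters[litters$n_offspring >= 2L, , drop = FALSE]
  n_poly <- sum(multi$n_sires >= 2L)
  poly_frac <- if (nrow(multi) > 0L) n_poly / nrow(multi) else NA_real_
  # father-level summary over litters with known year
  sire_lists <- strsplit(litters$sires, ";")
  father_litters <- table(unlist(sire_lists))
  frac_multi_fathers <- if (length(father_litters) > 0L)
    mean(father_litters >= 2L) else NA_real_
  # repeat-breeding mothers
  mm <- split(litters, litters$mother_ref)
  mm <- mm[vapply(mm, nrow, 1L) >= 2L]
  mothers_multi <- if (length(mm)) do.call(rbind, lapply(mm, function(g) {
    yrs <- sort(unique(g$cohort_year))
    data.frame(mother_ref = g$mother_ref[1],
               years = paste(yrs, collapse = ";"),
               n_litters = nrow(g),
               same_site = length(unique(unlist(strsplit(g$sites, ";")))) == 1L,
               min_gap = if (length(yrs) > 1L) min(diff(yrs)) else NA_integer_,
               stringsAsFactors = FALSE)
  })) else data.frame(mother_ref = character(0), years = character(0),
                      n_litters = integer(0), same_site = logical(0),
                      min_gap = integer(0))
  rownames(mothers_multi) <- NULL
  list(litters = litters, unknown_year = unknown_litters,
       summary = list(polyandry_fraction = poly_frac,
                      n_multi_young = nrow(multi), n_polyandrous = n_poly,
                      father_litter_counts = father_litters,
                      fraction_fathers_multiple_litters = frac_multi_fathers,
                      mothers_multi_year = mothers_multi))
}
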