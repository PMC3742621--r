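# Shared simulation helpers and independent oracles.

# Allele-frequency table with k equifrequent alleles (codes 1..k) at L loci.
equifreq_table <- function(L, k, loci = paste0("L", seq_len(L))) {
  out <- lapply(seq_len(L), function(i)
    list(freq = stats::setNames(rep(1 / k, k), seq_len(k)), n_copies = NA_integer_))
  names(out) <- loci
  structure(out, class = "allele_freq_table")
}

# HWE draws for a set of individuals at the loci of `freqs`.
hwe_table <- function(ids, freqs) {
  loci <- names(freqs)
  a1 <- sapply(loci, function(l) {
    f <- freqs[[l]]$freq
    sample(as.integer(names(f)), length(ids), replace = TRUE, prob = as.numeric(f))
  })
  a2 <- sapply(loci, function(l) {
    f <- freqs[[l]]$freq
    sample(as.integer(names(f)), length(ids), replace = TRUE, prob = as.numeric(f))
  })
  genotype_table(ids, loci, matrix(a1, nrow = length(ids)),
                 matrix(a2, nrow = length(ids)))
}

# Append a Mendelian offspring of two individuals to a genotype table.
add_child <- function(tab, id, mother, father) {
  g <- kinnet:::gene_drop(tab, mother, father)
  genotype_table(c(tab$ids, id), tab$loci, rbind(tab$a1, g$a1), rbind(tab$a2, g$a2))
}

# Independent brute-force oracle for the single-locus pair likelihood under
# k = (k0, k1, k2): full enumeration over ordered gene copies and IBD
# configurations.
oracle_pair_locus <- function(g1, g2, f, k) {
  codes <- as.integer(names(f)); p <- as.numeric(f)
  g1 <- sort(g1); g2 <- sort(g2)
  same <- function(x, y, g) min(x, y) == g[1] && max(x, y) == g[2]
  tot <- 0
  for (xi in seq_along(codes)) for (yi in seq_along(codes)) {
    if (!same(codes[xi], codes[yi], g1)) next
    pg1 <- p[xi] * p[yi]
    # IBD 0: independent HWE draw for g2
    p0 <- 0
    for (zi in seq_along(codes)) for (wi in seq_along(codes))
      if (same(codes[zi], codes[wi], g2)) p0 <- p0 + p[zi] * p[wi]
    # IBD 1: one gene copy of g2 is a uniformly chosen copy of g1
    p1 <- 0
    for (s in c(xi, yi)) for (zi in seq_along(codes))
      if (same(codes[s], codes[zi], g2)) p1 <- p1 + 0.5 * p[zi]
    # IBD 2
    p2 <- as.numeric(identical(g1, g2))
    tot <- tot + pg1 * (k[1] * p0 + k[2] * p1 + k[3] * p2)
  }
  tot
}

# All unordered genotypes over allele codes.
all_genotypes <- function(codes) {
  out <- list()
  for (i in seq_along(codes)) for (j in i:length(codes))
    out[[length(out) + 1L]] <- c(codes[i], codes[j])
  out
}
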