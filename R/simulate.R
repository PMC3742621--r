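## Ground-truthed pedigree and genotype simulator. The generator emulates a
## small, closed island shark population: a fixed pool of adults, biennial
## female breeding with occasional exceptions, litters of 1-13 pups,
## polyandrous females (2-3 sires per litter), skewed male reproductive
## success, female nursery fidelity, partial sampling of adults, a
## per-genotype error rate, optional null alleles at designated loci and
## missing data.

NULL_ALLELE_CODE <- 999L

#' Specification of a simulated pedigree study
#'
#' Defaults describe the emulated study population: 16 microsatellite loci
#' with 2-15 alleles, tens of adults of each sex, four breeding years,
#' mostly biennial females, litters of 1-13 pups dominated by singletons,
#' 2-3 sires for most multi-pup litters, skewed male success, four nursery
#' sites with high female fidelity, a 1\% genotyping error rate and a little
#' missing data.
#'
#' @param n_founder_males,n_founder_females Adults of each sex in the pool.
#' @param n_breeding_years Number of breeding seasons simulated.
#' @param start_year Calendar year of the first season.
#' @param female_cycle `"biennial"`, `"annual"` or `"mixed"`.
#' @param cycle_exception_prob For `"mixed"`: probability that a female
#'   ignores the biennial rule in a given year.
#' @param female_breed_prob Probability an eligible female breeds in a year.
#' @param litter_size_probs Probabilities over litter sizes 1..13.
#' @param sires_per_litter_probs Probabilities over 1..`length` sires per
#'   litter (capped at the litter size).
#' @param male_skew Gamma concentration of male mating weights; smaller
#'   values give stronger reproductive skew.
#' @param nursery_sites Character vector of nursery site labels.
#' @param site_fidelity Probability a female reuses her home nursery.
#' @param adult_sampling_fraction,juvenile_sampling_fraction Sampling
#'   probabilities applied when the observation model is run.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Integer vector (recycled) of allele counts per
#'   locus; `NULL` spreads counts over 2..15.
#' @param freq_profile `"empirical"` (uneven frequencies) or
#'   `"equifrequent"`.
#' @param error_rate Per-individual per-locus genotyping error probability.
#' @param null_allele_freq Named numeric vector of null-allele frequencies
#'   for designated loci (empty = none).
#' @param missing_rate Per-call missing-data probability.
#' @return List of class `pedigree_spec`.
#' @export
pedigree_spec <- function(n_founder_males = 18, n_founder_females = 22,
                          n_breeding_years = 4, start_year = 2006,
                          female_cycle = c("biennial", "annual", "mixed"),
                          cycle_exception_prob = 0.1,
                          female_breed_prob = 0.5,
                          litter_size_probs = NULL,
                          sires_per_litter_probs = c(0.35, 0.45, 0.2),
                          male_skew = 0.5,
                          nursery_sites = c("Moorea", "Tetiaroa", "Tahaa", "Rangiroa"),
                          site_fidelity = 0.85,
                          adult_sampling_fraction = 0.75,
                          juvenile_sampling_fraction = 1,
                          n_loci = 16, alleles_per_locus = NULL,
                          freq_profile = c("empirical", "equifrequent"),
                          error_rate = 0.01,
                          null_allele_freq = numeric(0),
                          missing_rate = 0.02) {
  female_cycle <- match.arg(female_cycle)
  freq_profile <- match.arg(freq_profile)
  if (is.null(litter_size_probs)) {
    litter_size_probs <- c(20, 2, 3, 6, 1, 0.5, 0.25, 0.1, 0.05, 0.03, 0.02, 0.01, 0.01)
  }
  if (length(litter_size_probs) != 13L || any(litter_size_probs < 0))
    stop_kinnet("litter_size_probs must be 13 non-negative weights (sizes 1..13)")
  litter_size_probs <- litter_size_probs / sum(litter_size_probs)
  sires_per_litter_probs <- sires_per_litter_probs / sum(sires_per_litter_probs)
  if (is.null(alleles_per_locus)) {
    alleles_per_locus <- round(seq(2, 15, length.out = n_loci))
  }
  alleles_per_locus <- rep_len(alleles_per_locus, n_loci)
  probs <- c(cycle_exception_prob, female_breed_prob, site_fidelity,
             adult_sampling_fraction, juvenile_sampling_fraction,
             error_rate, missing_rate, null_allele_freq)
  if (any(probs < 0 | probs > 1)) stop_kinnet("probabilities must lie in [0, 1]")
  structure(list(n_founder_males = n_founder_males,
                 n_founder_females = n_founder_females,
                 n_breeding_years = n_breeding_years, start_year = start_year,
                 female_cycle = female_cycle,
                 cycle_exception_prob = cycle_exception_prob,
                 female_breed_prob = female_breed_prob,
                 litter_size_probs = litter_size_probs,
                 sires_per_litter_probs = sires_per_litter_probs,
                 male_skew = male_skew, nursery_sites = nursery_sites,
                 site_fidelity = site_fidelity,
                 adult_sampling_fraction = adult_sampling_fraction,
                 juvenile_sampling_fraction = juvenile_sampling_fraction,
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 freq_profile = freq_profile, error_rate = error_rate,
                 null_allele_freq = null_allele_freq,
                 missing_rate = missing_rate),
            class = "pedigree_spec")
}

# Truth allele-frequency tables for the spec's loci (including null alleles
# at designated loci, coded NULL_ALLELE_CODE).
simulate_locus_freqs <- function(spec) {
  loci <- paste0("Loc", formatC(seq_len(spec$n_loci), width = 2, flag = "0"))
  nl <- names(spec$null_allele_freq)
  if (length(nl) && !all(nl %in% loci))
    stop_kinnet("null_allele_freq names must match locus names (Loc01, Loc02, ...)")
  out <- list()
  for (i in seq_len(spec$n_loci)) {
    k <- spec$alleles_per_locus[i]
    codes <- 100L + 2L * seq_len(k)
    w <- if (spec$freq_profile == "equifrequent") rep(1, k) else stats::rgamma(k, 1)
    f <- w / sum(w)
    lname <- loci[i]
    fn <- spec$null_allele_freq[lname]
    if (length(fn) == 1L && !is.na(fn) && fn > 0) {
      f <- c(f * (1 - fn), fn)
      codes <- c(codes, NULL_ALLELE_CODE)
    }
    names(f) <- codes
    out[[lname]] <- list(freq = f, n_copies = NA_integer_)
  }
  structure(out, class = "allele_freq_table")
}

#' Simulate founder adults under Hardy-Weinberg equilibrium
#'
#' @param spec A [pedigree_spec()].
#' @param seed Optional seed.
#' @param male_ids,female_ids Optional ID vectors overriding the defaults
#'   (`M01..`, `F01..`).
#' @return List with `table` (true founder genotypes, possibly carrying
#'   null alleles), `freqs` (truth frequencies), `sex` (named vector).
#' @export
simulate_founders <- function(spec, seed = NULL, male_ids = NULL, female_ids = NULL) {
  with_seed(seed, {
    freqs <- simulate_locus_freqs(spec)
    male_ids <- male_ids %||% paste0("M", formatC(seq_len(spec$n_founder_males), width = 2, flag = "0"))
    female_ids <- female_ids %||% paste0("F", formatC(seq_len(spec$n_founder_females), width = 2, flag = "0"))
    ids <- c(male_ids, female_ids)
    n <- length(ids)
    loci <- names(freqs)
    a1 <- a2 <- matrix(NA_integer_, n, length(loci))
    for (l in seq_along(loci)) {
      f <- freqs[[l]]$freq
      codes <- as.integer(names(f))
      a1[, l] <- sample(codes, n, replace = TRUE, prob = as.numeric(f))
      a2[, l] <- sample(codes, n, replace = TRUE, prob = as.numeric(f))
    }
    tab <- genotype_table(ids, loci, a1, a2)
    sex <- stats::setNames(c(rep("M", length(male_ids)), rep("F", length(female_ids))), ids)
    list(table = tab, freqs = freqs, sex = sex)
  })
}

# One Mendelian offspring from two parent rows of a genotype table.
gene_drop <- function(table, mother, father) {
  im <- match(mother, table$ids); ip <- match(father, table$ids)
  L <- length(table$loci)
  from_m <- ifelse(stats::runif(L) < 0.5, table$a1[im, ], table$a2[im, ])
  from_f <- ifelse(stats::runif(L) < 0.5, table$a1[ip, ], table$a2[ip, ])
  list(a1 = pmin(from_m, from_f), a2 = pmax(from_m, from_f))
}

#' Simulate a multi-year breeding pedigree
#'
#' Each year, cycle-eligible females breed with probability
#' `female_breed_prob`, producing one litter with a drawn size and sire
#' count; sires are drawn by skew-weighted sampling without replacement and
#' every sire of a litter fathers at least one pup. Offspring genotypes are
#' produced by Mendelian gene dropping; nurseries follow female site
#' fidelity.
#'
#' @param spec A [pedigree_spec()].
#' @param founders Output of [simulate_founders()].
#' @param seed Optional seed.
#' @return A truth set: list with `pedigree` (data.frame `id`, `mother`,
#'   `father`, `cohort_year`, `site`, `sex`), `genotypes` (true genotypes of
#'   founders and offspring), `freqs`, `sampled` (named logical vector),
#'   `spec`, `male_weights`.
#' @export
simulate_pedigree <- function(spec, founders, seed = NULL) {
  with_seed(seed, {
    sex <- founders$sex
    males <- names(sex)[sex == "M"]; females <- names(sex)[sex == "F"]
    if (length(males) == 0L) stop_kinnet("no founder males")
    w <- stats::rgamma(length(males), shape = spec$male_skew)
    w <- w / sum(w)
    home <- stats::setNames(sample(spec$nursery_sites, length(females), replace = TRUE),
                            females)
    last_breed <- stats::setNames(rep(-Inf, length(females)), females)
    years <- spec$start_year + seq_len(spec$n_breeding_years) - 1L
    ped <- list()
    offspring <- list()
    counter <- 0L
    tab <- founders$table
    for (y in years) {
      eligible <- vapply(females, function(fm) {
        ok <- switch(spec$female_cycle,
                     annual = TRUE,
                     biennial = (y - last_breed[fm]) >= 2,
                     mixed = (y - last_breed[fm]) >= 2 ||
                       stats::runif(1) < spec$cycle_exception_prob)
        ok
      }, TRUE)
      breeding <- females[eligible & stats::runif(length(females)) < spec$female_breed_prob]
      for (fm in breeding) {
        size <- sample.int(13L, 1L, prob = spec$litter_size_probs)
        n_sires <- min(size, sample.int(length(spec$sires_per_litter_probs), 1L,
                                        prob = spec$sires_per_litter_probs))
        n_sires <- min(n_sires, length(males))
        sires <- sample(males, n_sires, prob = w)
        # every sire gets at least one pup
        pup_sires <- c(sires, sample(sires, size - n_sires, replace = TRUE))
        pup_sires <- sample(pup_sires)
        site <- if (stats::runif(1) < spec$site_fidelity || length(spec$nursery_sites) == 1L)
          home[fm] else sample(setdiff(spec$nursery_sites, home[fm]), 1L)
        for (s in pup_sires) {
          counter <- counter + 1L
          oid <- paste0("J", formatC(counter, width = 3, flag = "0"))
          g <- gene_drop(tab, fm, s)
          offspring[[oid]] <- g
          ped[[oid]] <- data.frame(id = oid, mother = fm, father = s,
                                   cohort_year = y, site = unname(site),
                                   sex = sample(c("M", "F"), 1L),
                                   stringsAsFactors = FALSE)
        }
        last_breed[fm] <- y
      }
      if (length(breeding) == 0L) next
    }
    ped <- if (length(ped)) do.call(rbind, ped) else
      data.frame(id = character(0), mother = character(0), father = character(0),
                 cohort_year = integer(0), site = character(0), sex = character(0))
    rownames(ped) <- NULL
    all_ids <- c(tab$ids, ped$id)
    a1 <- rbind(tab$a1, do.call(rbind, lapply(offspring, `[[`, "a1")))
    a2 <- rbind(tab$a2, do.call(rbind, lapply(offspring, `[[`, "a2")))
    geno <- genotype_table(all_ids, tab$loci, a1, a2)
    sampled <- c(stats::runif(length(tab$ids)) < spec$adult_sampling_fraction,
                 stats::runif(nrow(ped)) < spec$juvenile_sampling_fraction)
    names(sampled) <- all_ids
    list(pedigree = ped, genotypes = geno, freqs = founders$freqs,
         sex = c(sex, stats::setNames(ped$sex, ped$id)),
         sampled = sampled, spec = spec,
         male_weights = stats::setNames(w, males))
  })
}

#' Apply the observation model to a truth set
#'
#' With probability `error_rate` an individual-locus genotype is replaced by
#' an independent HWE draw; heterozygotes carrying a null allele appear as
#' homozygotes for the visible allele and null homozygotes as missing;
#' additional calls go missing at `missing_rate`; only sampled individuals
#' are emitted. Metadata (sex, length, stage, group, site, cohort year) are
#' generated consistently with the pedigree.
#'
#' @param truth A truth set from [simulate_pedigree()].
#' @param spec A [pedigree_spec()] (defaults to the truth's).
#' @param seed Optional seed.
#' @return List with `table` (observed [genotype_table()]) and `meta`
#'   (data.frame as in [read_individual_meta()]).
#' @export
apply_observation_model <- function(truth, spec = truth$spec, seed = NULL) {
  with_seed(seed, {
    keep <- names(truth$sampled)[truth$sampled]
    tab <- subset_genotypes(truth$genotypes, ids = keep)
    n <- length(tab$ids); L <- length(tab$loci)
    a1 <- tab$a1; a2 <- tab$a2
    # genotyping error: replacement by an independent HWE draw
    if (spec$error_rate > 0) {
      err <- matrix(stats::runif(n * L) < spec$error_rate, n, L)
      for (l in seq_len(L)) {
        idx <- which(err[, l])
        if (!length(idx)) next
        f <- truth$freqs[[tab$loci[l]]]$freq
        codes <- as.integer(names(f))
        d1 <- sample(codes, length(idx), replace = TRUE, prob = as.numeric(f))
        d2 <- sample(codes, length(idx), replace = TRUE, prob = as.numeric(f))
        a1[idx, l] <- pmin(d1, d2); a2[idx, l] <- pmax(d1, d2)
      }
    }
    # null-allele masking
    null1 <- a1 == NULL_ALLELE_CODE; null2 <- a2 == NULL_ALLELE_CODE
    both <- null1 & null2
    a1[both] <- NA_integer_; a2[both] <- NA_integer_
    one2 <- !both & null2 & !null1          # canonical order puts null last
    a2[one2] <- a1[one2]
    one1 <- !both & null1 & !null2
    a1[one1] <- a2[one1]
    # missingness
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    }
    obs <- genotype_table(tab$ids, tab$loci, a1, a2)
    is_adult <- !(tab$ids %in% truth$pedigree$id)
    pid <- match(tab$ids, truth$pedigree$id)
    final_year <- spec$start_year + spec$n_breeding_years - 1L
    age <- ifelse(is_adult, NA_integer_, final_year - truth$pedigree$cohort_year[pid])
    len <- ifelse(is_adult, stats::runif(n, 240, 310),
                  ifelse(age <= 0, stats::runif(n, 70, 99),
                         ifelse(age == 1, stats::runif(n, 100, 114),
                                ifelse(age == 2, stats::runif(n, 115, 129),
                                       stats::runif(n, 130, 199)))))
    meta <- data.frame(
      id = tab$ids,
      sex = unname(truth$sex[tab$ids]),
      total_length_cm = round(len, 1),
      stage = stage_from_length(len),
      group = ifelse(is_adult,
                     ifelse(seq_len(n) %% 2 == 0, "resident", "non-resident"),
                     "juvenile"),
      site = ifelse(is_adult, spec$nursery_sites[1], truth$pedigree$site[pid]),
      cohort_year = ifelse(is_adult, NA_integer_, truth$pedigree$cohort_year[pid]),
      stringsAsFactors = FALSE)
    list(table = obs, meta = meta)
  })
}

## ------------------------------------------------------- study fixture

# Deterministic litter plan emulating the study's reproductive output:
# 29 litters totalling 52 pups over 4 years, 21 mothers (4 sampled),
# 20 fathers (8 sampled), 9 multi-pup litters of which 7 are polyandrous,
# 10 fathers siring more than one litter, mostly biennial repeat mothers.
study_litter_plan <- function(start_year = 2006) {
  mothers <- c(paste0("F", formatC(1:4, width = 2, flag = "0")),
               paste0("UF", 1:17))
  fathers <- c(paste0("M", formatC(1:8, width = 2, flag = "0")),
               paste0("UM", 1:12))
  repeat_mothers <- mothers[1:8]             # F01 F02 F03 F04 UF1..UF4
  single_mothers <- mothers[9:21]
  yr <- function(k) start_year + k
  plan <- list()
  add <- function(mother, year, size) {
    plan[[length(plan) + 1L]] <<- list(mother = mother, year = year, size = size)
  }
  # biennial repeats (6 mothers), consecutive-year repeats (2 mothers)
  pairs <- list(c(0, 2), c(0, 2), c(0, 2), c(1, 3), c(1, 3), c(1, 3),
                c(2, 3), c(2, 3))
  for (i in seq_along(repeat_mothers)) {
    add(repeat_mothers[i], yr(pairs[[i]][1]), 1L)
    add(repeat_mothers[i], yr(pairs[[i]][2]), 1L)
  }
  for (i in seq_along(single_mothers)) {
    add(single_mothers[i], yr((i - 1L) %% 4L), 1L)
  }
  sizes <- c(4L, 4L, 4L, 4L, 4L, 4L, 3L, 3L, 2L, rep(1L, 20L))
  for (i in seq_along(plan)) plan[[i]]$size <- sizes[i]
  # sire counts: 7 of the 9 multi-pup litters polyandrous (2-3 sires)
  n_sires <- c(3L, 3L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, rep(1L, 20L))
  # father litter quotas: 10 fathers with >= 2 litters (sum 38 slots)
  quota <- stats::setNames(c(4L, 4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, rep(1L, 10L)),
                           fathers)
  for (i in order(-n_sires)) {
    take <- names(sort(quota, decreasing = TRUE))[seq_len(n_sires[i])]
    plan[[i]]$sires <- take
    quota[take] <- quota[take] - 1L
  }
  # nursery sites: most mothers pup in Moorea, some in Tetiaroa/Tahaa/Rangiroa
  home <- stats::setNames(rep("Moorea", 21), mothers)
  home[c("UF3", "UF5", "UF9", "UF13")] <- "Tetiaroa"
  home["UF15"] <- "Tahaa"; home["UF17"] <- "Rangiroa"
  for (i in seq_along(plan)) plan[[i]]$site <- unname(home[plan[[i]]$mother])
  list(plan = plan, mothers = mothers, fathers = fathers)
}

#' One-call study fixture with known pedigree truth
#'
#' Generates a synthetic dataset shaped like the study population: 33
#' sampled adults (13 males, 20 females, four of them from an outgroup site
#' that never breeds), 52 sampled juveniles over 4 cohorts and 4 nursery
#' sites, 41 true breeders of whom 12 are sampled, 16 loci of which 2 carry
#' planted null alleles (loci `LS15` and `Cli107`, null frequency 0.2),
#' a 1\% genotyping error rate and sparse missing data. Optionally writes
#' GenePop genotypes, a metadata CSV and a truth JSON.
#'
#' @param seed Integer seed; the same seed reproduces the files byte for
#'   byte.
#' @param dir Optional output directory (created if needed).
#' @return List with `table` (observed genotypes of sampled individuals),
#'   `meta`, `truth` (list: `pedigree`, `breeders`, `sampled_breeders`,
#'   `null_loci`, `litters`), `genotypes_true`, `freqs_true`, and `files`
#'   (paths, when `dir` is given).
#' @export
make_study_fixture <- function(seed = 1, dir = NULL) {
  plan <- study_litter_plan()
  # adult pool: 13 sampled males + 12 unsampled, 16+4 sampled females + 17 unsampled
  male_ids <- c(paste0("M", formatC(1:13, width = 2, flag = "0")), paste0("UM", 1:12))
  female_ids <- c(paste0("F", formatC(1:16, width = 2, flag = "0")),
                  paste0("B", 1:4), paste0("UF", 1:17))
  spec <- pedigree_spec(n_founder_males = length(male_ids),
                        n_founder_females = length(female_ids),
                        n_breeding_years = 4, start_year = 2006,
                        n_loci = 16,
                        alleles_per_locus = c(3, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 9, 7, 8, 10),
                        error_rate = 0.01, missing_rate = 0.015,
                        null_allele_freq = c(Loc15 = 0.2, Loc16 = 0.2))
  with_seed(derive_seed(seed, "fixture"), {
    founders <- simulate_founders(spec, male_ids = male_ids, female_ids = female_ids)
    # rename the two null loci to their study-style labels
    loci <- names(founders$freqs)
    loci[15:16] <- c("LS15", "Cli107")
    names(founders$freqs) <- loci
    founders$table$loci <- loci
    colnames(founders$table$a1) <- colnames(founders$table$a2) <- loci
    tab <- founders$table
    ped <- list(); offspring_a1 <- list(); offspring_a2 <- list()
    counter <- 0L
    for (lt in plan$plan) {
      pup_sires <- c(lt$sires, sample(lt$sires, lt$size - length(lt$sires), replace = TRUE))
      pup_sires <- sample(pup_sires)
      for (s in pup_sires) {
        counter <- counter + 1L
        oid <- paste0("J", formatC(counter, width = 3, flag = "0"))
        g <- gene_drop(tab, lt$mother, s)
        offspring_a1[[oid]] <- g$a1; offspring_a2[[oid]] <- g$a2
        ped[[oid]] <- data.frame(id = oid, mother = lt$mother, father = s,
                                 cohort_year = lt$year, site = lt$site,
                                 sex = sample(c("M", "F"), 1L),
                                 stringsAsFactors = FALSE)
      }
    }
    ped <- do.call(rbind, ped); rownames(ped) <- NULL
    all_ids <- c(tab$ids, ped$id)
    geno <- genotype_table(all_ids, loci,
                           rbind(tab$a1, do.call(rbind, offspring_a1)),
                           rbind(tab$a2, do.call(rbind, offspring_a2)))
    sampled_adults <- c(paste0("M", formatC(1:13, width = 2, flag = "0")),
                        paste0("F", formatC(1:16, width = 2, flag = "0")),
                        paste0("B", 1:4))
    sampled <- stats::setNames(all_ids %in% c(sampled_adults, ped$id), all_ids)
    truth <- list(pedigree = ped, genotypes = geno, freqs = founders$freqs,
                  sex = c(founders$sex, stats::setNames(ped$sex, ped$id)),
                  sampled = sampled, spec = spec)
    obs <- apply_observation_model(truth, spec)
    # richer metadata for adults: residency groups and sites
    meta <- obs$meta
    is_b <- grepl("^B", meta$id)
    meta$group[is_b] <- "bora_bora"
    meta$site[is_b] <- "BoraBora"
    res <- meta$id %in% c(paste0("M", formatC(1:7, width = 2, flag = "0")),
                          paste0("F", formatC(1:7, width = 2, flag = "0")))
    meta$group[res] <- "resident"
    meta$group[!res & !is_b & is.na(meta$cohort_year)] <- "non-resident"
    breeders <- list(mothers = unique(ped$mother), fathers = unique(ped$father))
    truth_out <- list(
      version = "1.0",
      pedigree = ped,
      breeders = breeders,
      n_breeders = length(breeders$mothers) + length(breeders$fathers),
      sampled_breeders = list(
        mothers = intersect(breeders$mothers, sampled_adults),
        fathers = intersect(breeders$fathers, sampled_adults)),
      null_loci = c("LS15", "Cli107"),
      litters = do.call(rbind, lapply(plan$plan, function(lt)
        data.frame(mother = lt$mother, year = lt$year, size = lt$size,
                   n_sires = length(lt$sires),
                   sires = paste(lt$sires, collapse = ";"),
                   site = lt$site, stringsAsFactors = FALSE))))
    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- list(genotypes = file.path(dir, "genotypes.gen"),
                    meta = file.path(dir, "meta.csv"),
                    truth = file.path(dir, "truth.json"))
      write_genotypes(obs$table, files$genotypes, format = "genepop",
                      title = "synthetic study fixture")
      utils::write.csv(meta, files$meta, row.names = FALSE, quote = FALSE)
      jsonlite::write_json(truth_out, files$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(table = obs$table, meta = meta, truth = truth_out,
         genotypes_true = geno, freqs_true = founders$freqs, files = files)
  })
}
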