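#' Genotype tables for codominant diploid markers
#'
#' A `genotype_table` stores one unordered diploid genotype per individual and
#' locus. Alleles are positive integer codes (for microsatellites, typically
#' fragment sizes); a cell is either fully typed (two alleles) or fully
#' missing. Pairs are stored canonically with the smaller code first.
#'
#' @param ids Character vector of unique individual identifiers.
#' @param loci Character vector of unique locus names.
#' @param a1,a2 Integer matrices (`length(ids)` x `length(loci)`) holding the
#'   two allele codes; `NA` in both marks a missing call. Rows and columns are
#'   matched positionally to `ids` and `loci`.
#' @return An object of class `genotype_table` with fields `ids`, `loci`,
#'   `a1`, `a2`.
#' @examples
#' gt <- genotype_table(c("i1", "i2"), "L1",
#'                      a1 = matrix(c(1L, NA), 2, 1),
#'                      a2 = matrix(c(2L, NA), 2, 1))
#' n_typed(gt)
#' @export
genotype_table <- function(ids, loci, a1, a2) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop_kinnet("duplicate individual IDs: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(loci)) stop_kinnet("duplicate locus names")
  a1 <- matrix(as.integer(a1), nrow = length(ids), ncol = length(loci))
  a2 <- matrix(as.integer(a2), nrow = length(ids), ncol = length(loci))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop_kinnet("half-called genotypes are not allowed (a cell must be fully typed or fully missing)")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop_kinnet("allele codes must be positive integers")
  # canonical order: smaller allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x", length(x$loci), "loci;",
      sum(!is.na(x$a1)), "typed calls,", sum(is.na(x$a1)), "missing\n")
  invisible(x)
}

#' Number of typed calls per locus
#' @param table A `genotype_table`.
#' @return Named integer vector of typed individuals per locus.
#' @export
n_typed <- function(table) {
  colSums(!is.na(table$a1))
}

#' Subset a genotype table
#'
#' @param table A `genotype_table`.
#' @param ids,loci Character vectors naming the individuals / loci to keep
#'   (default: all). Order follows the arguments.
#' @return A new `genotype_table`; the original is untouched.
#' @export
subset_genotypes <- function(table, ids = table$ids, loci = table$loci) {
  ids <- as.character(ids); loci <- as.character(loci)
  if (!all(ids %in% table$ids)) stop_kinnet("unknown individual ID(s): ",
    paste(setdiff(ids, table$ids), collapse = ", "))
  if (!all(loci %in% table$loci)) stop_kinnet("unknown locus name(s): ",
    paste(setdiff(loci, table$loci), collapse = ", "))
  genotype_table(ids, loci,
                 table$a1[ids, loci, drop = FALSE],
                 table$a2[ids, loci, drop = FALSE])
}

#' Drop flagged loci from a genotype table
#'
#' Used after marker QC to remove loci with evidence of null alleles or other
#' artefacts before relatedness and parentage analyses.
#'
#' @param table A `genotype_table`.
#' @param flags Character vector of locus names to drop.
#' @return The table restricted to the unflagged loci.
#' @export
filter_loci <- function(table, flags) {
  flags <- as.character(flags)
  if (!all(flags %in% table$loci))
    stop_kinnet("unknown locus name(s): ", paste(setdiff(flags, table$loci), collapse = ", "))
  keep <- setdiff(table$loci, flags)
  if (length(keep) == 0L) {
    warning("all loci removed; returning an empty table")
    return(genotype_table(table$ids, character(0),
                          matrix(NA_integer_, length(table$ids), 0),
                          matrix(NA_integer_, length(table$ids), 0)))
  }
  subset_genotypes(table, loci = keep)
}

## ---------------------------------------------------------------- file I/O

#' Read a genotype file
#'
#' Supports the GenePop dialect (title line, one locus name per line or a
#' single comma-separated line, `Pop` separators, then `id ,  0102 0304 ...`
#' rows with 2- or 3-digit allele codes, `00`/`000` meaning missing) and a
#' CSV dialect with one row per individual and two columns per locus named
#' `<locus>.1` / `<locus>.2` (empty cells = missing).
#'
#' @param path Path to the file.
#' @param format `"genepop"` or `"csv"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("genepop", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_kinnet("file not found: ", path)
  switch(format,
         genepop = read_genepop(path),
         csv = read_genotypes_csv(path))
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_kinnet("GenePop file too short: ", path)
  body <- lines[-1]                        # drop title
  is_pop <- toupper(trimws(body)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop_kinnet("GenePop file has no 'Pop' line: ", path)
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  ind_lines <- body[-seq_len(first_pop)]
  ind_lines <- ind_lines[!(toupper(trimws(ind_lines)) %in% "POP")]
  ind_lines <- ind_lines[nzchar(trimws(ind_lines))]
  n <- length(ind_lines)
  ids <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    line_no <- which(lines == ind_lines[i])[1]
    parts <- strsplit(ind_lines[i], ",")[[1]]
    if (length(parts) < 2L)
      stop_kinnet("line ", line_no, ": expected 'id , genotypes'")
    ids[i] <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(toks) != length(loci))
      stop_kinnet("line ", line_no, ": expected ", length(loci),
                  " genotypes, found ", length(toks))
    for (l in seq_along(toks)) {
      tok <- toks[l]
      w <- nchar(tok)
      if (!(w %in% c(4L, 6L)) || grepl("[^0-9]", tok))
        stop_kinnet("line ", line_no, ": malformed genotype '", tok, "'")
      half <- w / 2L
      x <- as.integer(substr(tok, 1L, half))
      y <- as.integer(substr(tok, half + 1L, w))
      if (x == 0L && y == 0L) next                      # missing
      if (x == 0L || y == 0L)
        stop_kinnet("line ", line_no, ": half-called genotype '", tok, "'")
      a1[i, l] <- x; a2[i, l] <- y
    }
  }
  if (anyDuplicated(ids))
    stop_kinnet("duplicate individual IDs in ", path, ": ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genotype_table(ids, loci, a1, a2)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"id" %in% names(df)) stop_kinnet("CSV genotype file must have an 'id' column")
  gcols <- setdiff(names(df), "id")
  m <- regmatches(gcols, regexec("^(.*)\\.([12])$", gcols))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop_kinnet("genotype columns must be named <locus>.1/<locus>.2; bad: ",
                            paste(gcols[bad], collapse = ", "))
  locus_of <- vapply(m, `[[`, "", 2L)
  which_a <- vapply(m, `[[`, "", 3L)
  loci <- unique(locus_of)
  for (lc in loci) {
    if (!all(c("1", "2") %in% which_a[locus_of == lc]))
      stop_kinnet("locus ", lc, " lacks one of its two allele columns")
  }
  n <- nrow(df)
  to_int <- function(v) {
    v <- trimws(v); v[!nzchar(v)] <- NA
    suppressWarnings(as.integer(v))
  }
  a1 <- sapply(loci, function(lc) to_int(df[[paste0(lc, ".1")]]))
  a2 <- sapply(loci, function(lc) to_int(df[[paste0(lc, ".2")]]))
  a1 <- matrix(a1, nrow = n); a2 <- matrix(a2, nrow = n)
  genotype_table(df$id, loci, a1, a2)
}

#' Write a genotype table
#'
#' @param table A `genotype_table`.
#' @param path Output path.
#' @param format `"genepop"` (3-digit codes) or `"csv"`.
#' @param title Title line for the GenePop dialect.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path, format = c("genepop", "csv"),
                            title = "kinnet genotypes") {
  format <- match.arg(format)
  if (format == "genepop") {
    enc <- function(a) ifelse(is.na(a), "000", formatC(a, width = 3, flag = "0"))
    rows <- vapply(seq_along(table$ids), function(i) {
      paste0(table$ids[i], " ,  ",
             paste0(enc(table$a1[i, ]), enc(table$a2[i, ]), collapse = " "))
    }, "")
    writeLines(c(title, table$loci, "Pop", rows), path)
  } else {
    cols <- list(id = table$ids)
    for (l in seq_along(table$loci)) {
      cols[[paste0(table$loci[l], ".1")]] <- ifelse(is.na(table$a1[, l]), "", table$a1[, l])
      cols[[paste0(table$loci[l], ".2")]] <- ifelse(is.na(table$a2[, l]), "", table$a2[, l])
    }
    utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

## ------------------------------------------------------------- metadata

#' Stage classification from total length
#'
#' Juveniles are below 100 cm total length, immature animals 100-199 cm and
#' mature animals 200 cm and above.
#'
#' @param total_length_cm Numeric vector of body lengths (cm).
#' @return Character vector in `{"juvenile","immature","mature"}`.
#' @export
stage_from_length <- function(total_length_cm) {
  ifelse(is.na(total_length_cm), NA_character_,
         ifelse(total_length_cm < 100, "juvenile",
                ifelse(total_length_cm < 200, "immature", "mature")))
}

#' Read an individual-metadata table
#'
#' Expects columns `id`, `sex` (M/F/unknown), `total_length_cm`, `stage`
#' (juvenile/immature/mature), `group`, `site`, `cohort_year`. Stage and
#' length are cross-checked against the [stage_from_length()] thresholds.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with one row per individual.
#' @export
read_individual_meta <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_individual_meta(df)
}

#' Validate an individual-metadata table
#' @param df A data.frame with the columns described in [read_individual_meta()].
#' @return The validated data.frame.
#' @export
validate_individual_meta <- function(df) {
  need <- c("id", "sex", "total_length_cm", "stage", "group", "site", "cohort_year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_kinnet("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop_kinnet("duplicate individual IDs in metadata")
  df$sex[is.na(df$sex) | !nzchar(as.character(df$sex))] <- "unknown"
  if (!all(df$sex %in% c("M", "F", "unknown")))
    stop_kinnet("sex must be one of M, F, unknown")
  ok_stage <- is.na(df$stage) | df$stage %in% c("juvenile", "immature", "mature")
  if (!all(ok_stage)) stop_kinnet("stage must be juvenile, immature or mature")
  both <- !is.na(df$stage) & !is.na(df$total_length_cm)
  bad <- both & df$stage != stage_from_length(df$total_length_cm)
  if (any(bad))
    stop_kinnet("stage inconsistent with total length for: ",
                paste(df$id[bad], collapse = ", "))
  df
}
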