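## First-order genetic network: nodes are individuals, edges connect dyads
## whose best relationship category is PO, FS or HS, weighted by r_hat.

FIRST_ORDER <- c("PO", "FS", "HS")

#' Build the first-order genetic network
#'
#' One node per individual (isolated nodes are kept), one edge per dyad whose
#' best category is PO, FS or HS; edge weight is the dyad's `r_hat` and the
#' category is stored as an edge attribute. Node attributes come from the
#' metadata table.
#'
#' @param dyads Dyad data.frame as produced by [relatedness_matrix()]
#'   (columns `id_a`, `id_b`, `r_hat`, `best_category`).
#' @param meta Individual metadata data.frame (see [read_individual_meta()]);
#'   every dyad member must appear in `meta$id`.
#' @return An [igraph::graph] with vertex attributes `sex`,
#'   `total_length_cm`, `stage`, `group`, `site` and edge attributes
#'   `weight`, `category`.
#' @export
build_network <- function(dyads, meta) {
  ids <- as.character(meta$id)
  unknown <- setdiff(unique(c(dyads$id_a, dyads$id_b)), ids)
  if (length(unknown))
    stop_kinnet("dyads reference individuals absent from metadata: ",
                paste(unknown, collapse = ", "))
  e <- dyads[dyads$best_category %in% FIRST_ORDER, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$id_a, to = e$id_b,
                   weight = e$r_hat, category = e$best_category,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids,
                          sex = meta$sex,
                          total_length_cm = meta$total_length_cm,
                          stage = meta$stage,
                          group = meta$group,
                          site = meta$site,
                          stringsAsFactors = FALSE))
  g
}

#' Degree distribution of a genetic network
#'
#' Genetic degree is the number of first-order relationships an individual
#' has; isolated individuals count with degree 0.
#'
#' @param network An igraph network from [build_network()].
#' @return List with `degree` (named vector), `histogram` (table over degree
#'   values), `mean`, `sd`.
#' @export
degree_distribution <- function(network) {
  d <- igraph::degree(network)
  list(degree = d, histogram = table(d), mean = mean(d), sd = stats::sd(d))
}

#' Fraction of first-order dyads
#'
#' Share of pairwise relationships classified PO, FS or HS among the internal
#' pairs of a subset of individuals.
#'
#' @param dyads Dyad data.frame (as in [build_network()]).
#' @param ids Optional subset of individual IDs; default: all dyads.
#' @return A fraction in `[0, 1]`.
#' @export
first_order_fraction <- function(dyads, ids = NULL) {
  if (!is.null(ids)) {
    dyads <- dyads[dyads$id_a %in% ids & dyads$id_b %in% ids, , drop = FALSE]
  }
  if (nrow(dyads) == 0L) stop_kinnet("no dyads in the chosen subset")
  mean(dyads$best_category %in% FIRST_ORDER)
}

#' Permutation test of within- versus between-group relatedness
#'
#' Statistic: mean relatedness over within-group dyads minus mean over
#' between-group dyads. The null distribution is obtained by permuting group
#' labels over individuals; the two-sided p-value uses the add-one rule.
#' Groups with fewer than 2 members contribute no within-group dyads and are
#' dropped from the within mean with a warning (their members still enter
#' between-group dyads).
#'
#' @param r_matrix Symmetric relatedness matrix with individual IDs as
#'   dimnames (e.g. the `r` element of [relatedness_matrix()]).
#' @param groups Named character vector or factor of group labels, names =
#'   individual IDs (or unnamed, ordered as the matrix).
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @param exclude_group Optional group label whose members are removed before
#'   testing.
#' @param two_sided Two-sided (default) or one-sided (within > between) test.
#' @return List with `mean_within`, `mean_between`, `statistic`, `p`,
#'   `n_perm`.
#' @export
group_relatedness_test <- function(r_matrix, groups, n_perm = 20000,
                                   seed = NULL, exclude_group = NULL,
                                   two_sided = TRUE) {
  ids <- rownames(r_matrix)
  g <- as.character(groups)
  if (!is.null(names(groups))) g <- as.character(groups[ids])
  if (length(g) != nrow(r_matrix)) stop_kinnet("groups must cover every individual")
  if (anyNA(g)) stop_kinnet("missing group label")
  if (!is.null(exclude_group)) {
    keep <- g != exclude_group
    r_matrix <- r_matrix[keep, keep, drop = FALSE]
    g <- g[keep]
  }
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("group(s) with fewer than 2 members contribute no within-group dyads: ",
            paste(small, collapse = ", "))
  if (sum(sizes >= 2) < 2) stop_kinnet("need at least two groups with >= 2 members")
  ut <- which(upper.tri(r_matrix), arr.ind = TRUE)
  rv <- r_matrix[ut]
  ok <- !is.na(rv)
  ut <- ut[ok, , drop = FALSE]; rv <- rv[ok]
  stat_fun <- function(lab) {
    w <- lab[ut[, 1]] == lab[ut[, 2]]
    if (!any(w) || all(w)) return(0)
    mean(rv[w]) - mean(rv[!w])
  }
  w_obs <- g[ut[, 1]] == g[ut[, 2]]
  mean_within <- mean(rv[w_obs]); mean_between <- mean(rv[!w_obs])
  obs <- mean_within - mean_between
  p <- with_seed(seed, {
    b <- 0L
    for (i in seq_len(n_perm)) {
      s <- stat_fun(sample(g))
      hit <- if (two_sided) abs(s) >= abs(obs) - 1e-12 else s >= obs - 1e-12
      if (hit) b <- b + 1L
    }
    mc_pvalue(b, n_perm)
  })
  list(mean_within = mean_within, mean_between = mean_between,
       statistic = obs, p = p, n_perm = n_perm)
}

#' Export a genetic network
#'
#' GraphML keeps node and edge attributes; the edge-CSV format mirrors the
#' dyad table (`id_a`, `id_b`, `weight`, `category`). Either can be
#' re-imported with [import_network()].
#'
#' @param network An igraph network from [build_network()].
#' @param path Output file.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("id_a", "id_b")
    utils::write.csv(el, path, row.names = FALSE)
  }
  invisible(path)
}

#' Import a genetic network written by [export_network()]
#'
#' @param path Input file.
#' @param format `"graphml"` or `"edge_csv"`.
#' @param meta Metadata data.frame, required for `"edge_csv"` (the edge list
#'   does not carry isolated nodes or node attributes).
#' @return An igraph network.
#' @export
import_network <- function(path, format = c("graphml", "edge_csv"), meta = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  if (is.null(meta)) stop_kinnet("edge_csv import needs the metadata table")
  el <- utils::read.csv(path, stringsAsFactors = FALSE)
  el$best_category <- el$category
  el$r_hat <- el$weight
  build_network(el, meta)
}
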