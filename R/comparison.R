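# Network-similarity statistics with permutation-based significance.

# Align two networks on the union node set; missing dyads get weight 0.
align_networks <- function(a, b) {
  ids <- sort(union(a$nodes, b$nodes))
  expand <- function(net) {
    w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (length(net$nodes)) w[net$nodes, net$nodes] <- net$weights
    w
  }
  list(a = expand(a), b = expand(b), ids = ids)
}

edge_set <- function(w) {
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  paste(rownames(w)[up[, 1]], colnames(w)[up[, 2]], sep = "|")
}

jaccard <- function(sa, sb) {
  u <- length(union(sa, sb))
  if (u == 0) return(1)  # both empty: identical
  length(intersect(sa, sb)) / u
}

#' Jaccard similarity of edge sets
#'
#' Proportion of shared dyadic edges among all edges present in either
#' network (nodes aligned on the union set; an edge is any strictly
#' positive SRI weight). 1 for identical edge sets, 0 for disjoint ones;
#' two empty networks count as identical.
#'
#' @param a,b [social_network] objects.
#' @return Scalar in [0, 1].
#' @export
jaccard_edges <- function(a, b) {
  al <- align_networks(a, b)
  jaccard(edge_set(al$a), edge_set(al$b))
}

triangle_set <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected", diag = FALSE)
  tr <- igraph::triangles(g)
  if (!length(tr)) return(character())
  m <- matrix(igraph::V(g)$name[tr], ncol = 3, byrow = TRUE)
  apply(m, 1L, function(x) paste(sort(x), collapse = "|"))
}

#' Jaccard similarity of closed triangles
#'
#' Jaccard index over the sets of node triples forming closed triangles — a
#' measure of shared clustering between two networks on the union node set.
#'
#' @inheritParams jaccard_edges
#' @return Scalar in [0, 1].
#' @export
jaccard_triangles <- function(a, b) {
  al <- align_networks(a, b)
  jaccard(triangle_set(al$a), triangle_set(al$b))
}

offdiag <- function(w) w[row(w) != col(w)]

scale_offdiag <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stopf("zero-variance adjacency matrix; slope undefined")
  (v - mean(v)) / s
}

mrqap_coef <- function(wa, wb) {
  x <- scale_offdiag(offdiag(wa))
  y <- scale_offdiag(offdiag(wb))
  sum(x * y) / sum(x^2)  # OLS slope of y on x after standardisation
}

mantel_r <- function(wa, wb) {
  stats::cor(offdiag(wa), offdiag(wb))
}

#' Simple MRQAP regression between two networks
#'
#' Regresses the standardised off-diagonal of network `b` on that of
#' network `a` (nodes aligned on the union set, missing dyads 0, both
#' vectors scaled to mean 0 and SD 1, so the slope equals the Pearson
#' correlation of the dyadic weights). Significance by quadratic
#' assignment: the node labels of `a` are permuted jointly over rows and
#' columns, and the two-sided p-value is the proportion of permuted |slope|
#' at least as large as observed, with the (1 + k) / (1 + n_perm)
#' correction.
#'
#' @param a,b [social_network] objects.
#' @param n_perm number of node-label permutations.
#' @param seed integer seed for the permutation stream.
#' @return List with `coef`, `p`, `n_perm`.
#' @export
mrqap_simple <- function(a, b, n_perm = 1000, seed = 1) {
  al <- align_networks(a, b)
  obs <- mrqap_coef(al$a, al$b)
  n <- length(al$ids)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    mrqap_coef(al$a[p, p], al$b)
  }, numeric(1)))
  list(coef = obs, p = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm),
       n_perm = n_perm)
}

#' Mantel test between two networks
#'
#' Pearson correlation of the off-diagonal association weights, with
#' significance from node-label matrix permutations (one-sided: proportion
#' of permuted correlations at least as large as observed, with the
#' (1 + k) / (1 + n_perm) correction).
#'
#' @inheritParams mrqap_simple
#' @param n_perm number of matrix permutations (999 by convention).
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_networks <- function(a, b, n_perm = 999, seed = 1) {
  al <- align_networks(a, b)
  obs <- mantel_r(al$a, al$b)
  n <- length(al$ids)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    mantel_r(al$a[p, p], al$b)
  }, numeric(1)))
  list(r = obs, p = (1 + sum(null >= obs)) / (1 + n_perm), n_perm = n_perm)
}

#' Compare two networks under all similarity statistics
#'
#' @inheritParams mrqap_simple
#' @param n_perm permutations for MRQAP; the Mantel test uses
#'   `min(n_perm, 999)`.
#' @return A `comparison_result` list: `jaccard_edges`, `jaccard_triangles`,
#'   `mrqap_coef`, `mrqap_p`, `mantel_r`, `mantel_p`.
#' @export
compare_networks <- function(a, b, n_perm = 1000, seed = 1) {
  q <- mrqap_simple(a, b, n_perm, seed = derive_seed(seed, "mrqap"))
  m <- mantel_networks(a, b, min(n_perm, 999), seed = derive_seed(seed, "mantel"))
  structure(list(jaccard_edges = jaccard_edges(a, b),
                 jaccard_triangles = jaccard_triangles(a, b),
                 mrqap_coef = q$coef, mrqap_p = q$p,
                 mantel_r = m$r, mantel_p = m$p),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> Jaccard edges %.3f | triangles %.3f | MRQAP %.3f (p=%.3g) | Mantel r %.3f (p=%.3g)\n",
              x$jaccard_edges, x$jaccard_triangles, x$mrqap_coef, x$mrqap_p,
              x$mantel_r, x$mantel_p))
  invisible(x)
}

#' Pre-network permutation of a GBI
#'
#' Shuffles each individual's occurrence column independently across
#' grouping events, without replacement: every individual keeps its number
#' of group memberships (column sums preserved exactly) while group
#' composition is randomised (row sums generally change). This is the
#' null model for "random group membership given individual detectability".
#'
#' @param gbi a [gbi].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so the permutation loop advances one stream).
#' @return A permuted [gbi] (event table retained).
#' @export
permute_gbi <- function(gbi, seed = NULL) {
  stopifnot(inherits(gbi, "gbi"))
  doperm <- function() {
    inc <- gbi$incidence
    if (nrow(inc) > 1L)
      for (j in seq_len(ncol(inc))) inc[, j] <- inc[sample.int(nrow(inc)), j]
    out <- gbi
    out$incidence <- inc
    out$events$size <- rowSums(inc)
    out
  }
  if (is.null(seed)) doperm() else with_seed(seed, doperm())
}

#' Permutation null distribution for a network-similarity statistic
#'
#' For each replicate both GBIs are independently column-permuted
#' ([permute_gbi]), both SRI networks rebuilt (isolates pruned, as in the
#' observed pipeline), and the statistic recomputed, yielding the
#' distribution expected if individuals joined groups at random. The
#' one-sided empirical p is (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param gbi_a,gbi_b [gbi] objects (typically the same stream under two
#'   association definitions, or two periods under one definition).
#' @param statistic `"jaccard_edges"`, `"jaccard_triangles"`, `"mantel_r"`
#'   or `"mrqap_coef"` (the bare statistic; no inner permutation loop).
#' @param n_perm number of permuted replicates.
#' @param seed integer seed.
#' @return A `null_distribution` list: `statistic`, `observed`,
#'   `null_values`, `empirical_p`, `n_perm`.
#' @export
permutation_null <- function(gbi_a, gbi_b,
                             statistic = c("jaccard_edges", "jaccard_triangles",
                                           "mantel_r", "mrqap_coef"),
                             n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  # degenerate (edgeless) permuted networks have undefined correlation;
  # score them as similarity 0 so the null distribution stays well defined
  stat_fun <- switch(statistic,
    jaccard_edges = jaccard_edges,
    jaccard_triangles = jaccard_triangles,
    mantel_r = function(a, b) {
      al <- align_networks(a, b)
      r <- suppressWarnings(mantel_r(al$a, al$b))
      if (is.na(r)) 0 else r
    },
    mrqap_coef = function(a, b) {
      al <- align_networks(a, b)
      tryCatch(mrqap_coef(al$a, al$b), error = function(e) 0)
    })
  net <- function(g) prune_isolates(build_sri_network(g))
  observed <- stat_fun(net(gbi_a), net(gbi_b))
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(k)
    stat_fun(net(permute_gbi(gbi_a)), net(permute_gbi(gbi_b))), numeric(1)))
  structure(list(statistic = statistic, observed = observed,
                 null_values = null_values,
                 empirical_p = (1 + sum(null_values >= observed)) / (1 + n_perm),
                 n_perm = n_perm),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: observed %.3f vs null mean %.3f (p = %.4g, %d perms)\n",
              x$statistic, x$observed, mean(x$null_values), x$empirical_p, x$n_perm))
  invisible(x)
}
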