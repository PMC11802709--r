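test_that("Jaccard similarities match set-arithmetic oracles", {
  net <- random_network(6, p = 0.6, seed = 1)
  expect_equal(jaccard_edges(net, net), 1)
  expect_equal(jaccard_triangles(net, net), 1)

  wa <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  wb <- wa
  wa["A", "B"] <- wa["B", "A"] <- 0.5
  wb["C", "D"] <- wb["D", "C"] <- 0.5
  expect_equal(jaccard_edges(social_network(wa), social_network(wb)), 0)

  # triangle vs path on the same nodes shares no closed triple
  tri <- social_network((random_network(3, 1, 1)$weights > 0) * 0.5)
  pw <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  pw[1, 2] <- pw[2, 1] <- pw[2, 3] <- pw[3, 2] <- 0.5
  expect_equal(jaccard_triangles(tri, social_network(pw)), 0)

  empty <- social_network(matrix(numeric(), 0, 0))
  expect_equal(jaccard_edges(empty, empty), 1)

  for (seed in 1:15) {
    a <- random_network(7, p = 0.5, seed = seed)
    b <- random_network(7, p = 0.5, seed = seed + 500)
    ea <- apply(which(upper.tri(a$weights) & a$weights > 0, arr.ind = TRUE), 1,
                function(i) paste(sort(rownames(a$weights)[i]), collapse = "|"))
    eb <- apply(which(upper.tri(b$weights) & b$weights > 0, arr.ind = TRUE), 1,
                function(i) paste(sort(rownames(b$weights)[i]), collapse = "|"))
    expect_equal(jaccard_edges(a, b),
                 length(intersect(ea, eb)) / length(union(ea, eb)))
    expect_equal(jaccard_triangles(a, b),
                 {
                   ta <- oracle_triangles(a$weights); tb <- oracle_triangles(b$weights)
                   if (!length(union(ta, tb))) 1
                   else length(intersect(ta, tb)) / length(union(ta, tb))
                 })
    # symmetry in the arguments
    expect_equal(jaccard_edges(a, b), jaccard_edges(b, a))
    expect_equal(jaccard_triangles(a, b), jaccard_triangles(b, a))
  }
})

test_that("MRQAP slope is the dyadic correlation with QAP significance", {
  a <- random_network(8, p = 0.6, seed = 7)
  expect_equal(mrqap_simple(a, a, n_perm = 50, seed = 1)$coef, 1)
  flipped <- social_network(with(a, {
    w <- max(weights) - weights; diag(w) <- 0
    w[weights == 0] <- max(weights)  # strictly decreasing transform
    dimnames(w) <- dimnames(weights); w / max(w)
  }))
  expect_lt(mrqap_simple(a, flipped, n_perm = 50, seed = 1)$coef, 0)

  empty_var <- social_network(matrix(0.5 - diag(0.5, 3), 3, 3,
                                     dimnames = list(LETTERS[1:3], LETTERS[1:3])))
  expect_error(mrqap_simple(empty_var, empty_var, 10, 1), "zero-variance")

  # sampled p agrees with exhaustive node-permutation enumeration at n = 5
  a5 <- random_network(5, p = 0.7, seed = 21)
  b5 <- random_network(5, p = 0.7, seed = 22)
  q <- mrqap_simple(a5, b5, n_perm = 3000, seed = 9)
  od <- function(m) m[row(m) != col(m)]
  stat <- function(wa, wb) {
    x <- scale(od(wa))[, 1]; y <- scale(od(wb))[, 1]
    sum(x * y) / sum(x^2)
  }
  p_exh <- oracle_exhaustive_p(a5$weights, b5$weights, stat, two_sided = TRUE)
  expect_lt(abs(q$p - p_exh), 0.05)
})

test_that("Mantel test matches vegan and exhaustive enumeration", {
  a <- random_network(8, p = 0.6, seed = 3)
  b <- random_network(8, p = 0.6, seed = 4)
  m <- mantel_networks(a, b, n_perm = 999, seed = 5)
  expect_equal(mantel_networks(a, a, 99, 1)$r, 1)

  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(a$weights), as.dist(b$weights),
                      method = "pearson", permutations = 999)
  expect_equal(m$r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(m$p - vg$signif), 0.08)  # two Monte-Carlo estimates of one p

  a5 <- random_network(5, p = 0.7, seed = 31)
  b5 <- random_network(5, p = 0.7, seed = 32)
  od <- function(m_) m_[row(m_) != col(m_)]
  p_exh <- oracle_exhaustive_p(a5$weights, b5$weights,
                               function(wa, wb) cor(od(wa), od(wb)),
                               two_sided = FALSE)
  m5 <- mantel_networks(a5, b5, n_perm = 3000, seed = 11)
  expect_lt(abs(m5$p - p_exh), 0.05)
})

test_that("GBI permutation preserves column sums and randomises rows", {
  set.seed(2)
  sets <- replicate(10, sample(LETTERS[1:5], sample(1:3, 1)), simplify = FALSE)
  g <- gbi_from_sets(sets)
  for (seed in 1:20) {
    p <- permute_gbi(g, seed = seed)
    expect_equal(colSums(p$incidence), colSums(g$incidence))
  }
  single <- gbi_from_sets(list(c("A", "B")))
  expect_equal(permute_gbi(single, 1)$incidence, single$incidence)

  # marginal cell frequency over many permutations approaches the column mean
  freq <- Reduce(`+`, lapply(1:1000, function(s) permute_gbi(g, s)$incidence)) / 1000
  colmeans <- colMeans(g$incidence)
  for (j in seq_len(ncol(freq)))
    expect_true(all(abs(freq[, j] - colmeans[j]) < 4 * sqrt(colmeans[j] / 1000) + 0.06))
})

test_that("permutation_null bookkeeping and extremity behave as specified", {
  set.seed(6)
  sets <- replicate(14, sample(LETTERS[1:8], sample(2:4, 1)), simplify = FALSE)
  g <- gbi_from_sets(sets)
  nul <- permutation_null(g, g, "jaccard_edges", n_perm = 99, seed = 2)
  expect_equal(nul$observed, 1)  # identical GBIs
  expect_length(nul$null_values, 99L)
  expect_gte(nul$empirical_p, 1 / (1 + 99))
  expect_lte(nul$empirical_p, 1)
  expect_equal(nul$empirical_p,
               (1 + sum(nul$null_values >= nul$observed)) / (1 + nul$n_perm))
})

test_that("structured data beats its permutation null", {
  ws <- well_separated_stream(seed = 1, n_visits = 14, n_ind = 15)
  g_win <- detect_groups_window(ws$stream, association_params(1))
  g_arr <- detect_groups_arrival(ws$stream, association_params(150, 300))
  nul <- permutation_null(g_win, g_arr, "mantel_r", n_perm = 200, seed = 4)
  expect_gte(mean(nul$observed > nul$null_values), 0.95)
})
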