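# Independent brute-force oracles and fixture builders. These deliberately
# use naive algorithms (union-find, exhaustive path enumeration, O(V^3)
# loops) so they share no code path with the implementation they check.

random_stream <- function(n = 40, n_ind = 8, span = 120, seed = 1,
                          n_loc = 1) {
  set.seed(seed)
  detection_stream(data.frame(
    time = round(runif(n, 0, span), 3),
    individual = sample(LETTERS[seq_len(n_ind)], n, replace = TRUE),
    antenna = "a1",
    location = sample(paste0("L", seq_len(n_loc)), n, replace = TRUE)))
}

stream_from <- function(times, inds, loc = "L1") {
  detection_stream(data.frame(time = times, individual = inds,
                              antenna = "a1", location = loc))
}

# union-find transitive closure of pairwise within-delta_t links,
# per location (single-day streams assumed)
oracle_window_groups <- function(stream, delta_t) {
  d <- as.data.frame(stream)
  out <- list()
  for (loc in unique(d$location)) {
    b <- d[d$location == loc, ]
    n <- nrow(b)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && abs(b$time[i] - b$time[j]) <= delta_t) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots))
      out[[length(out) + 1L]] <- sort(unique(b$individual[roots == r]))
  }
  out
}

member_sets <- function(gbi) {
  lapply(seq_len(nrow(gbi$incidence)), function(g)
    colnames(gbi$incidence)[gbi$incidence[g, ] == 1])
}

canon_groups <- function(sets) sort(vapply(sets, paste, character(1), collapse = "|"))

# exhaustive geodesic betweenness with edge cost 1/w, fractional splitting
oracle_betweenness <- function(w) {
  n <- nrow(w)
  btw <- stats::setNames(numeric(n), rownames(w))
  cost <- ifelse(w > 0, 1 / w, Inf)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path, c) {
      last <- path[length(path)]
      if (last == t) { paths[[length(paths) + 1L]] <<- list(path = path, cost = c); return() }
      for (nx in seq_len(n))
        if (is.finite(cost[last, nx]) && !(nx %in% path))
          walk(c(path, nx), c + cost[last, nx])
    }
    walk(s, 0)
    paths
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    ps <- all_paths(s, t)
    if (!length(ps)) next
    costs <- vapply(ps, `[[`, numeric(1), "cost")
    best <- min(costs)
    geo <- ps[costs <= best + 1e-9]
    for (g in geo) {
      inner <- setdiff(g$path, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(geo)
    }
  }
  btw
}

# O(V^3) triangle enumeration
oracle_triangles <- function(w) {
  n <- nrow(w)
  out <- character()
  if (n < 3) return(out)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (w[i, j] > 0 && w[j, k] > 0 && w[i, k] > 0)
      out <- c(out, paste(sort(rownames(w)[c(i, j, k)]), collapse = "|"))
  out
}

random_network <- function(n = 6, p = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) w[i, j] <- w[j, i] <- round(runif(1, 0.05, 1), 3)
  social_network(w)
}

gbi_from_sets <- function(sets, loc = "L1") {
  gbi_from_groups(lapply(seq_along(sets), function(k)
    list(location = loc, start = k, end = k + 0.5, members = sets[[k]])))
}

# exhaustive node-permutation p-values on tiny networks
oracle_exhaustive_p <- function(wa, wb, stat, two_sided) {
  n <- nrow(wa)
  perms <- gtools_permutations(n)
  od <- function(m) m[row(m) != col(m)]
  obs <- stat(wa, wb)
  vals <- apply(perms, 1L, function(p) stat(wa[p, p], wb))
  if (two_sided) mean(abs(vals) >= abs(obs) - 1e-12) else mean(vals >= obs - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# one-way ANOVA intraclass correlation on balanced data
oracle_anova_icc <- function(y, id) {
  k <- length(y) / length(unique(id))
  fit <- summary(stats::aov(y ~ factor(id)))[[1]]
  msb <- fit[["Mean Sq"]][1]; msw <- fit[["Mean Sq"]][2]
  max((msb - msw) / (msb + (k - 1) * msw), 0)
}

# well-separated regime: flock visits on a fixed grid (2500 s apart, so
# inter-visit silences dwarf every detector threshold), tight arrivals,
# no solo visits, perfect detection -- the regime in which all three
# association definitions must recover exactly the true visit groups.
# Returns the stream and the true member sets per visit.
well_separated_stream <- function(seed, n_visits = 8, n_ind = 15, n_units = 3) {
  set.seed(seed)
  ids <- sprintf("B%02d", seq_len(n_ind))
  unit <- rep(seq_len(n_units), length.out = n_ind)
  rows <- list(); truth <- list()
  for (v in seq_len(n_visits)) {
    u <- sample.int(n_units, 1)
    members <- ids[unit == u]
    members <- members[runif(length(members)) < 0.9]
    if (length(members) < 2) members <- ids[unit == u][1:2]
    t0 <- v * 2500
    for (m in members) {
      arr <- t0 + runif(1, 0, 10)
      rows[[length(rows) + 1L]] <- data.frame(
        time = seq(arr, arr + 30 + runif(1, 0, 20), by = 0.25),
        individual = m, antenna = "a1", location = "L1")
    }
    truth[[v]] <- sort(members)
  }
  list(stream = detection_stream(do.call(rbind, rows)), truth = truth)
}

# gregarious regime: heavily overlapping visits plus solo feeder use
gregarious_world <- function(seed, n_individuals = 30, n_units = 3, n_weeks = 1) {
  make_world(world_config(
    n_individuals = n_individuals, n_units = n_units, p_join = 0.8,
    sigma_social = 0.6, flock_rate = 2, solo_rate = 0.3,
    arrival_jitter_sd = 30, stay_mean = 20, read_interval = 0.25,
    p_read = 0.8, n_weeks = n_weeks, days_per_week = 1, hours_per_day = 4,
    seed = seed))
}
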