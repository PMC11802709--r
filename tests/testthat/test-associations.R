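test_that("time-window chain rule follows the A-B-C chaining contract", {
  s <- stream_from(c(0, 0.8, 1.5), c("A", "B", "C"))
  g <- detect_groups_window(s, association_params(1))
  expect_equal(member_sets(g), list(c("A", "B", "C")))  # C chains via B, not A

  g1 <- detect_groups_window(stream_from(5, "A"), association_params(1))
  expect_equal(member_sets(g1), list("A"))
  expect_equal(nrow(detect_groups_window(detection_stream(),
                                         association_params(1))$incidence), 0L)
})

test_that("time-window groups equal the union-find transitive closure", {
  for (seed in 1:30) {
    s <- random_stream(n = 50, n_ind = 7, span = 90, seed = seed, n_loc = 2)
    dt <- sample(c(0.5, 1, 3, 10), 1)
    g <- detect_groups_window(s, association_params(dt))
    expect_equal(canon_groups(member_sets(g)),
                 canon_groups(oracle_window_groups(s, dt)))
  }
})

test_that("grouping events never span locations or midnight", {
  ep <- as.POSIXct("2016-01-01 23:59:00", tz = "UTC")
  d <- data.frame(time = c(0, 30, 90), individual = c("A", "B", "C"),
                  antenna = "a1", location = "L1")
  s <- detection_stream(d, epoch = ep)
  g <- detect_groups_window(s, association_params(120))
  expect_length(member_sets(g), 2L)  # midnight falls between B and C
  s2 <- stream_from(c(0, 1, 2), c("A", "B", "C"), loc = c("L1", "L2", "L1"))
  g2 <- detect_groups_window(s2, association_params(5))
  expect_equal(canon_groups(member_sets(g2)), c("A|C", "B"))
})

test_that("arrival detection matches a linear gap-scan oracle", {
  # continuous presence: one arrival
  s <- stream_from(seq(0, 600, by = 0.25), "A")
  expect_equal(nrow(detect_arrivals(s, association_params(150, 300))), 1L)
  # absence beyond delta_i resets
  s2 <- stream_from(c(0, 400), c("A", "A"))
  expect_equal(nrow(detect_arrivals(s2, association_params(150, 300))), 2L)
  expect_equal(nrow(detect_arrivals(stream_from(c(0, 300), c("A", "A")),
                                    association_params(150, 300))), 1L)  # gap == delta_i

  for (seed in 1:20) {
    s <- random_stream(n = 60, n_ind = 5, span = 2000, seed = seed)
    di <- sample(c(50, 150, 300), 1)
    got <- detect_arrivals(s, association_params(150, di))
    d <- as.data.frame(s)
    want <- 0L
    for (id in unique(d$individual)) {
      t <- sort(d$time[d$individual == id])
      want <- want + 1L + sum(diff(t) > di)
    }
    expect_equal(nrow(got), want)
    expect_equal(got$time, sort(got$time))
  }
})

test_that("arrival grouping separates re-arrivals and lone late arrivals", {
  p <- association_params(150, 300)
  # A,B arrive together; B leaves, re-arrives with C much later -> two groups
  times <- c(seq(0, 30, 0.25),            # A present
             seq(100, 130, 0.25),         # B present
             seq(1000, 1030, 0.25),       # B back after > delta_i absence
             seq(1100, 1130, 0.25))       # C
  inds <- c(rep("A", 121), rep("B", 121), rep("B", 121), rep("C", 121))
  g <- detect_groups_arrival(stream_from(times, inds), p)
  expect_equal(canon_groups(member_sets(g)), c("A|B", "B|C"))

  # C arrives alone while A and B are still present -> singleton
  times2 <- c(seq(0, 2000, 0.25), seq(10, 2000, 0.25), seq(1000, 1500, 0.25))
  inds2 <- c(rep("A", 8001), rep("B", 7961), rep("C", 2001))
  g2 <- detect_groups_arrival(stream_from(times2, inds2), p)
  expect_equal(canon_groups(member_sets(g2)), c("A|B", "C"))

  expect_equal(nrow(detect_groups_arrival(detection_stream(), p)$incidence), 0L)
})

test_that("arrival detector with infinite delta_i gives one arrival per bird", {
  s <- random_stream(n = 80, n_ind = 6, span = 5000, seed = 4)
  a <- detect_arrivals(s, association_params(150, Inf))
  expect_equal(nrow(a), length(unique(s$individual)))
})

test_that("gathering-event detection recovers separated bursts", {
  set.seed(42)
  t1 <- sort(rnorm(50, 500, 30)); t2 <- sort(rnorm(50, 4100, 30))
  s <- stream_from(c(t1, t2) - min(t1),
                   c(rep(c("A", "B"), 25), rep(c("C", "D"), 25)))
  g <- detect_gathering_events(s)
  expect_equal(canon_groups(member_sets(g)), c("A|B", "C|D"))
  ev <- g$events
  expect_true(all(ev$start <= ev$end))

  # one burst -> one event with all individuals
  g1 <- detect_gathering_events(stream_from(sort(runif(60, 0, 120)),
                                            rep(c("A", "B", "C"), 20)))
  expect_equal(member_sets(g1), list(c("A", "B", "C")))

  # order independence of the input rows
  d <- as.data.frame(s)
  set.seed(7); d <- d[sample.int(nrow(d)), ]
  g2 <- detect_gathering_events(detection_stream(d))
  expect_equal(g2$incidence, g$incidence)

  # tiny block: single trivial event
  g3 <- detect_gathering_events(stream_from(3, "A"))
  expect_equal(member_sets(g3), list("A"))
})

test_that("gbi construction matches counting oracles", {
  g <- gbi_from_sets(list(c("A", "B"), c("B", "C")))
  expect_equal(dim(g$incidence), c(2L, 3L))
  expect_equal(unname(rowSums(g$incidence)), c(2, 2))
  expect_equal(nrow(gbi_from_groups(list())$incidence), 0L)

  set.seed(3)
  sets <- replicate(12, sample(LETTERS[1:6], sample(1:4, 1)), simplify = FALSE)
  g2 <- gbi_from_sets(sets)
  for (id in colnames(g2$incidence))
    expect_equal(sum(g2$incidence[, id]),
                 sum(vapply(sets, function(s) id %in% s, logical(1))))
  expect_equal(colnames(g2$incidence), sort(colnames(g2$incidence)))
})

test_that("gbi CSV round trip preserves incidence and events", {
  s <- random_stream(n = 60, n_ind = 6, span = 50, seed = 9)
  g <- detect_groups_window(s, association_params(2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_gbi(g, f)
  g2 <- read_gbi(f)
  expect_equal(g2$incidence, g$incidence)
  expect_equal(g2$events$start, g$events$start)
})

test_that("optional thinning collapses hardware repeat reads", {
  s <- stream_from(c(0, 0.25, 0.5, 5), c("A", "A", "A", "B"))
  g_raw <- detect_groups_window(s, association_params(1))
  g_thin <- detect_groups_window(s, association_params(1), thin_interval = 1)
  expect_equal(canon_groups(member_sets(g_raw)), c("A", "B"))
  expect_equal(canon_groups(member_sets(g_thin)), c("A", "B"))
  # continuous reads bridge a chain only when raw reads are kept
  s2 <- stream_from(c(0, 0.6, 1.2, 1.8, 2.4), c("A", "A", "A", "A", "B"))
  expect_equal(canon_groups(member_sets(detect_groups_window(s2, association_params(1)))),
               "A|B")
  expect_equal(canon_groups(member_sets(
    detect_groups_window(s2, association_params(1), thin_interval = 2))), c("A", "B"))
})
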