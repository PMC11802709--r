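#' Configuration for a synthetic flock-foraging world
#'
#' The simulator emulates the statistical structure that feeder-based
#' association inference assumes: latent social units whose members visit a
#' feeder together (fission-fusion flock visits with correlated arrival
#' times), a repeatable individual sociability trait on the logit scale,
#' non-social solo visits, and the read pattern of the feeder hardware.
#'
#' @param n_individuals number of PIT-tagged individuals.
#' @param n_units number of latent social units (flocks); must not exceed
#'   `n_individuals`.
#' @param p_join baseline probability that a unit member joins a given unit
#'   visit (modulated per individual by sociability on the logit scale).
#' @param sigma_social between-individual SD of the logit-scale sociability
#'   trait; the repeatable component of social phenotype.
#' @param flock_rate unit visits per hour (Poisson).
#' @param solo_rate non-social solo visits per individual per hour (Poisson).
#' @param arrival_jitter_sd SD (seconds) of the half-normal lag between a
#'   visit event and each joiner's arrival.
#' @param stay_mean mean stay duration in seconds (exponential).
#' @param read_interval hardware read interval in seconds (0.25 for open
#'   antennas, 0.5 for entry chambers and perch antennas).
#' @param p_read per-interval detection probability while present.
#' @param feeder feeder architecture: `"open"` (continuous presence reads),
#'   `"chamber"` (single-occupancy chamber; entry and exit reads only), or
#'   `"perches"` (k adjacent perch antennas, one location).
#' @param n_perches number of perch antennas when `feeder = "perches"`.
#' @param capacity maximum simultaneous occupants (`Inf` for open feeders;
#'   a chamber always serialises to 1).
#' @param n_weeks number of recording weeks.
#' @param days_per_week recording days per week (weekend-style blocks).
#' @param hours_per_day feeder-on hours per recording day.
#' @param background cross-unit baseline association weight.
#' @param seed master integer seed; every week derives its own RNG stream.
#' @return A `world_config` list.
#' @export
world_config <- function(n_individuals = 60, n_units = 6, p_join = 0.8,
                         sigma_social = 0.6, flock_rate = 0.5, solo_rate = 0.3,
                         arrival_jitter_sd = 30, stay_mean = 20,
                         read_interval = 0.25, p_read = 0.8,
                         feeder = c("open", "chamber", "perches"),
                         n_perches = 4, capacity = Inf,
                         n_weeks = 9, days_per_week = 2, hours_per_day = 8,
                         background = 0.01, seed = 42) {
  feeder <- match.arg(feeder)
  cfg <- list(n_individuals = as.integer(n_individuals), n_units = as.integer(n_units),
              p_join = p_join, sigma_social = sigma_social, flock_rate = flock_rate,
              solo_rate = solo_rate, arrival_jitter_sd = arrival_jitter_sd,
              stay_mean = stay_mean, read_interval = read_interval, p_read = p_read,
              feeder = feeder, n_perches = as.integer(n_perches),
              capacity = if (feeder == "chamber") 1 else capacity,
              n_weeks = as.integer(n_weeks), days_per_week = as.integer(days_per_week),
              hours_per_day = as.integer(hours_per_day),
              background = background, seed = as.integer(seed))
  probs <- c(p_join = cfg$p_join, p_read = cfg$p_read, background = cfg$background)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(c(cfg$flock_rate, cfg$solo_rate, cfg$arrival_jitter_sd, cfg$stay_mean) < 0))
    stopf("rates and scales must be >= 0")
  if (cfg$n_units > cfg$n_individuals) stopf("n_units must not exceed n_individuals")
  class(cfg) <- "world_config"
  cfg
}

#' Instantiate a synthetic world
#'
#' Assigns individuals to latent units, draws the repeatable sociability
#' trait, and records the ground-truth association structure. The true
#' association weight of a same-unit pair (i, j) is the probability that
#' both join a given unit visit, `q_i * q_j` with
#' `q_i = plogis(qlogis(p_join) + s_i)`; cross-unit pairs get the small
#' constant `background`.
#'
#' @param config a [world_config].
#' @return A `world` list: `config`, `individuals`, `memberships`,
#'   `sociability`, `true_association` (symmetric matrix, zero diagonal).
#' @export
make_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  ids <- sprintf("ID%03d", seq_len(config$n_individuals))
  with_seed(derive_seed(config$seed, "world"), {
    units <- rep(seq_len(config$n_units), length.out = config$n_individuals)
    units <- sample(units)
    soc <- stats::rnorm(config$n_individuals, 0, config$sigma_social)
  })
  names(units) <- names(soc) <- ids
  q <- stats::plogis(stats::qlogis(min(max(config$p_join, 1e-9), 1 - 1e-9)) + soc)
  A <- outer(q, q)
  same <- outer(units, units, "==")
  A[!same] <- config$background
  diag(A) <- 0
  A <- pmin(pmax(A, 0), 1)
  dimnames(A) <- list(ids, ids)
  structure(list(config = config, individuals = ids, memberships = units,
                 sociability = soc, true_association = A),
            class = "world")
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world> %d individuals in %d units, %s feeder, %d weeks (seed %d)\n",
              x$config$n_individuals, x$config$n_units, x$config$feeder,
              x$config$n_weeks, x$config$seed))
  invisible(x)
}

#' Ground-truth social network of a world
#'
#' @param world a [make_world] result.
#' @return A [social_network] whose weights are the true association
#'   probabilities (edges wherever the true weight is positive).
#' @export
true_network <- function(world) {
  stopifnot(inherits(world, "world"))
  social_network(world$true_association)
}

# Draw event times as a Poisson process over the week's feeder-on windows.
# Windows: days_per_week consecutive days, feeder on 06:00 for hours_per_day.
week_windows <- function(config, week) {
  day0 <- (week - 1L) * 7 * 86400
  starts <- day0 + (seq_len(config$days_per_week) - 1L) * 86400 + 6 * 3600
  cbind(start = starts, end = starts + config$hours_per_day * 3600)
}

poisson_times <- function(rate_per_hour, windows) {
  hours <- sum(windows[, "end"] - windows[, "start"]) / 3600
  n <- stats::rpois(1L, rate_per_hour * hours)
  if (n == 0L) return(numeric())
  u <- stats::runif(n, 0, hours) * 3600
  offs <- c(0, cumsum(windows[, "end"] - windows[, "start"]))
  w <- findInterval(u, offs, rightmost.closed = TRUE)
  sort(windows[w, "start"] + (u - offs[w]))
}

# Presence reads for one individual on an open/perch feeder.
presence_reads <- function(arrive, depart, config) {
  if (depart <= arrive) return(numeric())
  ticks <- seq(arrive, depart, by = config$read_interval)
  ticks[stats::runif(length(ticks)) < config$p_read]
}

#' Simulate one week of detections
#'
#' Flock visits arrive as a Poisson process per latent unit; each unit
#' member joins with probability `plogis(qlogis(p_join) + sociability)`,
#' arrives at the event time plus a half-normal jitter, and stays an
#' exponential time. Open and perch feeders emit presence reads every
#' `read_interval` seconds with probability `p_read`; chamber feeders
#' serialise entries (one bird inside at a time) and emit only an entry and
#' an exit read. Independent solo visits per individual model non-social
#' feeder use.
#'
#' @param world a [make_world] result.
#' @param week 1-based week index (`<= n_weeks`).
#' @return A [detection_stream] covering that week (times in seconds from
#'   the world epoch, so week 2 starts at 7 days).
#' @export
simulate_detections <- function(world, week = 1L) {
  stopifnot(inherits(world, "world"))
  cfg <- world$config
  if (week > cfg$n_weeks) stopf("week %d exceeds n_weeks = %d", week, cfg$n_weeks)
  ids <- world$individuals
  q <- stats::plogis(stats::qlogis(min(max(cfg$p_join, 1e-9), 1 - 1e-9)) + world$sociability)
  windows <- week_windows(cfg, week)
  antennas <- switch(cfg$feeder,
                     open = "A1", chamber = "A1",
                     perches = sprintf("P%d", seq_len(cfg$n_perches)))

  with_seed(derive_seed(cfg$seed, "week", week), {
    stays <- list()  # rows: individual, arrive, depart
    for (u in seq_len(cfg$n_units)) {
      members <- ids[world$memberships == u]
      for (ev in poisson_times(cfg$flock_rate, windows)) {
        join <- members[stats::runif(length(members)) < q[members]]
        if (!length(join)) next
        arr <- ev + abs(stats::rnorm(length(join), 0, cfg$arrival_jitter_sd))
        dur <- stats::rexp(length(join), 1 / cfg$stay_mean)
        stays[[length(stays) + 1L]] <-
          data.frame(individual = join, arrive = arr, depart = arr + dur)
      }
    }
    for (id in ids) {
      for (ev in poisson_times(cfg$solo_rate, windows)) {
        dur <- stats::rexp(1L, 1 / cfg$stay_mean)
        stays[[length(stays) + 1L]] <-
          data.frame(individual = id, arrive = ev, depart = ev + dur)
      }
    }
    if (!length(stays))
      return(detection_stream(metadata = list(week = week, feeder = cfg$feeder)))
    st <- do.call(rbind, stays)
    st <- st[order(st$arrive), , drop = FALSE]

    if (cfg$feeder == "chamber") {
      # single-occupancy queue: a bird enters when the chamber frees up,
      # occupies it for its stay, and is read at entry and exit only
      free_at <- 0
      rows <- vector("list", nrow(st))
      for (k in seq_len(nrow(st))) {
        entry <- max(st$arrive[k], free_at)
        exit <- entry + (st$depart[k] - st$arrive[k])
        free_at <- exit
        rows[[k]] <- data.frame(time = c(entry, exit),
                                individual = st$individual[k],
                                antenna = "A1", stringsAsFactors = FALSE)
      }
      d <- do.call(rbind, rows)
    } else {
      rows <- vector("list", nrow(st))
      for (k in seq_len(nrow(st))) {
        reads <- presence_reads(st$arrive[k], st$depart[k], cfg)
        if (!length(reads)) next
        ant <- if (length(antennas) == 1L) antennas
               else sample(antennas, 1L)  # the perch this bird lands on
        rows[[k]] <- data.frame(time = reads, individual = st$individual[k],
                                antenna = ant, stringsAsFactors = FALSE)
      }
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (!length(rows))
        return(detection_stream(metadata = list(week = week, feeder = cfg$feeder)))
      d <- do.call(rbind, rows)
    }
    d$location <- "F1"
    detection_stream(d, metadata = list(week = week, feeder = cfg$feeder,
                                        read_interval = cfg$read_interval))
  })
}

#' Simulate a panel of weekly detection streams
#'
#' One stream per week, independently drawn, sharing the same world (hence
#' the same unit memberships and sociability traits — the repeatable
#' component across weeks).
#'
#' @param world a [make_world] result.
#' @return List of [detection_stream], length `n_weeks`, named
#'   `week01, week02, ...`.
#' @export
simulate_weekly_panel <- function(world) {
  stopifnot(inherits(world, "world"))
  out <- lapply(seq_len(world$config$n_weeks), function(w) simulate_detections(world, w))
  names(out) <- sprintf("week%02d", seq_len(world$config$n_weeks))
  out
}
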