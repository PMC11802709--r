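#' Association parameters
#'
#' @param delta_t overlap / arrival threshold in seconds: detections (or
#'   arrivals) separated by at most `delta_t` chain into one grouping event.
#' @param delta_i inactivity threshold in seconds (arrival definition only):
#'   an individual is considered to have left a location after `delta_i`
#'   seconds without a read, so its next read is a fresh arrival.
#' @return An `association_params` list.
#' @export
association_params <- function(delta_t, delta_i = NULL) {
  if (delta_t <= 0) stopf("delta_t must be > 0")
  if (!is.null(delta_i) && delta_i <= 0) stopf("delta_i must be > 0")
  structure(list(delta_t = delta_t, delta_i = delta_i), class = "association_params")
}

# location x calendar-date blocks: all detectors operate within a block,
# so no grouping event spans locations or midnight.
stream_blocks <- function(stream, by_day = TRUE) {
  d <- as.data.frame(stream)
  if (!nrow(d)) return(list())
  key <- if (by_day)
    paste(d$location, format(attr(stream, "epoch") + d$time, "%Y-%m-%d"), sep = "|")
  else d$location
  split(d, key)
}

# Collapse same-individual repeat reads closer than `interval` seconds
# (optional pre-thinning; off by default so the raw stream feeds detection).
thin_reads <- function(block, interval) {
  keep <- unlist(lapply(split(seq_len(nrow(block)), block$individual), function(i) {
    t <- block$time[i]
    k <- logical(length(i))
    last <- -Inf
    for (j in seq_along(i)) {
      if (t[j] - last >= interval) { k[j] <- TRUE; last <- t[j] }
    }
    i[k]
  }))
  block[sort(keep), , drop = FALSE]
}

make_event <- function(location, start, end, members)
  list(location = location, start = start, end = end, members = sort(unique(members)))

#' Strict time-window grouping (chain rule)
#'
#' Implements the gambit-of-the-group chain rule on raw detections: within
#' each location-by-date block, time-sorted detections are split wherever
#' the gap between consecutive reads exceeds `delta_t`; each maximal chain
#' is one grouping event whose members are the individuals read in it. A
#' chain is exactly the transitive closure of pairwise
#' "within-`delta_t`" links, so A–B and B–C within `delta_t` connect A, B
#' and C into one group even if A and C never overlap directly.
#'
#' @param stream a [detection_stream].
#' @param params an [association_params] with `delta_t` set.
#' @param by_day split blocks at midnight (default TRUE).
#' @param thin_interval optional seconds; if set, same-individual repeat
#'   reads closer than this are collapsed before chaining.
#' @return A [gbi] (group-by-individual matrix).
#' @export
detect_groups_window <- function(stream, params, by_day = TRUE, thin_interval = NULL) {
  stopifnot(inherits(params, "association_params"))
  events <- list()
  for (block in stream_blocks(stream, by_day)) {
    if (!is.null(thin_interval)) block <- thin_reads(block, thin_interval)
    cut <- c(0L, which(diff(block$time) > params$delta_t), nrow(block))
    for (k in seq_len(length(cut) - 1L)) {
      i <- (cut[k] + 1L):cut[k + 1L]
      events[[length(events) + 1L]] <-
        make_event(block$location[1L], min(block$time[i]), max(block$time[i]),
                   block$individual[i])
    }
  }
  gbi_from_groups(events)
}

#' Detect arrival events
#'
#' Per individual and location, the first detection is an arrival; any later
#' detection separated from that individual's previous read at the location
#' by more than `delta_i` seconds of absence is a new arrival.
#'
#' @param stream a [detection_stream].
#' @param params an [association_params] with `delta_i` set.
#' @param by_day treat location-by-date blocks independently (default TRUE).
#' @return data.frame of arrival events (individual, location, time),
#'   sorted by time.
#' @export
detect_arrivals <- function(stream, params, by_day = TRUE) {
  stopifnot(inherits(params, "association_params"))
  if (is.null(params$delta_i)) stopf("arrival detection needs delta_i")
  rows <- list()
  for (block in stream_blocks(stream, by_day)) {
    for (i in split(seq_len(nrow(block)), block$individual)) {
      t <- block$time[i]
      new <- c(TRUE, diff(t) > params$delta_i)
      rows[[length(rows) + 1L]] <-
        data.frame(individual = block$individual[i[1L]],
                   location = block$location[1L],
                   time = t[new], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(individual = character(), location = character(),
                      time = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$time, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Arrival-time grouping
#'
#' Applies the chain rule to arrival events rather than raw reads: birds
#' arriving within `delta_t` of each other's arrivals form one group.
#' Because association is measured only at the point of arrival, a bird
#' arriving alone is a singleton even if earlier arrivals are still
#' physically present — the `delta_i` absence rule prevents the long chains
#' of connection that continuous presence would otherwise create.
#'
#' @inheritParams detect_arrivals
#' @param params an [association_params] with both `delta_t` and `delta_i`.
#' @return A [gbi].
#' @export
detect_groups_arrival <- function(stream, params, by_day = TRUE) {
  arr <- detect_arrivals(stream, params, by_day)
  events <- list()
  for (key in unique(arr$location)) {
    a <- arr[arr$location == key, , drop = FALSE]
    if (isTRUE(by_day)) {
      day <- format(attr(stream, "epoch") + a$time, "%Y-%m-%d")
      parts <- split(a, day)
    } else parts <- list(a)
    for (p in parts) {
      cut <- c(0L, which(diff(p$time) > params$delta_t), nrow(p))
      for (k in seq_len(length(cut) - 1L)) {
        i <- (cut[k] + 1L):cut[k + 1L]
        events[[length(events) + 1L]] <-
          make_event(p$location[1L], min(p$time[i]), max(p$time[i]), p$individual[i])
      }
    }
  }
  gbi_from_groups(events)
}

#' Gathering-event detection by Gaussian mixture
#'
#' Segments the detection times of each location-by-date block into
#' gathering events with a one-dimensional finite Gaussian mixture:
#' candidate component counts are scored by BIC, each detection is
#' hard-assigned to its maximum-responsibility component, and an event's
#' span is the min-max of its assigned times. Blocks are pre-split at long
#' silences (`pre_split_gap`) to bound the candidate range, and adjacent
#' components separated by less than `min_gap` seconds of silence are
#' merged: a gathering event must be bounded by genuine lulls in feeder
#' activity, not by the internal shape of one dense burst.
#'
#' @param stream a [detection_stream].
#' @param k_max maximum mixture components per segment (further capped at
#'   `ceiling(n/5)`).
#' @param pre_split_gap silence (seconds) at which a block is pre-split
#'   before mixture fitting (default 1800 s).
#' @param min_gap minimum silence (seconds) separating two events
#'   (default 30 s).
#' @param by_day split blocks at midnight (default TRUE).
#' @return A [gbi].
#' @export
detect_gathering_events <- function(stream, k_max = 25, pre_split_gap = 1800,
                                    min_gap = 30, by_day = TRUE) {
  events <- list()
  for (block in stream_blocks(stream, by_day)) {
    cut <- c(0L, which(diff(block$time) > pre_split_gap), nrow(block))
    for (k in seq_len(length(cut) - 1L)) {
      seg <- block[(cut[k] + 1L):cut[k + 1L], , drop = FALSE]
      for (ev in segment_events(seg$time, k_max, min_gap)) {
        events[[length(events) + 1L]] <-
          make_event(block$location[1L], min(seg$time[ev]), max(seg$time[ev]),
                     seg$individual[ev])
      }
    }
  }
  gbi_from_groups(events)
}

# Split one dense segment of times into events; returns a list of index
# vectors. Deterministic: mclust initialises EM from model-based
# hierarchical clustering (on a fixed subsample for large segments, with
# fitting on the subsample and responsibility-based assignment of all
# reads). If BIC saturates the candidate range the segment holds more
# events than the mixture can resolve, so it is split at its largest
# silence and each half re-fitted.
segment_events <- function(t, k_max, min_gap, depth = 0L) {
  n <- length(t)
  if (n < 2L || diff(range(t)) == 0) return(list(seq_len(n)))
  kmax <- max(1L, min(k_max, ceiling(n / 5)))
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this symbol in the caller scope
  sub <- if (n > 1500) with_seed(20160325, sort(sample.int(n, 1500))) else seq_len(n)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(t[sub], G = seq_len(min(kmax, length(sub) %/% 2L)),
                                    modelNames = c("E", "V"), verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # mixture non-convergence: fall back to a gap-based split at min_gap
    message("mixture fit failed for a segment of ", n, " reads; using gap-based split")
    cut <- c(0L, which(diff(t) > min_gap), n)
    return(lapply(seq_len(length(cut) - 1L), function(k) (cut[k] + 1L):cut[k + 1L]))
  }
  if (fit$G == kmax && kmax > 1L && depth < 20L) {
    gaps <- diff(t)
    at <- which.max(gaps)
    if (gaps[at] > 0) {
      left <- segment_events(t[1:at], k_max, min_gap, depth + 1L)
      right <- segment_events(t[(at + 1L):n], k_max, min_gap, depth + 1L)
      return(c(left, lapply(right, function(i) i + at)))
    }
  }
  grp <- if (n > 1500)
    suppressWarnings(stats::predict(fit, newdata = t)$classification)
  else fit$classification
  # order components by their time span and merge those not separated by
  # at least min_gap of silence
  comp <- split(seq_len(n), grp)
  comp <- comp[order(vapply(comp, function(i) min(t[i]), numeric(1)))]
  merged <- list(comp[[1L]])
  for (c in comp[-1L]) {
    prev <- merged[[length(merged)]]
    if (min(t[c]) - max(t[prev]) < min_gap)
      merged[[length(merged)]] <- c(prev, c)
    else merged[[length(merged) + 1L]] <- c
  }
  merged
}

#' Group-by-individual matrix
#'
#' The gambit-of-the-group intermediate: a binary incidence matrix with one
#' row per grouping event and one column per individual (columns in sorted
#' identifier order), plus the event table (location, start, end).
#'
#' @param groups list of grouping events, each a list with `location`,
#'   `start`, `end`, `members`.
#' @return A `gbi` object: `incidence` (0/1 matrix), `events` (data.frame).
#' @export
gbi_from_groups <- function(groups) {
  groups <- groups[order(vapply(groups, `[[`, numeric(1), "start"))]
  ids <- sort(unique(unlist(lapply(groups, `[[`, "members"))))
  inc <- matrix(0L, nrow = length(groups), ncol = length(ids),
                dimnames = list(NULL, ids))
  for (g in seq_along(groups)) inc[g, groups[[g]]$members] <- 1L
  events <- if (length(groups))
    data.frame(location = vapply(groups, `[[`, character(1), "location"),
               start = vapply(groups, `[[`, numeric(1), "start"),
               end = vapply(groups, `[[`, numeric(1), "end"),
               size = rowSums(inc), stringsAsFactors = FALSE)
  else data.frame(location = character(), start = numeric(), end = numeric(),
                  size = numeric(), stringsAsFactors = FALSE)
  structure(list(incidence = inc, events = events), class = "gbi")
}

#' @export
print.gbi <- function(x, ...) {
  cat(sprintf("<gbi> %d grouping events x %d individuals (mean group size %.2f)\n",
              nrow(x$incidence), ncol(x$incidence),
              if (nrow(x$incidence)) mean(rowSums(x$incidence)) else NA_real_))
  invisible(x)
}

#' Dispatch an association definition by name
#'
#' @param stream a [detection_stream].
#' @param method `"window"`, `"arrival"` or `"gmm"`.
#' @param params an [association_params] (ignored for `"gmm"`).
#' @param ... passed on to the specific detector.
#' @return A [gbi].
#' @export
detect_groups <- function(stream, method = c("window", "arrival", "gmm"),
                          params = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         window = detect_groups_window(stream, params, ...),
         arrival = detect_groups_arrival(stream, params, ...),
         gmm = detect_gathering_events(stream, ...))
}

#' Write / read a group-by-individual matrix as wide CSV
#'
#' Rows are grouping events (location, start, end columns first), followed
#' by one 0/1 column per individual.
#'
#' @param gbi a [gbi]. @param path file path.
#' @return `path` (write) or a [gbi] (read).
#' @export
write_gbi <- function(gbi, path) {
  out <- cbind(gbi$events[c("location", "start", "end")],
               as.data.frame(gbi$incidence, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gbi
#' @export
read_gbi <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idc <- setdiff(names(raw), c("location", "start", "end"))
  groups <- lapply(seq_len(nrow(raw)), function(g)
    make_event(raw$location[g], raw$start[g], raw$end[g],
               idc[raw[g, idc] == 1]))
  gbi_from_groups(groups)
}
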