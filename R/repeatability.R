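# Weekly metric panels, variance-component repeatability, and the
# time-window sensitivity sweep.

z_transform <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Weekly panel of individual network metrics
#'
#' For each weekly stream: detect grouping events under one association
#' definition, build the SRI network, prune degree-zero individuals, and
#' extract degree, strength and weighted betweenness. Metrics are
#' z-transformed within each (week, metric) cell to normalise across weeks
#' of different network size. Individuals absent (or pruned) in a week
#' contribute no row for that week.
#'
#' @param streams list of weekly [detection_stream] objects (names used as
#'   week labels; defaults to `week1, week2, ...`).
#' @param method association definition: `"window"`, `"arrival"` or `"gmm"`.
#' @param params an [association_params] (ignored for `"gmm"`).
#' @param ... further arguments to [detect_groups].
#' @return A `metric_panel` data.frame with columns `individual`, `week`,
#'   `definition`, `metric`, `value`, `z`.
#' @export
weekly_metric_panel <- function(streams, method = c("window", "arrival", "gmm"),
                                params = NULL, ...) {
  method <- match.arg(method)
  if (is.null(names(streams)) || any(!nzchar(names(streams))))
    names(streams) <- sprintf("week%d", seq_along(streams))
  rows <- list()
  for (wk in names(streams)) {
    net <- prune_isolates(build_sri_network(detect_groups(streams[[wk]], method, params, ...)))
    if (length(net$nodes) < 2L) {
      warning("week '", wk, "' has fewer than 2 connected individuals; skipped",
              call. = FALSE)
      next
    }
    m <- node_metrics(net)
    rows[[wk]] <- data.frame(
      individual = rep(m$individual, 3L),
      week = wk,
      definition = method,
      metric = rep(c("degree", "strength", "betweenness"), each = nrow(m)),
      value = c(m$degree, m$strength, m$betweenness),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    panel <- data.frame(individual = character(), week = character(),
                        definition = character(), metric = character(),
                        value = numeric(), z = numeric(), stringsAsFactors = FALSE)
  } else {
    panel <- do.call(rbind, rows)
    panel$z <- stats::ave(panel$value, panel$week, panel$metric, FUN = z_transform)
  }
  rownames(panel) <- NULL
  class(panel) <- c("metric_panel", "data.frame")
  panel
}

#' Repeatability of an individual network metric
#'
#' Fits the intercept-only random-effects model
#' `y = mu + alpha_i + epsilon` with individual identity as the random
#' intercept, by REML, and reports repeatability
#' `R = sigma^2_alpha / (sigma^2_alpha + sigma^2_epsilon)` — the proportion
#' of total variance attributable to consistent between-individual
#' differences. The 95% CI comes from a parametric bootstrap (simulate from
#' the fitted model, refit, take percentile quantiles of R). On balanced
#' data the REML point estimate coincides with the one-way ANOVA
#' intraclass correlation whenever the latter is positive.
#'
#' @param panel a [weekly_metric_panel] (or any data.frame with
#'   `individual`, `week`, `metric`, `definition`, `z` columns).
#' @param metric which metric (`"degree"`, `"strength"`, `"betweenness"`).
#' @param definition which association definition; `NULL` if the panel
#'   holds a single one.
#' @param response model the `z` (default) or raw `value` column.
#' @param n_boot parametric bootstrap replicates for the CI (0 skips the
#'   bootstrap and returns NA bounds when the bootstrap is in use).
#' @param ci_method `"auto"` (default) uses the exact F-pivot interval of
#'   the balanced one-way random model whenever the panel is balanced
#'   (every individual observed once in every week) and the parametric
#'   bootstrap otherwise; `"exact"` and `"boot"` force one method.
#' @param seed integer seed for the bootstrap.
#' @return A `repeatability` list: `metric`, `definition`, `R`, `ci_low`,
#'   `ci_high`, `band`, `n_individuals`, `n_weeks`, `n_boot`.
#' @export
estimate_repeatability <- function(panel, metric, definition = NULL,
                                   response = c("z", "value"),
                                   n_boot = 1000,
                                   ci_method = c("auto", "exact", "boot"),
                                   seed = 1) {
  response <- match.arg(response)
  ci_method <- match.arg(ci_method)
  d <- panel[panel$metric == metric, , drop = FALSE]
  if (!is.null(definition)) d <- d[d$definition == definition, , drop = FALSE]
  if (!nrow(d)) stopf("no rows for metric '%s'", metric)
  if (length(unique(d$week)) < 2L) stopf("repeatability needs >= 2 weeks")
  y <- d[[response]]
  if (stats::sd(y) == 0) stopf("response has zero total variance")
  dat <- data.frame(y = y, individual = factor(d$individual))

  rfrom <- function(fit) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    va <- vc$vcov[vc$grp == "individual"]
    ve <- vc$vcov[vc$grp == "Residual"]
    min(max(va / (va + ve), 0), 1)
  }
  fit <- lme4::lmer(y ~ 1 + (1 | individual), data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  R <- rfrom(fit)

  counts <- table(dat$individual, d$week)
  balanced <- all(counts == 1L)
  use_exact <- ci_method == "exact" || (ci_method == "auto" && balanced)
  if (ci_method == "exact" && !balanced)
    stopf("exact CI requires a balanced panel (one row per individual per week)")

  if (use_exact) {
    # exact F-pivot interval for the intraclass correlation of the
    # balanced one-way random model (Searle): F = MSB/MSW, df (n-1, n(k-1))
    n <- nlevels(dat$individual); k <- ncol(counts)
    gm <- tapply(dat$y, dat$individual, mean)
    msb <- k * stats::var(gm)
    msw <- sum((dat$y - gm[as.character(dat$individual)])^2) / (n * (k - 1))
    f0 <- msb / msw
    fl <- f0 / stats::qf(0.975, n - 1, n * (k - 1))
    fu <- f0 * stats::qf(0.975, n * (k - 1), n - 1)
    ci <- pmin(pmax(c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)), 0), 1)
  } else {
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      boot <- with_seed(seed, {
        sims <- stats::simulate(fit, nsim = n_boot)
        vapply(seq_len(n_boot), function(k) {
          rf <- tryCatch(suppressWarnings(suppressMessages(
            lme4::refit(fit, newresp = sims[[k]]))), error = function(e) NULL)
          if (is.null(rf)) NA_real_ else rfrom(rf)
        }, numeric(1))
      })
      ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    }
  }
  structure(list(metric = metric, definition = definition %||% unique(d$definition)[1],
                 R = R, ci_low = ci[1], ci_high = ci[2],
                 band = classify_repeatability(R),
                 n_individuals = nlevels(dat$individual),
                 n_weeks = length(unique(d$week)), n_boot = n_boot),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> %s (%s): R = %.3f [%.3f, %.3f] (%s; %d individuals x %d weeks)\n",
              x$metric, x$definition, x$R, x$ci_low, x$ci_high, x$band,
              x$n_individuals, x$n_weeks))
  invisible(x)
}

#' Band a repeatability estimate
#'
#' Conventional bands for behavioural repeatability: low below 0.3, medium
#' from 0.3 to 0.5 (boundaries inclusive), high above 0.5.
#'
#' @param R repeatability in [0, 1] (vectorised).
#' @return Character vector in `c("low", "medium", "high")`.
#' @export
classify_repeatability <- function(R) {
  ifelse(R < 0.3, "low", ifelse(R <= 0.5, "medium", "high"))
}

#' Cross-definition regression of a network metric
#'
#' OLS of the within-week z-scored metric under definition B on the same
#' individuals' z-scores under definition A, pairing rows on (individual,
#' week). Quantifies how well one association definition's individual
#' network positions predict another's.
#'
#' @param panel a combined [weekly_metric_panel] holding both definitions
#'   (rbind of per-definition panels).
#' @param metric which metric.
#' @param def_a,def_b definition labels (x and y sides).
#' @return List with `slope`, `intercept`, `p` (two-sided slope p-value),
#'   `n` (matched rows).
#' @export
cross_definition_regression <- function(panel, metric, def_a, def_b) {
  a <- panel[panel$metric == metric & panel$definition == def_a, ]
  b <- panel[panel$metric == metric & panel$definition == def_b, ]
  m <- merge(a[c("individual", "week", "z")], b[c("individual", "week", "z")],
             by = c("individual", "week"), suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stopf("fewer than 3 matched (individual, week) rows")
  fit <- stats::lm(z_b ~ z_a, data = m)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["z_a", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p = unname(cf["z_a", "Pr(>|t|)"]), n = nrow(m))
}

#' Sensitivity of repeatability to the time-window parameter
#'
#' Recomputes weekly panels and repeatability across a grid of `delta_t`
#' values for the window or arrival definition (the inactivity threshold
#' `delta_i` is held fixed for the arrival method, 300 s by default).
#'
#' @param streams list of weekly [detection_stream] objects.
#' @param method `"window"` or `"arrival"`.
#' @param delta_t_grid numeric vector of `delta_t` values (seconds).
#' @param delta_i fixed inactivity threshold (arrival method).
#' @param metrics metrics to track.
#' @param n_boot bootstrap replicates per estimate (0 = point estimates
#'   only, the default for sweeps).
#' @param seed integer seed.
#' @return data.frame (delta_t, metric, R, ci_low, ci_high, n_dyads) where
#'   `n_dyads` is the total positive-dyad count summed over weeks.
#' @export
sweep_time_window <- function(streams, method = c("window", "arrival"),
                              delta_t_grid = c(1, 5, 15, 50, 150, 300),
                              delta_i = 300,
                              metrics = c("degree", "strength", "betweenness"),
                              n_boot = 0, seed = 1) {
  method <- match.arg(method)
  out <- list()
  for (dt in delta_t_grid) {
    params <- association_params(delta_t = dt, delta_i = delta_i)
    panel <- suppressWarnings(weekly_metric_panel(streams, method, params))
    ndy <- sum(vapply(unique(panel$week), function(wk) {
      sub <- panel[panel$week == wk & panel$metric == "degree", ]
      sum(sub$value) / 2
    }, numeric(1)))
    for (met in metrics) {
      r <- tryCatch(
        estimate_repeatability(panel, met, n_boot = n_boot,
                               seed = derive_seed(seed, met, round(dt * 1000))),
        error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        delta_t = dt, metric = met,
        R = if (is.null(r)) NA_real_ else r$R,
        ci_low = if (is.null(r)) NA_real_ else r$ci_low,
        ci_high = if (is.null(r)) NA_real_ else r$ci_high,
        n_dyads = ndy, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
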