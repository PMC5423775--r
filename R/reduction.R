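#' Initial slope of a fluorescence trace
#'
#' Ordinary least-squares slope over the leading window of the trace. With a
#' first-order decay the expected initial slope is `-F0 * k_unf`, so slopes of
#' doped reactions divided by the undoped slope give normalized unfolding
#' activities. The default window is the first 10% of points or 5 points,
#' whichever is larger.
#'
#' @param trace A [gen_fluorescence_trace()] output or any data frame whose
#'   first two columns are time and signal.
#' @param window `NULL` for the default; a single integer for that many
#'   leading points; or a length-2 numeric `c(t0, t1)` time interval. The
#'   window must contain at least 3 points.
#' @return The signed slope (signal units per time unit) with attributes
#'   `se` (standard error) and `n_points`.
#' @export
initial_slope <- function(trace, window = NULL) {
  tt <- trace[[1]]
  ff <- trace[[2]]
  n <- length(tt)
  if (n < 3L) stop("trace too short: need at least 3 points")
  keep <- if (is.null(window)) {
    seq_len(max(5L, ceiling(0.1 * n)))
  } else if (length(window) == 1L) {
    seq_len(min(n, as.integer(window)))
  } else if (length(window) == 2L) {
    which(tt >= window[1] & tt <= window[2])
  } else {
    stop("`window` must be NULL, a point count, or a time interval c(t0, t1)")
  }
  if (length(keep) < 3L) stop("window must contain at least 3 points")
  ols <- .ols_line(tt[keep], ff[keep])
  slope <- ols$slope
  attr(slope, "se") <- ols$se
  attr(slope, "n_points") <- length(keep)
  slope
}

# slope, intercept and slope SE of y ~ x without summary.lm's perfect-fit
# warnings on noiseless synthetic input
.ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate window: all time points identical")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  inter <- mean(y) - slope * mean(x)
  res <- y - inter - slope * x
  list(slope = slope, intercept = inter,
       se = sqrt(sum(res^2) / (n - 2L) / sxx))
}

#' Normalize raw rates by the undoped baseline and aggregate per r
#'
#' Divides every rate by the mean rate of the `r = 0` group and returns the
#' per-`r` mean and sample standard deviation (the error bars of the doping
#' curves are +/- 1 SD over replicates).
#'
#' @param rates Data frame with columns `r` and `rate` (one row per
#'   replicate). Slopes may be negative; ratios to the baseline are returned
#'   as-is.
#' @return An [activity_curve()]-classed data frame with columns `r`,
#'   `activity` (mean), `sd`, `n_replicates`.
#' @export
normalize_and_aggregate <- function(rates) {
  if (!all(c("r", "rate") %in% names(rates)))
    stop("`rates` must have columns `r` and `rate`")
  base <- rates$rate[rates$r == 0]
  if (length(base) < 1L)
    stop("cannot normalize: no replicates at r = 0")
  b <- mean(base)
  if (b == 0) stop("cannot normalize: mean r = 0 rate is zero")
  a <- rates$rate / b
  grp <- split(a, rates$r)
  out <- data.frame(r = as.numeric(names(grp)),
                    activity = vapply(grp, mean, numeric(1)),
                    sd = vapply(grp, function(x)
                      if (length(x) > 1L) stats::sd(x) else 0, numeric(1)),
                    n_replicates = lengths(grp))
  rownames(out) <- NULL
  out <- out[order(out$r), ]
  class(out) <- c("activity_curve", "data.frame")
  out
}

#' Fit the threshold (subunit-poisoning) model to a doping dataset
#'
#' Compares replicate activities against the closed-form curves
#' [activity_threshold()] for every threshold `m` in `1..n+1` by residual sum
#' of squares. `m` is a discrete hypothesis with no free parameters, so model
#' selection is the RSS argmin (ties broken toward smaller `m`); confidence is
#' quantified by the selection frequency over bootstrap resamples of the
#' replicates within each mixing fraction.
#'
#' @param data A [gen_doping_dataset()] output or data frame with columns `r`
#'   and `activity` (>= 3 distinct `r` values).
#' @param ring A [ring_spec()].
#' @param n_bootstrap Number of bootstrap resamples (0 disables).
#' @param weights `"none"` (default) or `"inverse_variance"` (weight each
#'   point by the inverse replicate variance of its `r` group).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `"threshold_fit"`: list with `rss_by_m` (named
#'   numeric, `m = 1..n+1`), `best_m`, `bootstrap_freq` (named selection
#'   frequencies or `NULL`), `n_bootstrap`, `ring`.
#' @export
fit_threshold_model <- function(data, ring = ring_spec(), n_bootstrap = 0,
                                weights = c("none", "inverse_variance"),
                                seed = NULL) {
  weights <- match.arg(weights)
  if (!all(c("r", "activity") %in% names(data)))
    stop("`data` must have columns `r` and `activity`")
  if (length(unique(data$r)) < 3L)
    stop("degenerate data: need >= 3 distinct r values")
  n <- ring$n_protomers
  m_grid <- seq_len(n + 1L)

  w <- rep(1, nrow(data))
  if (weights == "inverse_variance") {
    v <- tapply(data$activity, data$r, stats::var)
    v[!is.finite(v) | v <= 0] <- min(v[is.finite(v) & v > 0], 1e-8)
    w <- 1 / v[as.character(data$r)]
  }

  rss_of <- function(dat, wt) {
    vapply(m_grid, function(m) {
      sum(wt * (dat$activity - activity_threshold(dat$r, m, ring))^2)
    }, numeric(1))
  }
  rss <- rss_of(data, w)
  names(rss) <- m_grid
  best <- m_grid[which.min(rss)]  # which.min takes the first minimum: smaller m

  boot_freq <- NULL
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx_by_r <- split(seq_len(nrow(data)), data$r)
    picks <- vapply(seq_len(n_bootstrap), function(b) {
      take <- unlist(lapply(idx_by_r, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
      dat <- data[take, , drop = FALSE]
      m_grid[which.min(rss_of(dat, w[take]))]
    }, numeric(1))
    boot_freq <- as.numeric(table(factor(picks, levels = m_grid))) / n_bootstrap
    names(boot_freq) <- m_grid
  }

  structure(list(rss_by_m = rss, best_m = best, bootstrap_freq = boot_freq,
                 n_bootstrap = n_bootstrap, ring = ring),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  n <- x$ring$n_protomers
  cat("Threshold (subunit-poisoning) model fit\n")
  cat(sprintf("  best m = %d%s\n", x$best_m,
              if (x$best_m == n + 1L) " (uncoupled, A = 1 - r)" else ""))
  cat("  RSS by m:\n")
  print(round(x$rss_by_m, 6))
  if (!is.null(x$bootstrap_freq)) {
    cat(sprintf("  bootstrap selection frequency (%d resamples):\n",
                x$n_bootstrap))
    print(x$bootstrap_freq)
  }
  invisible(x)
}

#' Fit the escape rate by matching simulated ensembles to data
#'
#' Grid search over `k_escape` minimizing the squared error between
#' [ensemble_activity()] curves and the per-`r` mean activities of the data.
#' Common random numbers (one fixed sub-seed per mixing fraction, shared
#' across grid points) make the stochastic objective quasi-deterministic, so
#' the profile is smooth and its flatness visible.
#'
#' @param data Data frame with columns `r` and `activity`.
#' @param params A [motor_params()]; its `k_escape` is overridden by the grid
#'   and its `k_reengage` should be positive for escape to matter.
#' @param k_escape_grid Non-negative, increasing grid of candidate rates.
#' @param n_complexes,t_end Ensemble size and horizon per grid point.
#' @param seed Integer seed for the common random numbers (recorded).
#' @param ring A [ring_spec()].
#' @return An object of class `"escape_fit"`: list with `k_escape_hat`,
#'   `profile` (data frame `k_escape`, `objective`), `curves` (data frame of
#'   fitted activities per `k_escape` and `r`), `seed`.
#' @export
fit_escape_model <- function(data, params, k_escape_grid, n_complexes = 400,
                             t_end = 120, seed = 1, ring = ring_spec()) {
  if (!all(c("r", "activity") %in% names(data)))
    stop("`data` must have columns `r` and `activity`")
  if (length(k_escape_grid) < 2L || any(k_escape_grid < 0) ||
      is.unsorted(k_escape_grid, strictly = TRUE))
    stop("`k_escape_grid` must be >= 2 increasing non-negative values")
  r_vals <- sort(unique(data$r))
  means <- vapply(split(data$activity, data$r), mean, numeric(1))
  means <- means[order(as.numeric(names(means)))]
  set.seed(seed)
  seeds_r <- sample.int(.Machine$integer.max - 1L, length(r_vals))

  rows <- vector("list", length(k_escape_grid))
  objective <- numeric(length(k_escape_grid))
  for (g in seq_along(k_escape_grid)) {
    pk <- params
    pk$k_escape <- k_escape_grid[g]
    act <- vapply(seq_along(r_vals), function(j) {
      ensemble_activity(pk, r_vals[j], n_complexes, t_end,
                        seed = seeds_r[j], ring = ring)$activity
    }, numeric(1))
    objective[g] <- sum((means - act)^2)
    rows[[g]] <- data.frame(k_escape = k_escape_grid[g], r = r_vals,
                            activity = act)
  }
  if (any(!is.finite(objective)))
    stop("non-finite escape-fit objective; check simulator parameters")
  structure(list(k_escape_hat = k_escape_grid[which.min(objective)],
                 profile = data.frame(k_escape = k_escape_grid,
                                      objective = objective),
                 curves = do.call(rbind, rows),
                 seed = seed),
            class = "escape_fit")
}

#' @export
print.escape_fit <- function(x, ...) {
  cat(sprintf("Escape-rate fit: k_escape_hat = %g (seed %d)\n",
              x$k_escape_hat, x$seed))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Quantify a degradation time course
#'
#' Normalizes band intensities to the first time point and estimates the
#' first-order degradation rate by log-linear least squares,
#' `log(fraction) = -k_deg * t`.
#'
#' @param tab Data frame with columns `time` and `intensity` (positive), and
#'   optionally `condition` for several series.
#' @return An object of class `"degradation_fit"`: list with `table` (input
#'   plus a `fraction` column) and `rates` (data frame `condition`, `k_deg`,
#'   `se`).
#' @export
quantify_degradation <- function(tab) {
  if (!all(c("time", "intensity") %in% names(tab)))
    stop("`tab` must have columns `time` and `intensity`")
  cond <- if ("condition" %in% names(tab)) tab$condition else "series"
  pieces <- split(seq_len(nrow(tab)), cond)
  frac <- numeric(nrow(tab))
  rates <- lapply(names(pieces), function(cc) {
    ix <- pieces[[cc]]
    tt <- tab$time[ix]
    ii <- tab$intensity[ix]
    if (length(ix) < 3L) stop("need >= 3 time points per condition")
    if (any(ii <= 0)) stop("intensities must be positive for a log-linear fit")
    f <- ii / ii[which.min(tt)]
    frac[ix] <<- f
    fit <- .ols_line(tt, log(f))
    data.frame(condition = cc, k_deg = -fit$slope, se = fit$se)
  })
  out <- as.data.frame(tab)
  out$fraction <- frac
  structure(list(table = out, rates = do.call(rbind, rates)),
            class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat("First-order degradation fit\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
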