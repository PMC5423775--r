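#' Ensemble activity of doped complexes at one mixing fraction
#'
#' Samples `n_complexes` complexes whose protomers are independently dead with
#' probability `r` (the same random-assembly assumption as the binomial
#' composition model), simulates each to `t_end`, and returns mean ATPase
#' activity and unfolding throughput normalized to the all-wild-type rate.
#'
#' Normalization uses a paired all-active reference: every complex is
#' simulated twice from the same sub-seed, once with its sampled dead flags
#' and once fully active, and activities are means over the doped ensemble
#' divided by the reference mean. The common random numbers make the r = 0
#' point exactly 1, reduce Monte Carlo variance, and pair cleanly across
#' parameter grids (e.g. escape-rate scans run with the same `seed`).
#'
#' @param params A [motor_params()].
#' @param r Mixing fraction of dead protomers in `[0, 1]`.
#' @param n_complexes Number of complexes to simulate (>= 1).
#' @param t_end Simulation horizon per complex.
#' @param seed Optional integer seed.
#' @param ring A [ring_spec()] giving the number of protomers.
#' @return An object of class `"ensemble_point"`: list with `r`, `activity`
#'   (normalized mean ATPase rate), `se`, `unfolding` (normalized mean
#'   translocation throughput in residues/time; partial substrates count),
#'   `unfolding_se`, `n_complexes`, `t_end`, `seed`.
#' @examples
#' p <- motor_params()
#' ensemble_activity(p, r = 0, n_complexes = 20, t_end = 30, seed = 1)$activity
#' @export
ensemble_activity <- function(params, r, n_complexes, t_end, seed = NULL,
                              ring = ring_spec()) {
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("mixing fraction `r` must be a single value in [0, 1]")
  if (n_complexes < 1L) stop("`n_complexes` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- ring$n_protomers
  dead <- matrix(stats::runif(n_complexes * n) < r, n_complexes, n)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_complexes)
  none <- rep(FALSE, n)

  atp <- ref_atp <- res <- ref_res <- numeric(n_complexes)
  for (i in seq_len(n_complexes)) {
    tr <- simulate_motor(params, dead[i, ], t_end, seed = sub_seeds[i],
                         record = FALSE)
    rf <- simulate_motor(params, none, t_end, seed = sub_seeds[i],
                         record = FALSE)
    atp[i] <- tr$final_state$atp_hydrolyzed
    res[i] <- tr$final_state$translocated_res
    ref_atp[i] <- rf$final_state$atp_hydrolyzed
    ref_res[i] <- rf$final_state$translocated_res
  }
  if (mean(ref_atp) <= 0)
    stop("all-active reference ensemble produced no transitions; increase `t_end`")

  # activity = mean(atp)/mean(ref); SE from the paired per-complex deviations
  d_atp <- (atp - ref_atp) / mean(ref_atp)
  d_res <- (res - ref_res) / mean(ref_res)
  structure(list(
    r = r,
    activity = 1 + mean(d_atp),
    se = stats::sd(d_atp) / sqrt(n_complexes),
    unfolding = 1 + mean(d_res),
    unfolding_se = stats::sd(d_res) / sqrt(n_complexes),
    n_complexes = n_complexes, t_end = t_end, seed = seed),
    class = "ensemble_point")
}

#' Simulated activity curve over a grid of mixing fractions
#'
#' Convenience wrapper running [ensemble_activity()] at each `r` with seeds
#' derived from `seed` (one independent sub-seed per grid point, so the same
#' `seed` gives paired curves across parameter settings).
#'
#' @param params A [motor_params()].
#' @param r_values Vector of mixing fractions.
#' @inheritParams ensemble_activity
#' @return An [activity_curve()] with columns `r`, `activity`, `stderr`.
#' @export
ensemble_curve <- function(params, r_values, n_complexes, t_end, seed = NULL,
                           ring = ring_spec()) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(r_values))
  pts <- lapply(seq_along(r_values), function(j)
    ensemble_activity(params, r_values[j], n_complexes, t_end,
                      seed = seeds[j], ring = ring))
  activity_curve(r_values,
                 vapply(pts, `[[`, numeric(1), "activity"),
                 vapply(pts, `[[`, numeric(1), "se"))
}

#' ATP dependence of the simulated hydrolysis rate with a Hill fit
#'
#' Simulates all-active complexes across a grid of ATP concentrations (the
#' transition rate saturates as `k_step * c / (K_bind + c)`, single engaging
#' site per transition) and fits the Hill equation
#' `rate = Vmax * c^h / (K^h + c^h)` by nonlinear least squares. The
#' hand-over-hand cycle engages one nucleotide site per transition, so the
#' fitted Hill coefficient should be close to 1 (hyperbolic
#' Michaelis-Menten kinetics, little cooperativity).
#'
#' @param params A [motor_params()] with `K_bind` set (its `atp_conc` is
#'   overridden by the grid).
#' @param atp_grid Vector of >= 4 positive ATP concentrations; should span
#'   `K_bind`.
#' @param n_reps Complexes simulated per concentration.
#' @param t_end Horizon per complex.
#' @param seed Optional integer seed.
#' @param ring A [ring_spec()].
#' @return An object of class `"atp_dependence"`: list with `table`
#'   (data frame: `atp`, `rate`, `se`), `vmax`, `k_half`, `hill`, and the
#'   underlying `nls` fit.
#' @export
atp_dependence <- function(params, atp_grid, n_reps = 200, t_end = 100,
                           seed = NULL, ring = ring_spec()) {
  if (length(atp_grid) < 4L) stop("`atp_grid` needs at least 4 points")
  if (any(atp_grid <= 0)) stop("`atp_grid` must be positive")
  if (is.null(params$K_bind))
    stop("`params$K_bind` must be set for an ATP titration")
  if (min(atp_grid) >= params$K_bind || max(atp_grid) <= params$K_bind)
    warning("`atp_grid` does not span `K_bind`; the fit may be poorly constrained")
  if (!is.null(seed)) set.seed(seed)
  n <- ring$n_protomers
  none <- rep(FALSE, n)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(atp_grid) * n_reps),
                  nrow = length(atp_grid))
  rate_mean <- rate_se <- numeric(length(atp_grid))
  for (j in seq_along(atp_grid)) {
    pj <- params
    pj$atp_conc <- atp_grid[j]
    rates <- vapply(seq_len(n_reps), function(i) {
      simulate_motor(pj, none, t_end, seed = seeds[j, i],
                     record = FALSE)$final_state$atp_hydrolyzed / t_end
    }, numeric(1))
    rate_mean[j] <- mean(rates)
    rate_se[j] <- stats::sd(rates) / sqrt(n_reps)
  }
  tab <- data.frame(atp = atp_grid, rate = rate_mean, se = rate_se)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ Vmax * atp^h / (K^h + atp^h), data = tab,
                      start = list(Vmax = max(rate_mean), K = params$K_bind,
                                   h = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(table = tab, vmax = unname(cf["Vmax"]),
                 k_half = unname(cf["K"]), hill = unname(cf["h"]),
                 fit = fit),
            class = "atp_dependence")
}

#' @export
print.atp_dependence <- function(x, ...) {
  cat("ATP dependence of simulated hydrolysis rate\n")
  cat(sprintf("  Hill fit: Vmax = %.4g, K_half = %.4g, h = %.3f\n",
              x$vmax, x$k_half, x$hill))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.ensemble_point <- function(x, ...) {
  cat(sprintf(
    "Ensemble point r = %.3g: activity %.4f (SE %.2g), unfolding %.4f (SE %.2g), n = %d\n",
    x$r, x$activity, x$se, x$unfolding, x$unfolding_se, x$n_complexes))
  invisible(x)
}
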