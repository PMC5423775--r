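#' Ring geometry of a hexameric AAA+ motor
#'
#' Describes the oligomeric state of the motor: how many protomers form a
#' complex and how many nucleotide-binding sites each protomer carries. VAT is
#' a homohexamer with two tandem AAA+ domains (NBD1, NBD2) per protomer, hence
#' the defaults of 6 and 2.
#'
#' @param n_protomers Integer number of protomers per complex (>= 2).
#' @param sites_per_protomer Integer nucleotide-binding sites per protomer
#'   (>= 1). Only used for bookkeeping of functional-site counts; a dead
#'   protomer inactivates all of its sites at once (the double Walker-B
#'   construct mutates both domains).
#' @return An object of class `"ring_spec"`.
#' @examples
#' ring_spec()          # the VAT hexamer
#' ring_spec(6, 2)
#' @export
ring_spec <- function(n_protomers = 6L, sites_per_protomer = 2L) {
  n <- as.integer(n_protomers)
  s <- as.integer(sites_per_protomer)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("`n_protomers` must be a single integer >= 2")
  if (length(s) != 1L || is.na(s) || s < 1L)
    stop("`sites_per_protomer` must be a single integer >= 1")
  structure(list(n_protomers = n, sites_per_protomer = s), class = "ring_spec")
}

#' Coupling model: how many dead protomers abolish hydrolysis
#'
#' The subunit-poisoning model assumes that activity in the functional sites is
#' unaffected by incorporation of catalytically dead protomers until `m` of
#' them are present, at which point all hydrolysis in that complex stops.
#' `m = 1` is the strict sequential (hand-over-hand) limit, `m = 2` requires
#' two dead protomers, and `m = n_protomers + 1` encodes the uncoupled
#' (independent-subunit) model, for which the activity curve reduces to
#' `1 - r`.
#'
#' @param threshold_m Integer in `[1, n_protomers + 1]`.
#' @param ring A [ring_spec()].
#' @return An object of class `"coupling_model"`.
#' @export
coupling_model <- function(threshold_m, ring = ring_spec()) {
  m <- as.integer(threshold_m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > ring$n_protomers + 1L)
    stop("`threshold_m` must be an integer in [1, n_protomers + 1]")
  structure(list(threshold_m = m, n_protomers = ring$n_protomers),
            class = "coupling_model")
}

.threshold_m <- function(coupling, ring) {
  m <- if (inherits(coupling, "coupling_model")) coupling$threshold_m
       else as.integer(coupling)
  if (length(m) != 1L || is.na(m) || m < 1L || m > ring$n_protomers + 1L)
    stop("coupling threshold `m` must be an integer in [1, n_protomers + 1]")
  m
}

#' Composition distribution of mixed complexes
#'
#' For complexes assembled from a mixture containing a fraction `r` of
#' catalytically dead protomers, with equal probability of inserting either
#' protomer species at each position, the number of dead protomers per complex
#' is binomial: `P(k) = C(n, k) r^k (1 - r)^(n - k)`.
#'
#' @param r Mixing fraction of dead protomers, in `[0, 1]`.
#' @param ring A [ring_spec()].
#' @return An object of class `"composition_pmf"`: a list with
#'   `probabilities` (vector of length `n_protomers + 1`, entry `k + 1` is
#'   `P(k)`), `mixing_fraction_r` and `ring`.
#' @examples
#' composition_pmf(0.5)$probabilities[4]  # P(3 dead) = 20/64
#' @export
composition_pmf <- function(r, ring = ring_spec()) {
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("mixing fraction `r` must be a single value in [0, 1]")
  n <- ring$n_protomers
  structure(list(probabilities = stats::dbinom(0:n, n, r),
                 mixing_fraction_r = r,
                 ring = ring),
            class = "composition_pmf")
}

#' Closed-form fractional activity under the threshold coupling model
#'
#' Fractional ATPase activity of a solution of complexes assembled at mixing
#' fraction `r`, normalized to the all-wild-type rate:
#' `A(r) = (1/n) * sum_{j=0}^{m-1} (n - j) C(n, j) r^j (1 - r)^(n - j)`.
#' Complexes with `j < m` dead protomers run at the fraction `(n - j)/n` of
#' the wild-type rate (proportional to their functional protomers); complexes
#' with `j >= m` dead protomers are fully inactive. Special cases:
#' `m = 1` gives `(1 - r)^n`; `m = n + 1` (no coupling) gives `1 - r`.
#'
#' @param r Vector of mixing fractions in `[0, 1]`.
#' @param coupling A [coupling_model()] or a bare integer threshold `m`.
#' @param ring A [ring_spec()].
#' @return Numeric vector of fractional activities, same length as `r`.
#' @seealso [enumeration_oracle()] for the brute-force check.
#' @examples
#' activity_threshold(0.5, 1)                 # (1 - 0.5)^6
#' activity_threshold(0.3, 7)                 # uncoupled: 1 - 0.3
#' @export
activity_threshold <- function(r, coupling, ring = ring_spec()) {
  if (anyNA(r) || any(r < 0 | r > 1))
    stop("mixing fraction `r` must lie in [0, 1]")
  n <- ring$n_protomers
  m <- .threshold_m(coupling, ring)
  j <- 0:(m - 1L)
  vapply(r, function(ri) {
    sum((n - j) * choose(n, j) * ri^j * (1 - ri)^(n - j)) / n
  }, numeric(1))
}

#' Brute-force enumeration oracle for the threshold activity model
#'
#' Enumerates all `2^n` labeled active/dead protomer configurations, weights
#' each by `r^k (1 - r)^(n - k)` where `k` is its number of dead protomers,
#' assigns activity `0` if `k >= m` and `(n - k)/n` otherwise, and returns the
#' weighted mean. Deliberately independent of [activity_threshold()]; the two
#' must agree to floating-point precision.
#'
#' @inheritParams activity_threshold
#' @return Numeric vector of fractional activities, same length as `r`.
#' @export
enumeration_oracle <- function(r, coupling, ring = ring_spec()) {
  if (anyNA(r) || any(r < 0 | r > 1))
    stop("mixing fraction `r` must lie in [0, 1]")
  n <- ring$n_protomers
  if (n > 20L)
    stop("refusing to enumerate 2^n configurations for n_protomers > 20")
  m <- .threshold_m(coupling, ring)
  configs <- 0:(2^n - 1L)
  k <- vapply(configs, function(x)
    sum(bitwAnd(bitwShiftR(x, 0:(n - 1L)), 1L)), integer(1))
  act <- ifelse(k >= m, 0, (n - k) / n)
  vapply(r, function(ri) sum(ri^k * (1 - ri)^(n - k) * act), numeric(1))
}

#' Activity-curve container
#'
#' A tidy table of fractional activity versus mixing fraction, the common
#' currency between the closed-form model, the stochastic ensemble and the
#' assay-reduction layer.
#'
#' @param r_values Vector of mixing fractions.
#' @param activity Vector of fractional activities.
#' @param stderr Optional vector of standard errors (Monte Carlo or replicate).
#' @return A data frame of class `c("activity_curve", "data.frame")` with
#'   columns `r`, `activity` and (if given) `stderr`.
#' @export
activity_curve <- function(r_values, activity, stderr = NULL) {
  if (length(r_values) != length(activity))
    stop("`r_values` and `activity` must have the same length")
  out <- data.frame(r = as.numeric(r_values), activity = as.numeric(activity))
  if (!is.null(stderr)) {
    if (length(stderr) != length(activity))
      stop("`stderr` must match `activity` in length")
    out$stderr <- as.numeric(stderr)
  }
  class(out) <- c("activity_curve", "data.frame")
  out
}

#' Evaluate a threshold-model activity curve on a grid
#'
#' @param r_grid Vector of mixing fractions.
#' @inheritParams activity_threshold
#' @return An [activity_curve()].
#' @export
threshold_activity_curve <- function(r_grid, coupling, ring = ring_spec()) {
  activity_curve(r_grid, activity_threshold(r_grid, coupling, ring))
}
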