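#' Kinetic parameters of the hand-over-hand translocation cycle
#'
#' One productive cycle transition moves the staircase of substrate-gripping
#' protomers by one position: the seam protomer rebinds ATP and re-engages the
#' substrate at the top of the helix while the bottom protomer releases and
#' becomes the new seam. Each transition translocates `step_length` angstroms
#' (about two extended residues) and hydrolyzes `atp_per_step` ATP (default 2:
#' one per AAA+ ring, since the two NBDs of each protomer move in unison;
#' configurable to 1 because the stoichiometry is not fixed by the data —
#' normalized activities are invariant to this choice).
#'
#' A complex whose current seam protomer is catalytically dead cannot rebind
#' ATP and stalls. With `k_escape > 0` a stalled complex may release the
#' substrate, wait, and re-engage (rate `k_reengage`) with a uniformly random
#' protomer in the seam position on a fresh substrate.
#'
#' If `atp_conc` and `K_bind` are supplied, the transition rate becomes
#' `k_step * atp_conc / (K_bind + atp_conc)` (single-site binding, hence
#' hyperbolic Michaelis-Menten ATP dependence).
#'
#' @param k_step Rate of one productive cycle transition at saturating ATP
#'   (1/time).
#' @param atp_per_step ATP hydrolyzed per transition.
#' @param step_length Substrate translocated per transition (angstrom).
#' @param step_residues Residues translocated per transition.
#' @param k_escape Rate at which a stalled complex disengages (0 disables).
#' @param k_reengage Rate of re-engagement after disengaging.
#' @param substrate_length Substrate length in residues for throughput
#'   accounting (`Inf` for an effectively endless substrate).
#' @param atp_conc,K_bind Optional ATP concentration and half-saturation
#'   constant (same units); both or neither.
#' @return An object of class `"motor_params"`.
#' @export
motor_params <- function(k_step = 1, atp_per_step = 2, step_length = 13,
                         step_residues = 2, k_escape = 0, k_reengage = 1,
                         substrate_length = Inf,
                         atp_conc = NULL, K_bind = NULL) {
  rates <- c(k_step = k_step, k_escape = k_escape, k_reengage = k_reengage)
  if (anyNA(rates) || any(rates < 0))
    stop("rates `k_step`, `k_escape`, `k_reengage` must be non-negative")
  if (is.na(step_length) || step_length <= 0) stop("`step_length` must be > 0")
  if (is.na(step_residues) || step_residues <= 0) stop("`step_residues` must be > 0")
  if (is.na(atp_per_step) || atp_per_step <= 0) stop("`atp_per_step` must be > 0")
  if (!(is.infinite(substrate_length) || substrate_length > 0))
    stop("`substrate_length` must be > 0 (possibly Inf)")
  if (!is.null(atp_conc) && is.null(K_bind))
    stop("`K_bind` must be supplied together with `atp_conc`")
  if (!is.null(atp_conc) && atp_conc < 0) stop("`atp_conc` must be >= 0")
  if (!is.null(K_bind) && K_bind <= 0) stop("`K_bind` must be > 0")
  structure(list(k_step = k_step, atp_per_step = atp_per_step,
                 step_length = step_length, step_residues = step_residues,
                 k_escape = k_escape, k_reengage = k_reengage,
                 substrate_length = substrate_length,
                 atp_conc = atp_conc, K_bind = K_bind),
            class = "motor_params")
}

# Effective transition rate, saturable in ATP when atp_conc/K_bind are set.
step_rate <- function(params) {
  if (!is.null(params$atp_conc))
    params$k_step * params$atp_conc / (params$K_bind + params$atp_conc)
  else params$k_step
}

#' Initialize the per-protomer ring state
#'
#' Protomer ranks encode the staircase: rank 0 is the topmost gripping
#' position (nearest the folded substrate), rank `n - 2` the bottom gripping
#' position, and rank `n - 1` the seam, which does not contact substrate.
#' Ranks are assigned so that protomer `seam` holds the seam rank and protomer
#' `seam + 1` (cyclically) sits at the top.
#'
#' @param dead_flags Logical vector, one per protomer in cyclic order; `TRUE`
#'   marks a catalytically dead (Walker-B) protomer.
#' @param seam Index of the protomer initially in the seam position.
#' @return An object of class `"motor_state"`.
#' @export
init_motor_state <- function(dead_flags, seam = length(dead_flags)) {
  dead <- as.logical(dead_flags)
  n <- length(dead)
  if (n < 2L || anyNA(dead)) stop("`dead_flags` must be >= 2 logicals without NA")
  seam <- as.integer(seam)
  if (is.na(seam) || seam < 1L || seam > n) stop("`seam` must index a protomer")
  structure(list(dead = dead,
                 rank = (seq_len(n) - seam - 1L) %% n,
                 n = n,
                 translocated_A = 0, translocated_res = 0,
                 substrate_progress = 0, substrates_completed = 0L,
                 atp_hydrolyzed = 0,
                 engaged = TRUE, stalled = FALSE),
            class = "motor_state")
}

#' Index of the protomer currently in the seam position
#' @param state A `"motor_state"`.
#' @return Integer protomer index.
#' @export
seam_protomer <- function(state) which(state$rank == state$n - 1L)

#' Advance the motor by one cycle transition
#'
#' Attempts one productive transition: the seam protomer rebinds ATP and
#' re-engages at the top (rank `n - 1` to 0) while every other protomer's rank
#' increments, so the former bottom protomer becomes the new seam. Substrate
#' advances by `step_length` angstrom / `step_residues` residues and
#' `atp_per_step` ATP are consumed. If the seam protomer is dead it cannot
#' rebind ATP: the state becomes stalled and no counters change.
#'
#' @param state A `"motor_state"`, engaged and not stalled.
#' @param params A [motor_params()].
#' @return A list with elements `state` (updated `"motor_state"`) and `event`
#'   (one of `"transition"`, `"substrate_complete"`, `"stall"`). A transition
#'   that brings the running substrate-progress counter to `substrate_length`
#'   is reported as `"substrate_complete"`; it is still a productive
#'   transition for ATP accounting.
#' @export
advance_motor <- function(state, params) {
  if (!inherits(state, "motor_state")) stop("`state` must be a motor_state")
  if (!state$engaged || state$stalled)
    stop("advance_motor() requires an engaged, unstalled motor state")
  seam <- which(state$rank == state$n - 1L)
  if (state$dead[seam]) {
    state$stalled <- TRUE
    return(list(state = state, event = "stall"))
  }
  state$rank <- (state$rank + 1L) %% state$n
  state$translocated_A <- state$translocated_A + params$step_length
  state$translocated_res <- state$translocated_res + params$step_residues
  state$substrate_progress <- state$substrate_progress + params$step_residues
  state$atp_hydrolyzed <- state$atp_hydrolyzed + params$atp_per_step
  event <- "transition"
  if (is.finite(params$substrate_length) &&
      state$substrate_progress >= params$substrate_length) {
    state$substrates_completed <- state$substrates_completed + 1L
    state$substrate_progress <- 0
    event <- "substrate_complete"
  }
  list(state = state, event = event)
}

#' Simulate one motor complex (Gillespie event loop)
#'
#' Exponential waiting times between events (memoryless single-rate cycle).
#' While engaged, ATP-binding attempts occur at the effective step rate; an
#' attempt on a dead seam protomer produces a stall. A stalled complex
#' disengages at rate `k_escape` (if positive), waits at rate `k_reengage`,
#' and re-engages a fresh substrate with a uniformly random seam phase. No ATP
#' is consumed while stalled or disengaged.
#'
#' The event loop mirrors [advance_motor()] with the seam index tracked
#' directly for speed; the two are equivalent step for step.
#'
#' @param params A [motor_params()].
#' @param dead_flags Logical vector of per-protomer dead flags.
#' @param t_end Simulation horizon (> 0).
#' @param seed Optional integer seed; fixed seeds give bit-reproducible
#'   trajectories.
#' @param seam Initial seam protomer; drawn uniformly if `NULL`.
#' @param record If `FALSE`, skip the per-event log (counters only); used by
#'   large ensembles.
#' @return An object of class `"motor_trajectory"`: list with `event_times`
#'   (strictly increasing), `event_kinds` (`transition`, `substrate_complete`,
#'   `stall`, `escape`, `reengage`), `final_state`, `n_transitions`
#'   (productive transitions, substrate completions included), `rng_seed`,
#'   `t_end`, `params`.
#' @export
simulate_motor <- function(params, dead_flags, t_end, seed = NULL,
                           seam = NULL, record = TRUE) {
  if (is.na(t_end) || t_end <= 0) stop("`t_end` must be positive")
  if (!is.null(seed)) set.seed(seed)
  dead <- as.logical(dead_flags)
  n <- length(dead)
  if (n < 2L || anyNA(dead)) stop("`dead_flags` must be >= 2 logicals without NA")
  seam_i <- if (is.null(seam)) sample.int(n, 1L) else as.integer(seam)
  if (seam_i < 1L || seam_i > n) stop("`seam` must index a protomer")
  k_eff <- step_rate(params)
  sub_len <- params$substrate_length
  step_res <- params$step_residues

  t <- 0
  transitions <- 0L
  completions <- 0L
  progress <- 0
  engaged <- TRUE
  stalled <- FALSE

  nev <- 0L
  cap <- 256L
  times <- numeric(cap)
  kinds <- character(cap)
  push <- function(tt, kk) {
    if (nev == cap) {
      cap <<- cap * 2L
      length(times) <<- cap
      length(kinds) <<- cap
    }
    nev <<- nev + 1L
    times[nev] <<- tt
    kinds[nev] <<- kk
  }

  repeat {
    if (!stalled) {
      if (k_eff <= 0) break
      t <- t + stats::rexp(1L, k_eff)
      if (t > t_end) break
      if (dead[seam_i]) {
        stalled <- TRUE
        if (record) push(t, "stall")
        next
      }
      transitions <- transitions + 1L
      ev <- "transition"
      if (is.finite(sub_len)) {
        progress <- progress + step_res
        if (progress >= sub_len) {
          completions <- completions + 1L
          progress <- 0
          ev <- "substrate_complete"
        }
      }
      seam_i <- if (seam_i == 1L) n else seam_i - 1L
      if (record) push(t, ev)
    } else {
      if (params$k_escape <= 0) break
      t <- t + stats::rexp(1L, params$k_escape)
      if (t > t_end) break
      stalled <- FALSE
      engaged <- FALSE
      if (record) push(t, "escape")
      if (params$k_reengage <= 0) break
      t <- t + stats::rexp(1L, params$k_reengage)
      if (t > t_end) break
      seam_i <- sample.int(n, 1L)
      progress <- 0
      engaged <- TRUE
      if (record) push(t, "reengage")
    }
  }

  state <- structure(list(
    dead = dead,
    rank = (seq_len(n) - seam_i - 1L) %% n,
    n = n,
    translocated_A = transitions * params$step_length,
    translocated_res = transitions * step_res,
    substrate_progress = progress,
    substrates_completed = completions,
    atp_hydrolyzed = transitions * params$atp_per_step,
    engaged = engaged, stalled = stalled), class = "motor_state")

  structure(list(event_times = times[seq_len(nev)],
                 event_kinds = kinds[seq_len(nev)],
                 final_state = state,
                 n_transitions = transitions,
                 rng_seed = seed, t_end = t_end, params = params),
            class = "motor_trajectory")
}

#' @export
print.motor_trajectory <- function(x, ...) {
  s <- x$final_state
  cat("Hand-over-hand motor trajectory\n")
  cat(sprintf("  horizon: %g, events recorded: %d, productive transitions: %d\n",
              x$t_end, length(x$event_times), x$n_transitions))
  cat(sprintf("  ATP hydrolyzed: %g, translocated: %g A (%g residues), substrates completed: %d\n",
              s$atp_hydrolyzed, s$translocated_A, s$translocated_res,
              s$substrates_completed))
  cat(sprintf("  final: engaged=%s stalled=%s, seam protomer %d of %d\n",
              s$engaged, s$stalled, seam_protomer(s), s$n))
  invisible(x)
}
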