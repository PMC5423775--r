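#' Generate a synthetic doping-experiment dataset
#'
#' Emulates the mixed wild-type/Walker-B-mutant doping assay: protomers are
#' mixed at a fraction `r` of dead subunits, complexes assemble binomially,
#' and replicate activity measurements (triplicates in the lab protocol) are
#' recorded with additive Gaussian noise.
#'
#' The ground truth is either the closed-form threshold model
#' (`truth = list(m = ...)`) or the stochastic simulator
#' (`truth = list(params = motor_params(...), n_complexes = ..., t_end = ...)`).
#' In analytic mode (`n_assembled = Inf`, the default) the noiseless replicate
#' mean is exactly [activity_threshold()]; a finite `n_assembled` adds
#' binomial assembly noise from sampling that many complexes per measurement.
#'
#' @param truth List describing the generating model (see Details).
#' @param r_grid Vector of mixing fractions (must be non-empty).
#' @param reps Replicates per mixing fraction (>= 1; the assay uses 3).
#' @param noise_sd SD of additive Gaussian measurement noise on the
#'   normalized-activity scale.
#' @param n_assembled Complexes sampled per measurement (`Inf` = analytic).
#' @param seed Optional integer seed; generation is a pure function of
#'   (parameters, seed).
#' @param ring A [ring_spec()].
#' @param assay_kind `"atpase"` or `"unfolding"` (metadata only; both assays
#'   share the activity scale after normalization).
#' @return A data frame of class `c("doping_dataset", "data.frame")` with
#'   columns `r`, `replicate`, `activity`, and attributes `assay_kind`,
#'   `ring`, `noise_sd`, `n_assembled`, `seed`, `truth`.
#' @examples
#' d <- gen_doping_dataset(list(m = 1), seq(0, 0.9, 0.1), seed = 7)
#' head(d)
#' @export
gen_doping_dataset <- function(truth = list(m = 1), r_grid, reps = 3,
                               noise_sd = 0.02, n_assembled = Inf,
                               seed = NULL, ring = ring_spec(),
                               assay_kind = c("atpase", "unfolding")) {
  assay_kind <- match.arg(assay_kind)
  if (length(r_grid) == 0L) stop("`r_grid` must be non-empty")
  if (anyNA(r_grid) || any(r_grid < 0 | r_grid > 1))
    stop("`r_grid` values must lie in [0, 1]")
  if (reps < 1L) stop("`reps` must be >= 1")
  if (is.na(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!(is.infinite(n_assembled) || n_assembled >= 1))
    stop("`n_assembled` must be >= 1 (possibly Inf)")
  if (!is.null(seed)) set.seed(seed)
  n <- ring$n_protomers

  mean_fun <- if (!is.null(truth$m)) {
    m <- .threshold_m(truth$m, ring)
    function(r) {
      if (is.infinite(n_assembled)) {
        activity_threshold(r, m, ring)
      } else {
        k <- stats::rbinom(n_assembled, n, r)
        mean(ifelse(k >= m, 0, (n - k) / n))
      }
    }
  } else if (!is.null(truth$params)) {
    nc <- if (is.null(truth$n_complexes)) 200L else truth$n_complexes
    te <- if (is.null(truth$t_end)) 100 else truth$t_end
    function(r) {
      ensemble_activity(truth$params, r, nc, te,
                        seed = sample.int(.Machine$integer.max - 1L, 1L),
                        ring = ring)$activity
    }
  } else {
    stop("`truth` must contain either `m` (threshold model) or `params` (simulator)")
  }

  rows <- expand.grid(replicate = seq_len(reps), r = r_grid)[, 2:1]
  rows <- rows[order(rows$r, rows$replicate), ]
  rows$activity <- vapply(rows$r, mean_fun, numeric(1)) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rownames(rows) <- NULL
  structure(rows, class = c("doping_dataset", "data.frame"),
            assay_kind = assay_kind, ring = ring, noise_sd = noise_sd,
            n_assembled = n_assembled, seed = seed, truth = truth)
}

#' Generate a synthetic fluorescence unfolding trace
#'
#' Models the GFP-ssrA unfolding assay read in a plate reader: a chaperonin
#' trap binds unfolded GFP and prevents refolding, so fluorescence decays
#' first-order in the remaining folded substrate,
#' `F(t) = F_bg + F0 exp(-k_unf t)` plus Gaussian noise. Only the initial
#' slope (`-F0 * k_unf` in expectation) is used downstream, which is
#' insensitive to the tail shape.
#'
#' @param k_unf First-order unfolding rate (1/s, >= 0).
#' @param F0 Initial substrate fluorescence above background (a.u.).
#' @param F_bg Background fluorescence (a.u.).
#' @param noise_sd SD of additive Gaussian noise (a.u.).
#' @param dt Sampling interval (s).
#' @param t_end Trace duration (s); the trace must have >= 10 points.
#' @param seed Optional integer seed.
#' @return A data frame of class `c("fluorescence_trace", "data.frame")` with
#'   columns `time`, `fluorescence` and attributes `true_rate` (= `k_unf`),
#'   `F0`, `F_bg`, `noise_sd`, `seed`.
#' @export
gen_fluorescence_trace <- function(k_unf, F0 = 100, F_bg = 5, noise_sd = 1,
                                   dt = 1, t_end = 500, seed = NULL) {
  if (is.na(k_unf) || k_unf < 0) stop("`k_unf` must be >= 0")
  if (dt <= 0 || t_end <= 0) stop("`dt` and `t_end` must be positive")
  times <- seq(0, t_end, by = dt)
  if (length(times) < 10L) stop("trace must contain at least 10 points")
  if (!is.null(seed)) set.seed(seed)
  f <- F_bg + F0 * exp(-k_unf * times) +
    stats::rnorm(length(times), 0, noise_sd)
  structure(data.frame(time = times, fluorescence = f),
            class = c("fluorescence_trace", "data.frame"),
            true_rate = k_unf, F0 = F0, F_bg = F_bg,
            noise_sd = noise_sd, seed = seed)
}

#' Generate labeled pore-loop coordinates on an ideal staircase helix
#'
#' Emulates the substrate-gripping architecture: `n - 1` gripping protomers on
#' an ideal helix (helical index `i` at angle `i * twist` and height
#' `i * rise`), plus a seam protomer displaced radially outward and axially
#' upward by the stated offsets, bridging the top and bottom of the staircase
#' without touching substrate. Four pore loops per protomer (two per AAA+
#' ring) are generated on coaxial helices with loop-specific radius and axial
#' offsets; the defaults give a wider NBD1 opening (radius 14, ~28 angstrom
#' across), a tighter NBD2 opening (radius 9, ~18 angstrom), and a combined
#' gripping span of ~80 angstrom along the axis. Gaussian jitter is added to
#' every coordinate.
#'
#' @param n Number of protomers (>= 4).
#' @param rise Helical rise per protomer (angstrom).
#' @param twist Helical twist per protomer (degrees), in
#'   `(0, 360 / (n - 1))`.
#' @param radius Reference pore-loop radius (angstrom, NBD1-PL1).
#' @param seam_radial_offset,seam_axial_offset Displacement of the seam
#'   protomer outward / upward from its helical continuation (angstrom).
#' @param jitter_sd SD of isotropic Gaussian coordinate jitter (angstrom).
#' @param seed Optional integer seed.
#' @param seam_index Which protomer is the seam (ground truth, default `n`).
#' @param loops Character vector of loop labels to generate.
#' @param loop_radius_offsets,loop_z_offsets Per-loop radius and axial offsets
#'   (angstrom), parallel to `loops`.
#' @return A data frame of class `c("pore_loop_set", "data.frame")` with
#'   columns `protomer`, `loop`, `x`, `y`, `z` (one row per protomer-loop
#'   pair) and attributes `seam_index`, `rise`, `twist`, `radius`,
#'   `jitter_sd`, `seed`.
#' @export
gen_pore_loop_helix <- function(n = 6, rise = 13, twist = 60, radius = 14,
                                seam_radial_offset = 8, seam_axial_offset = 6,
                                jitter_sd = 0, seed = NULL, seam_index = n,
                                loops = c("NBD1-PL1", "NBD1-PL2",
                                          "NBD2-PL1", "NBD2-PL2"),
                                loop_radius_offsets = c(0, 1.5, -5, -3.5),
                                loop_z_offsets = c(0, -4, -28, -32)) {
  n <- as.integer(n)
  if (n < 4L) stop("`n` must be >= 4")
  if (is.na(twist) || twist <= 0 || twist >= 360 / (n - 1))
    stop("`twist` must lie in (0, 360/(n-1)) degrees")
  if (rise <= 0 || radius <= 0) stop("`rise` and `radius` must be positive")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  if (length(loop_radius_offsets) != length(loops) ||
      length(loop_z_offsets) != length(loops))
    stop("loop offset vectors must match `loops` in length")
  if (seam_index < 1L || seam_index > n) stop("`seam_index` must index a protomer")
  if (!is.null(seed)) set.seed(seed)

  protomer <- rep(seq_len(n), times = length(loops))
  loop <- rep(loops, each = n)
  # helical index: gripping protomers occupy 0..n-2 in cyclic order after the
  # seam; the seam itself continues the helix at index n-1 before displacement
  idx <- (protomer - seam_index - 1L) %% n
  is_seam <- protomer == seam_index
  rad <- radius + loop_radius_offsets[match(loop, loops)] +
    ifelse(is_seam, seam_radial_offset, 0)
  ang <- idx * twist * pi / 180
  z <- idx * rise + loop_z_offsets[match(loop, loops)] +
    ifelse(is_seam, seam_axial_offset, 0)
  out <- data.frame(protomer = protomer, loop = loop,
                    x = rad * cos(ang), y = rad * sin(ang), z = z)
  if (jitter_sd > 0) {
    jit <- matrix(stats::rnorm(3L * nrow(out), 0, jitter_sd), ncol = 3L)
    out$x <- out$x + jit[, 1]
    out$y <- out$y + jit[, 2]
    out$z <- out$z + jit[, 3]
  }
  structure(out, class = c("pore_loop_set", "data.frame"),
            seam_index = seam_index, rise = rise, twist = twist,
            radius = radius, jitter_sd = jitter_sd, seed = seed)
}

#' Generate a synthetic degradation band-intensity time course
#'
#' Emulates densitometry of substrate bands during a degradation reaction:
#' `intensity(t) = exp(-k_deg t)` plus Gaussian noise, alongside a flat
#' control series (`k_deg = 0`) standing in for the -ATP / -proteasome
#' controls.
#'
#' @param k_deg First-order degradation rate (1/h, >= 0).
#' @param times Increasing vector of sampling times (h).
#' @param noise_sd SD of additive Gaussian noise on the intensity scale.
#' @param seed Optional integer seed.
#' @param include_control If `TRUE`, append a `"control"` condition with
#'   `k_deg = 0`.
#' @return A data frame of class `c("band_timecourse", "data.frame")` with
#'   columns `time`, `intensity`, `condition` and attributes `k_deg`,
#'   `noise_sd`, `seed`.
#' @export
gen_band_timecourse <- function(k_deg, times, noise_sd = 0, seed = NULL,
                                include_control = TRUE) {
  if (is.na(k_deg) || k_deg < 0) stop("`k_deg` must be >= 0")
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  one <- function(k, cond) {
    data.frame(time = times,
               intensity = exp(-k * times) +
                 stats::rnorm(length(times), 0, noise_sd),
               condition = cond)
  }
  out <- one(k_deg, "reaction")
  if (include_control) out <- rbind(out, one(0, "control"))
  structure(out, class = c("band_timecourse", "data.frame"),
            k_deg = k_deg, noise_sd = noise_sd, seed = seed)
}
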