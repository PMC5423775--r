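#' Write an activity curve to CSV with an optional JSON metadata sidecar
#'
#' @param curve An [activity_curve()] (or compatible data frame).
#' @param file Path of the CSV to write (columns `r`, `activity`, and
#'   whatever error column the curve carries).
#' @param meta Optional named list of model metadata (e.g. `n`, `m`, seed);
#'   written as JSON next to `file` (extension `.json`) when non-empty.
#' @return `file`, invisibly.
#' @export
write_activity_curve <- function(curve, file, meta = list()) {
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  if (length(meta) > 0) {
    jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", file),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read / write doping datasets as CSV
#'
#' The on-disk format is the assay table: columns `r`, `replicate`,
#' `activity`. [write_doping_csv()] also writes a JSON sidecar with the
#' generation metadata carried by [gen_doping_dataset()] outputs.
#'
#' @param data A doping dataset data frame.
#' @param file CSV path.
#' @return The dataset (read) or `file` invisibly (write).
#' @export
write_doping_csv <- function(data, file) {
  utils::write.csv(as.data.frame(data)[, c("r", "replicate", "activity")],
                   file, row.names = FALSE)
  meta <- list(assay_kind = attr(data, "assay_kind"),
               noise_sd = attr(data, "noise_sd"),
               n_assembled = attr(data, "n_assembled"),
               seed = attr(data, "seed"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  meta <- lapply(meta, function(x) if (is.infinite(x)) "Inf" else x)
  if (length(meta) > 0) {
    jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", file),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname write_doping_csv
#' @export
read_doping_csv <- function(file) {
  out <- utils::read.csv(file)
  need <- c("r", "replicate", "activity")
  if (!all(need %in% names(out)))
    stop("doping CSV must have columns r, replicate, activity")
  class(out) <- c("doping_dataset", "data.frame")
  out
}

#' Read / write labeled pore-loop points as CSV
#'
#' Plain-text interchange format: columns `protomer`, `loop`, `x`, `y`, `z`
#' (angstrom).
#'
#' @param points A `"pore_loop_set"` data frame.
#' @param file CSV path.
#' @return The point set (read) or `file` invisibly (write).
#' @export
write_pore_loops_csv <- function(points, file) {
  utils::write.csv(as.data.frame(points), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pore_loops_csv
#' @export
read_pore_loops_csv <- function(file) {
  out <- utils::read.csv(file)
  need <- c("protomer", "loop", "x", "y", "z")
  if (!all(need %in% names(out)))
    stop("pore-loop CSV must have columns protomer, loop, x, y, z")
  class(out) <- c("pore_loop_set", "data.frame")
  out
}

#' Export pore-loop points as a minimal PDB file
#'
#' Writes one CA pseudo-atom per pore-loop point (chain = protomer letter,
#' residue number = loop index) so the point set can be inspected in standard
#' structure viewers. Requires the bio3d package.
#'
#' @param points A `"pore_loop_set"` data frame.
#' @param file PDB path.
#' @return `file`, invisibly.
#' @export
write_pore_loops_pdb <- function(points, file) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("package `bio3d` is required for PDB export")
  pts <- as.data.frame(points)
  loops <- unique(pts$loop)
  na <- nrow(pts)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(pts[, c("x", "y", "z")]))),
                   resno = match(pts$loop, loops),
                   chain = LETTERS[pts$protomer],
                   resid = rep("GLY", na), elety = rep("CA", na),
                   eleno = seq_len(na))
  invisible(file)
}

#' Read labeled pore-loop points from a PDB file
#'
#' Extracts one point per (protomer, loop) as the centroid of the CA atoms in
#' a residue range on a chain. Chain order in the selection is trusted as the
#' protomer cyclic order, not inferred. Requires the bio3d package.
#'
#' @param file PDB path.
#' @param selection Data frame with columns `protomer`, `loop`, `chain`,
#'   `resno_start`, `resno_end` (inclusive residue range of the loop).
#' @return A `"pore_loop_set"` data frame.
#' @export
read_pore_loops_pdb <- function(file, selection) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("package `bio3d` is required for PDB import")
  need <- c("protomer", "loop", "chain", "resno_start", "resno_end")
  if (!all(need %in% names(selection)))
    stop("`selection` must have columns ", paste(need, collapse = ", "))
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  rows <- lapply(seq_len(nrow(selection)), function(i) {
    s <- selection[i, ]
    hit <- at$chain == s$chain & at$resno >= s$resno_start &
      at$resno <= s$resno_end & at$elety == "CA"
    if (!any(hit))
      stop(sprintf("no CA atoms for chain %s residues %d-%d",
                   s$chain, s$resno_start, s$resno_end))
    data.frame(protomer = s$protomer, loop = s$loop,
               x = mean(at$x[hit]), y = mean(at$y[hit]), z = mean(at$z[hit]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pore_loop_set", "data.frame")
  out
}

#' Export a trajectory event log as CSV
#'
#' Columns: `time`, `event`, `atp_cumulative`, `translocated_A_cumulative`.
#' Productive transitions (including substrate completions) advance both
#' counters; stall/escape/reengage events advance neither.
#'
#' @param traj A `"motor_trajectory"` from [simulate_motor()].
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  prod <- traj$event_kinds %in% c("transition", "substrate_complete")
  df <- data.frame(time = traj$event_times,
                   event = traj$event_kinds,
                   atp_cumulative = cumsum(prod) * traj$params$atp_per_step,
                   translocated_A_cumulative =
                     cumsum(prod) * traj$params$step_length)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export a model or escape fit as JSON
#'
#' @param fit A `"threshold_fit"`, `"escape_fit"` or `"helix_params"` object.
#' @param file JSON path.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  x <- unclass(fit)
  x$ring <- NULL
  x$fit <- NULL
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}
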