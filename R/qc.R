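#' Mean relative displacement of a motion trace
#'
#' Arithmetic mean over frames of the per-frame relative RMS displacement.
#'
#' @param trace Numeric vector of per-frame displacements (mm).
#' @return Mean displacement (mm).
#' @export
mean_relative_displacement <- function(trace) {
  if (length(trace) == 0L) stop("empty motion trace")
  if (any(trace < 0)) stop("displacements must be nonnegative")
  mean(trace)
}

#' Subject-level motion exclusion
#'
#' A subject is excluded when the mean relative RMS displacement over frames
#' exceeds 0.2 mm, or otherwise when at least 20 individual frames exceed
#' 0.25 mm.  The mean rule is evaluated first, so exactly one reason is
#' recorded per decision.
#'
#' @param trace Numeric vector of per-frame displacements (mm).
#' @param subject_id Identifier copied into the decision.
#' @param mean_limit Mean-displacement threshold (mm).
#' @param spike_limit Per-frame spike threshold (mm).
#' @param max_spikes Number of spike frames at which exclusion triggers.
#' @return A \code{qc_decision} list: \code{subject_id}, \code{included},
#'   \code{reason} (\code{ok}, \code{mean_displacement} or
#'   \code{frame_spikes}), \code{mean_displacement}, \code{spike_frames}.
#' @export
apply_exclusion <- function(trace, subject_id = NA_character_,
                            mean_limit = 0.2, spike_limit = 0.25,
                            max_spikes = 20L) {
  m <- mean_relative_displacement(trace)
  spikes <- sum(trace > spike_limit)
  if (m > mean_limit) {
    reason <- "mean_displacement"
  } else if (spikes >= max_spikes) {
    reason <- "frame_spikes"
  } else {
    reason <- "ok"
  }
  structure(list(subject_id = subject_id, included = reason == "ok",
                 reason = reason, mean_displacement = m,
                 spike_frames = as.integer(spikes)),
            class = "qc_decision")
}

#' Motion QC for a whole cohort
#'
#' @param motion Named list of motion traces (one per subject).
#' @param ... Threshold overrides passed to \code{\link{apply_exclusion}}.
#' @return Data frame with one QC decision row per subject.
#' @export
qc_cohort <- function(motion, ...) {
  rows <- lapply(names(motion), function(id) {
    d <- apply_exclusion(motion[[id]], subject_id = id, ...)
    data.frame(subject_id = d$subject_id, included = d$included,
               reason = d$reason, mean_displacement = d$mean_displacement,
               spike_frames = d$spike_frames, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
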