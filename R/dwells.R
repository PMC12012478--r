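#' Extract dwells from a state assignment
#'
#' Run-length encodes the Viterbi path into a dwell table; each dwell
#' carries its state, start time, duration and mean force computed from the
#' raw samples. Dwells shorter than \code{min_dwell} samples are treated as
#' sub-dead-time blips: their samples are merged into the preceding dwell
#' and adjacent same-state dwells are re-joined.
#'
#' @param assignment a \code{state_assignment} from [fit_hmm()], or an
#'   integer per-sample state vector.
#' @param trace the [ot_trace()] the assignment was computed from.
#' @param min_dwell minimum dwell length in samples (default 0: keep all;
#'   the package's dead-time default for kinetics is 3 samples).
#' @return data.frame of class \code{dwell_table} with columns
#'   \code{state}, \code{t_start}, \code{duration}, \code{mean_force};
#'   attribute \code{dt} holds the sampling interval.
#' @export
extract_dwells <- function(assignment, trace, min_dwell = 0) {
  path <- if (inherits(assignment, "state_assignment")) {
    assignment$path
  } else as.integer(assignment)
  stopifnot(length(path) == length(trace$force))
  dt <- trace_dt(trace)
  if (min_dwell > 0) {
    repeat {
      r <- rle(path)
      short <- which(r$lengths < min_dwell)
      short <- short[short > 1]          # first dwell has no predecessor
      if (!length(short)) break
      # absorb the shortest blip into its predecessor, then re-scan
      i <- short[which.min(r$lengths[short])]
      r$values[i] <- r$values[i - 1]
      path <- inverse.rle(r)
    }
  }
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  mf <- vapply(seq_along(starts), function(i) {
    mean(trace$force[starts[i]:ends[i]])
  }, numeric(1))
  out <- data.frame(state = r$values,
                    t_start = trace$time[starts],
                    duration = r$lengths * dt,
                    mean_force = mf)
  attr(out, "dt") <- dt
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' Segment a dwell table into protein-bound and unbound phases
#'
#' Identifies bound phases by the kinetic fingerprint of binding: strongly
#' stabilized dwells of the protein-binding-competent state. Candidate runs
#' are maximal stretches of consecutive dwells whose states all belong to
#' \code{c(state, allowed_states)}; a run is labeled bound if it contains
#' at least one dwell of \code{state} lasting at least \code{min_duration}
#' (and, when \code{force_band} is given, with mean force inside it).
#'
#' @param dwells a \code{dwell_table}.
#' @param criteria list with \code{state} (index of the stabilized state),
#'   \code{min_duration} (s), optional \code{force_band} (length-2 pN
#'   interval) and optional \code{allowed_states} (other states a bound
#'   phase may visit, e.g. a more-folded state reachable while bound).
#' @return the dwell table with an added \code{phase} column
#'   ("bound"/"unbound") plus attribute \code{phases}: a data.frame of
#'   contiguous phase intervals (\code{type}, \code{t_start}, \code{t_end},
#'   \code{duration}).
#' @export
segment_bound_phases <- function(dwells, criteria) {
  stopifnot(!is.null(criteria$state), !is.null(criteria$min_duration))
  s0 <- criteria$state
  if (!s0 %in% dwells$state) stop("criteria state ", s0, " not present")
  allowed <- unique(c(s0, criteria$allowed_states))
  in_run <- dwells$state %in% allowed
  run_id <- cumsum(c(TRUE, diff(in_run) != 0))
  anchor <- dwells$state == s0 & dwells$duration >= criteria$min_duration
  if (!is.null(criteria$force_band)) {
    anchor <- anchor & dwells$mean_force >= criteria$force_band[1] &
      dwells$mean_force <= criteria$force_band[2]
  }
  phase <- rep("unbound", nrow(dwells))
  for (id in unique(run_id[in_run])) {
    sel <- run_id == id
    if (any(anchor[sel])) phase[sel] <- "bound"
  }
  dwells$phase <- phase
  # contiguous phase intervals
  pr <- rle(phase)
  ends <- cumsum(pr$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  phases <- data.frame(
    type = pr$values,
    t_start = dwells$t_start[starts],
    t_end = dwells$t_start[ends] + dwells$duration[ends])
  phases$duration <- phases$t_end - phases$t_start
  attr(dwells, "phases") <- phases
  dwells
}
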