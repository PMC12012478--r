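#' Construct a force trace object
#'
#' Uniformly sampled passive-mode or constant-velocity force time series
#' with acquisition metadata, the container every analysis step consumes.
#' Synthetic traces additionally carry per-sample truth labels.
#'
#' @param time time grid, s (uniform).
#' @param force force, pN.
#' @param extension optional extension channel, nm.
#' @param sampling_hz raw acquisition rate, Hz (before downsampling).
#' @param downsample_factor integer downsampling factor applied to the raw
#'   rate; \code{time} is on the downsampled grid.
#' @param mode "passive" or "constant_velocity".
#' @param trap_separation trap separation, nm (scalar in passive mode, one
#'   value per sample for a ramp).
#' @param model optional [elastic_model()] the trace was recorded/simulated
#'   with.
#' @param truth_state optional per-sample true state name (synthetic).
#' @param truth_bound optional per-sample logical bound flag (synthetic).
#' @param truth_dwells optional true dwell table (synthetic; survives the
#'   sampling grid so sub-sample events remain quantifiable).
#' @return object of class \code{ot_trace}.
#' @export
ot_trace <- function(time, force, extension = NULL,
                     sampling_hz = 78125, downsample_factor = 3L,
                     mode = c("passive", "constant_velocity"),
                     trap_separation = NA_real_, model = NULL,
                     truth_state = NULL, truth_bound = NULL,
                     truth_dwells = NULL) {
  mode <- match.arg(mode)
  n <- length(time)
  stopifnot(length(force) == n, n >= 2)
  if (!all(is.finite(force))) stop("force must be finite")
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("time grid must be strictly increasing and uniform")
  }
  if (!is.null(truth_state) && length(truth_state) != n) {
    stop("truth_state must match the trace length")
  }
  if (!is.null(truth_bound) && length(truth_bound) != n) {
    stop("truth_bound must match the trace length")
  }
  structure(list(time = time, force = force, extension = extension,
                 sampling_hz = sampling_hz,
                 downsample_factor = as.integer(downsample_factor),
                 mode = mode, trap_separation = trap_separation,
                 model = model, truth_state = truth_state,
                 truth_bound = truth_bound, truth_dwells = truth_dwells),
            class = "ot_trace")
}

#' @export
print.ot_trace <- function(x, ...) {
  cat(sprintf(
    "ot_trace: %d samples, %.3f s, %s mode, %.0f Hz / %d = %.1f Hz\n",
    length(x$time), diff(range(x$time)), x$mode, x$sampling_hz,
    x$downsample_factor, x$sampling_hz / x$downsample_factor))
  cat(sprintf("  force: %.2f-%.2f pN%s\n", min(x$force), max(x$force),
              if (!is.null(x$truth_state)) "  [truth labels present]" else ""))
  invisible(x)
}

#' @export
length.ot_trace <- function(x) length(x$time)

# effective (stored) sampling interval, s
trace_dt <- function(trace) {
  trace$downsample_factor / trace$sampling_hz
}
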