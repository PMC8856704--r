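# Containers and per-session preprocessing for extracted fluorescence
# traces: sliding-window photobleaching correction (rolling-percentile
# baseline -> dF/F) and whole-session z-scoring.

#' Fluorescence trace matrix
#'
#' Container for extracted single-cell fluorescence: a neurons x frames
#' numeric matrix at a fixed frame rate, with the session's cue events
#' (frame index, trial type, outcome, day) attached.
#'
#' @param values numeric matrix, neurons as rows, frames as columns; all
#'   values must be finite.
#' @param frame_rate_hz acquisition rate in frames per second (default 20).
#' @param cue_events optional data frame with columns `frame_index`
#'   (1-based onset frame), `trial_type` (`"go"`/`"nogo"`), `outcome`,
#'   `day`.
#' @return A `trace_matrix` object.
#' @export
trace_matrix <- function(values, frame_rate_hz = 20, cue_events = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("trace error: `values` must be a finite numeric matrix",
         call. = FALSE)
  }
  if (length(frame_rate_hz) != 1L || frame_rate_hz <= 0) {
    stop("trace error: `frame_rate_hz` must be a single positive number",
         call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("neuron_%03d", seq_len(nrow(values)))
  }
  if (!is.null(cue_events)) {
    need <- c("frame_index", "trial_type", "outcome", "day")
    miss <- setdiff(need, names(cue_events))
    if (length(miss)) {
      stop("trace error: cue_events missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fi <- cue_events$frame_index
    if (any(fi < 1 | fi > ncol(values))) {
      stop("trace error: cue frame_index outside [1, n_frames]",
           call. = FALSE)
    }
  }
  structure(list(values = values,
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 cue_events = cue_events),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("Trace matrix: %d neurons x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              ncol(x$values) / x$frame_rate_hz))
  if (!is.null(x$cue_events)) {
    cat(sprintf("  %d cue events (%s)\n", nrow(x$cue_events),
                paste(names(table(x$cue_events$trial_type)),
                      table(x$cue_events$trial_type),
                      sep = ": ", collapse = ", ")))
  }
  invisible(x)
}

# rolling percentile baseline: exact quantiles on a regular grid of window
# centers (grid step ~ window/20), linearly interpolated between centers;
# windows are truncated at the session edges.
.rolling_percentile <- function(x, width, prob, step = NULL) {
  n <- length(x)
  if (is.null(step)) step <- max(1L, floor(width / 20))
  half <- floor(width / 2)
  centers <- unique(c(seq(1L, n, by = step), n))
  q <- vapply(centers, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' Sliding-window photobleaching correction (dF/F)
#'
#' Removes slow drift (photobleaching) from each neuron's trace by
#' estimating a running baseline as a rolling low percentile over a
#' centered window (truncated at the session edges), then converting to
#' fractional change in fluorescence: `dF/F = (F - baseline) / baseline`.
#'
#' @param trace a [trace_matrix()] of raw fluorescence.
#' @param window_s baseline window length in seconds (default 30).
#' @param percentile baseline percentile in (0, 50) (default 8).
#' @return A `trace_matrix` in dF/F units (cue events carried over).
#' @export
correct_drift <- function(trace, window_s = 30, percentile = 8) {
  stopifnot(inherits(trace, "trace_matrix"))
  fps <- trace$frame_rate_hz
  if (window_s < 1 / fps) {
    stop("drift error: `window_s` must be at least one frame", call. = FALSE)
  }
  if (percentile <= 0 || percentile >= 50) {
    stop("drift error: `percentile` must be in (0, 50)", call. = FALSE)
  }
  width <- max(1L, round(window_s * fps))
  v <- trace$values
  out <- v
  for (i in seq_len(nrow(v))) {
    b <- .rolling_percentile(v[i, ], width, percentile / 100)
    if (any(b <= 0)) {
      stop("drift error: baseline <= 0 for neuron ", rownames(v)[i],
           "; raise `percentile` or add an offset to the traces",
           call. = FALSE)
    }
    out[i, ] <- (v[i, ] - b) / b
  }
  res <- trace_matrix(out, fps, trace$cue_events)
  attr(res, "units") <- "dff"
  res
}

#' Whole-session z-scoring of traces
#'
#' Standardizes each neuron over the full session: `(x - mean(x)) / sd(x)`.
#' Neurons with zero variance carry no signal and are excluded with a
#' warning (their ids are recorded in `attr(, "excluded")`) rather than
#' propagating NaN.
#'
#' @param trace a [trace_matrix()] (typically dF/F from [correct_drift()]).
#' @return A `trace_matrix` of z-scored traces.
#' @export
zscore_traces <- function(trace) {
  stopifnot(inherits(trace, "trace_matrix"))
  v <- trace$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance neuron(s) excluded from z-scoring",
            call. = FALSE)
  }
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  res <- trace_matrix(z, trace$frame_rate_hz, trace$cue_events)
  attr(res, "units") <- "zscore"
  attr(res, "excluded") <- rownames(v)[!keep]
  res
}
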