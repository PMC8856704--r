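# Peri-cue analysis: alignment of z-scored traces to cue onsets, population
# median/MAD time courses, rank-sum screening of cue-modulated neurons, and
# normalized heat-map matrices sorted by peak latency.

#' Align traces to cue onsets
#'
#' Extracts a peri-cue window (default 3 s before to 10 s after onset) from
#' every cue event, producing a neurons x trials x samples tensor. At 20
#' frames/s with the default window each trial contributes
#' `round(3*20) + round(10*20) + 1 = 261` samples with cue onset at sample
#' 61 (time 0). Cues whose window does not fit inside the session are
#' dropped with a warning.
#'
#' @param trace a [trace_matrix()] with `cue_events` (typically z-scored).
#' @param pre_s,post_s window extent in seconds before/after cue onset.
#' @return An `aligned_tensor`: list with `z` (array neurons x trials x
#'   samples), `time_s` (sample axis, seconds relative to onset), `trials`
#'   (data frame of the retained cue events), `onset_index`,
#'   `frame_rate_hz`, and `n_dropped`.
#' @export
align_to_cues <- function(trace, pre_s = 3, post_s = 10) {
  stopifnot(inherits(trace, "trace_matrix"))
  cues <- trace$cue_events
  if (is.null(cues) || nrow(cues) == 0L) {
    stop("alignment error: no cue events attached to the trace matrix",
         call. = FALSE)
  }
  fps <- trace$frame_rate_hz
  n_pre <- as.integer(round(pre_s * fps))
  n_post <- as.integer(round(post_s * fps))
  n_samp <- n_pre + n_post + 1L
  n_frames <- ncol(trace$values)

  onset <- cues$frame_index
  ok <- onset - n_pre >= 1 & onset + n_post <= n_frames
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warning(n_dropped, " cue(s) dropped: peri-cue window outside session",
            call. = FALSE)
  }
  if (!any(ok)) {
    stop("alignment error: no cue has a full peri-cue window in the session",
         call. = FALSE)
  }
  cues <- cues[ok, , drop = FALSE]
  onset <- onset[ok]
  n_neur <- nrow(trace$values)
  n_tr <- length(onset)
  z <- array(NA_real_, dim = c(n_neur, n_tr, n_samp),
             dimnames = list(rownames(trace$values), NULL, NULL))
  offsets <- -n_pre:n_post
  for (j in seq_len(n_tr)) {
    z[, j, ] <- trace$values[, onset[j] + offsets]
  }
  structure(list(z = z,
                 time_s = offsets / fps,
                 trials = cues,
                 onset_index = n_pre + 1L,
                 frame_rate_hz = fps,
                 n_dropped = n_dropped),
            class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("Peri-cue tensor: %d neurons x %d trials x %d samples (%g..%g s)\n",
              d[1], d[2], d[3], min(x$time_s), max(x$time_s)))
  invisible(x)
}

.neuron_names <- function(tensor) {
  nm <- dimnames(tensor$z)[[1]]
  if (is.null(nm)) nm <- sprintf("neuron_%03d", seq_len(dim(tensor$z)[1]))
  nm
}

.select_neurons <- function(tensor, neurons) {
  n <- dim(tensor$z)[1]
  if (is.null(neurons)) return(seq_len(n))
  if (inherits(neurons, "modulation_result")) {
    return(which(neurons$modulated))
  }
  if (is.logical(neurons)) return(which(neurons))
  as.integer(neurons)
}

#' Population median (+/- MAD) peri-cue time course
#'
#' The standard population summary trace: at each peri-cue time sample,
#' the median over all selected neurons and trials of the z-scored dF/F,
#' with the median absolute deviation (MAD, unscaled) about that median. Optionally split by trial type, outcome (correct vs incorrect
#' response), or day.
#'
#' @param tensor an [align_to_cues()] result.
#' @param split_by `"none"`, `"trial_type"`, `"outcome"`, `"correct"`
#'   (hit/correct_rejection vs commission/omission), or `"day"`.
#' @param neurons neuron selection: `NULL` for all, an integer/logical
#'   vector, or a [detect_modulated()] result (its modulated set is used).
#' @return A `population_median` data frame: `level`, `time_s`, `median`,
#'   `mad`, `n_neurons`, `n_trials`. Split levels with no trials are absent
#'   from the result.
#' @export
population_median <- function(tensor,
                              split_by = c("none", "trial_type", "outcome",
                                           "correct", "day"),
                              neurons = NULL) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  split_by <- match.arg(split_by)
  nsel <- .select_neurons(tensor, neurons)
  if (length(nsel) == 0L) {
    stop("population error: empty neuron selection", call. = FALSE)
  }
  lab <- switch(split_by,
                none = rep("all", nrow(tensor$trials)),
                trial_type = as.character(tensor$trials$trial_type),
                outcome = as.character(tensor$trials$outcome),
                correct = ifelse(tensor$trials$outcome %in%
                                   c("hit", "correct_rejection"),
                                 "correct", "incorrect"),
                day = paste0("day_", tensor$trials$day))
  out <- lapply(sort(unique(lab)), function(lv) {
    tsel <- which(lab == lv)
    slab <- tensor$z[nsel, tsel, , drop = FALSE]
    med <- apply(slab, 3, stats::median)
    mad_ <- vapply(seq_along(med), function(k) {
      stats::median(abs(slab[, , k] - med[k]))
    }, numeric(1))
    data.frame(level = lv, time_s = tensor$time_s, median = med, mad = mad_,
               n_neurons = length(nsel), n_trials = length(tsel),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("population_median", "data.frame")
  attr(res, "split_by") <- split_by
  res
}

#' Plot a population median time course
#'
#' Base-graphics line plot of the median with a +/- MAD ribbon, one panel
#' overlaying all split levels.
#'
#' @param x a [population_median()] result.
#' @param ... passed to [plot()].
#' @export
plot.population_median <- function(x, ...) {
  levels_ <- unique(x$level)
  cols <- grDevices::hcl.colors(max(2L, length(levels_)), "Dark 2")
  rng <- range(x$median + x$mad, x$median - x$mad)
  plot(NA, xlim = range(x$time_s), ylim = rng,
       xlab = "time from cue onset (s)", ylab = "median z-scored dF/F", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  for (i in seq_along(levels_)) {
    d <- x[x$level == levels_[i], ]
    graphics::polygon(c(d$time_s, rev(d$time_s)),
                      c(d$median + d$mad, rev(d$median - d$mad)),
                      col = grDevices::adjustcolor(cols[i], 0.2),
                      border = NA)
    graphics::lines(d$time_s, d$median, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = levels_, col = cols[seq_along(levels_)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Screen for cue-modulated neurons (rank-sum test)
#'
#' For each neuron, compares per-trial mean activity in the pre-cue window
#' (times < 0) against the post-cue window (times >= 0) with a two-sided
#' Wilcoxon rank-sum test (exact for small untied samples, tie-corrected
#' normal approximation otherwise). A neuron is flagged cue-modulated when
#' its p value falls below the cutoff (default the stringent 1e-4 screen);
#' no correction beyond that fixed cutoff is applied unless requested.
#'
#' @param tensor an [align_to_cues()] result (>= 2 trials).
#' @param cutoff significance cutoff (default `1e-4`).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment of the p values before thresholding.
#' @return A `modulation_result` data frame: `neuron`, `p_value`,
#'   `modulated`, `direction` (`"up"`/`"down"`, sign of the post-pre median
#'   difference).
#' @export
detect_modulated <- function(tensor, cutoff = 1e-4,
                             adjust = c("none", "BH")) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  adjust <- match.arg(adjust)
  d <- dim(tensor$z)
  if (d[2] < 2L) {
    stop("modulation error: need >= 2 trials", call. = FALSE)
  }
  pre <- tensor$time_s < 0
  post <- tensor$time_s >= 0
  p <- numeric(d[1])
  dir_ <- character(d[1])
  for (i in seq_len(d[1])) {
    M <- tensor$z[i, , ]
    pre_m <- rowMeans(M[, pre, drop = FALSE])
    post_m <- rowMeans(M[, post, drop = FALSE])
    if (max(pre_m, post_m) == min(pre_m, post_m)) {
      p[i] <- 1
      dir_[i] <- "up"
      next
    }
    wt <- suppressWarnings(
      stats::wilcox.test(post_m, pre_m, alternative = "two.sided"))
    p[i] <- min(wt$p.value, 1)
    dir_[i] <- if (stats::median(post_m) >= stats::median(pre_m)) "up"
               else "down"
  }
  p_use <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  res <- data.frame(neuron = .neuron_names(tensor),
                    p_value = p_use,
                    modulated = p_use < cutoff,
                    direction = dir_,
                    stringsAsFactors = FALSE)
  class(res) <- c("modulation_result", "data.frame")
  attr(res, "cutoff") <- cutoff
  attr(res, "adjust") <- adjust
  res
}

#' Normalized per-neuron heat-map matrix
#'
#' For each selected neuron (by default the cue-modulated set), computes the
#' trial-median peri-cue time course and scales it by its maximum absolute
#' value, so every row lies in [-1, 1] with at least one entry of magnitude
#' 1. Rows are ordered by peak latency (time of maximum absolute response,
#' ascending), which makes between-day synchronization visible. All-zero
#' rows are left as zeros and flagged.
#'
#' @param tensor an [align_to_cues()] result.
#' @param neurons neuron selection (see [population_median()]); typically a
#'   [detect_modulated()] result.
#' @return A `gonogo_heatmap` matrix (rows = neurons in plot order) with
#'   attributes `time_s`, `peak_latency_s`, `order` (original indices) and
#'   `zero_rows`.
#' @export
heatmap_matrix <- function(tensor, neurons = NULL) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  nsel <- .select_neurons(tensor, neurons)
  if (length(nsel) == 0L) {
    stop("heatmap error: no neurons selected (no modulated neurons?)",
         call. = FALSE)
  }
  n_samp <- dim(tensor$z)[3]
  rows <- t(vapply(nsel, function(i) {
    apply(tensor$z[i, , , drop = FALSE], 3, stats::median)
  }, numeric(n_samp)))
  peak_amp <- apply(abs(rows), 1, max)
  zero_rows <- peak_amp == 0
  norm <- rows
  norm[!zero_rows, ] <- rows[!zero_rows, , drop = FALSE] /
    peak_amp[!zero_rows]
  peak_idx <- apply(abs(norm), 1, which.max)
  # zero rows have no peak: they sort last and get NA latency
  ord <- order(ifelse(zero_rows, Inf, peak_idx))
  out <- norm[ord, , drop = FALSE]
  rownames(out) <- .neuron_names(tensor)[nsel][ord]
  lat <- tensor$time_s[peak_idx]
  lat[zero_rows] <- NA_real_
  structure(out,
            class = c("gonogo_heatmap", "matrix"),
            time_s = tensor$time_s,
            peak_latency_s = lat[ord],
            order = nsel[ord],
            zero_rows = zero_rows[ord])
}

#' Plot a heat-map matrix
#'
#' @param x a [heatmap_matrix()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.gonogo_heatmap <- function(x, ...) {
  time_s <- attr(x, "time_s")
  m <- unclass(x)
  graphics::image(time_s, seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(65, "Blue-Red 3"),
                  xlab = "time from cue onset (s)", ylab = "neuron (sorted)",
                  ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
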