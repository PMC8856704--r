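# Synthetic fluorescence generator with known ground truth. Each neuron
# fires Poisson transient events at a background rate; a modulated subset
# fires at `effect_gain` times that rate inside a window after every cue.
# Events are convolved with an amplitude-normalized double-exponential
# kernel with GCaMP6f-like rise/decay constants, Gaussian noise is added on
# top of a positive baseline offset, and the whole trace is multiplied by a
# single-exponential photobleaching curve.

#' Specification for a synthetic calcium session
#'
#' @param n_neurons,n_frames matrix dimensions.
#' @param frame_rate_hz frames per second (default 20).
#' @param baseline_rate_hz background transient rate per neuron (events/s).
#' @param frac_modulated fraction of neurons with a cue-locked response;
#'   exactly `round(frac_modulated * n_neurons)` neurons are modulated.
#' @param effect_gain multiplicative event-rate gain inside the post-cue
#'   window for modulated neurons (1 = no effect).
#' @param cue_window_s length of the elevated-rate window after each cue
#'   (default 10 s, the full post-cue analysis window).
#' @param rise_tau_s,decay_tau_s kernel time constants in seconds (defaults
#'   0.07 / 0.7, fast-indicator-like); must satisfy `rise < decay`.
#' @param transient_amplitude peak amplitude of one transient in baseline
#'   fluorescence units.
#' @param noise_sd additive Gaussian noise SD (same units).
#' @param baseline_f0 positive baseline fluorescence offset.
#' @param bleach_tau_s photobleaching time constant in seconds; 0 disables
#'   bleaching.
#' @param cue_frames integer vector of cue-onset frames (1-based).
#' @param cue_labels optional data frame with one row per cue
#'   (`trial_type`, `outcome`, `day`); defaults to alternating go/no-go
#'   trials with matching correct outcomes on day 1.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A `calcium_sim_spec` object.
#' @export
calcium_sim_spec <- function(n_neurons = 100L, n_frames = 36000L,
                             frame_rate_hz = 20,
                             baseline_rate_hz = 0.15,
                             frac_modulated = 0.1,
                             effect_gain = 3,
                             cue_window_s = 10,
                             rise_tau_s = 0.07, decay_tau_s = 0.7,
                             transient_amplitude = 0.6,
                             noise_sd = 0.05,
                             baseline_f0 = 1,
                             bleach_tau_s = 0,
                             cue_frames = integer(0),
                             cue_labels = NULL,
                             seed = 1L) {
  chk_pos <- function(x, name, strict = TRUE) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
        (strict && x <= 0) || (!strict && x < 0)) {
      stop(sprintf("sim-spec error: `%s` must be %s 0", name,
                   if (strict) ">" else ">="), call. = FALSE)
    }
  }
  chk_pos(n_neurons, "n_neurons"); chk_pos(n_frames, "n_frames")
  chk_pos(frame_rate_hz, "frame_rate_hz")
  chk_pos(baseline_rate_hz, "baseline_rate_hz", strict = FALSE)
  chk_pos(effect_gain, "effect_gain", strict = FALSE)
  chk_pos(cue_window_s, "cue_window_s")
  chk_pos(rise_tau_s, "rise_tau_s"); chk_pos(decay_tau_s, "decay_tau_s")
  chk_pos(transient_amplitude, "transient_amplitude", strict = FALSE)
  chk_pos(noise_sd, "noise_sd", strict = FALSE)
  chk_pos(baseline_f0, "baseline_f0")
  chk_pos(bleach_tau_s, "bleach_tau_s", strict = FALSE)
  if (frac_modulated < 0 || frac_modulated > 1) {
    stop("sim-spec error: `frac_modulated` must be in [0, 1]", call. = FALSE)
  }
  if (rise_tau_s >= decay_tau_s) {
    stop("sim-spec error: `rise_tau_s` must be < `decay_tau_s`",
         call. = FALSE)
  }
  cue_frames <- as.integer(cue_frames)
  if (length(cue_frames) &&
      (any(cue_frames < 1) || any(cue_frames > n_frames))) {
    stop("sim-spec error: `cue_frames` outside [1, n_frames]", call. = FALSE)
  }
  if (!is.null(cue_labels) && nrow(cue_labels) != length(cue_frames)) {
    stop("sim-spec error: `cue_labels` must have one row per cue frame",
         call. = FALSE)
  }
  structure(list(n_neurons = as.integer(n_neurons),
                 n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz,
                 baseline_rate_hz = baseline_rate_hz,
                 frac_modulated = frac_modulated,
                 effect_gain = effect_gain,
                 cue_window_s = cue_window_s,
                 rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 transient_amplitude = transient_amplitude,
                 noise_sd = noise_sd,
                 baseline_f0 = baseline_f0,
                 bleach_tau_s = bleach_tau_s,
                 cue_frames = cue_frames,
                 cue_labels = cue_labels,
                 seed = as.integer(seed)),
            class = "calcium_sim_spec")
}

# amplitude-normalized double-exponential transient kernel sampled at fps;
# peak amplitude is 1 regardless of frame rate
.transient_kernel <- function(rise_tau_s, decay_tau_s, fps) {
  t <- seq(0, 7 * decay_tau_s, by = 1 / fps)
  k <- exp(-t / decay_tau_s) - exp(-t / rise_tau_s)
  k / max(k)
}

# causal convolution of an event-count vector with a kernel. FFT-based,
# zero-padded to a 5-smooth length so the transform stays O(n log n) for
# arbitrary trace lengths.
.convolve_events <- function(counts, kernel) {
  n <- length(counts)
  m <- length(kernel)
  N <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  fx <- stats::fft(c(counts, numeric(N - n)))
  fk <- stats::fft(c(kernel, numeric(N - m)))
  out <- Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n)] / N
  # FFT round-off can leave tiny negative values where the signal is zero
  out[abs(out) < 1e-12] <- 0
  out
}

#' Generate a synthetic calcium session with ground truth
#'
#' @param spec a [calcium_sim_spec()].
#' @return List with `trace` (a [trace_matrix()]) and `truth` (a
#'   `calcium_truth`: `modulated_ids` (integer indices), `rate_gain`
#'   per neuron, `event_times` per neuron in seconds, and the generating
#'   spec).
#' @examples
#' spec <- calcium_sim_spec(n_neurons = 10, n_frames = 2000,
#'                          cue_frames = c(300, 800, 1300), seed = 3)
#' sim <- simulate_calcium(spec)
#' sim$trace
#' sim$truth$modulated_ids
#' @export
simulate_calcium <- function(spec) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  set.seed(spec$seed)
  fps <- spec$frame_rate_hz
  n <- spec$n_neurons
  nf <- spec$n_frames
  T_s <- nf / fps
  n_mod <- round(spec$frac_modulated * n)
  modulated_ids <- if (n_mod > 0) sort(sample.int(n, n_mod)) else integer(0)
  kernel <- .transient_kernel(spec$rise_tau_s, spec$decay_tau_s, fps)
  bleach <- if (spec$bleach_tau_s > 0) {
    exp(-(seq_len(nf) - 1) / (fps * spec$bleach_tau_s))
  } else {
    rep(1, nf)
  }
  cue_t <- (spec$cue_frames - 1) / fps
  W <- spec$cue_window_s

  values <- matrix(0, n, nf)
  event_times <- vector("list", n)
  for (i in seq_len(n)) {
    n_base <- stats::rpois(1, spec$baseline_rate_hz * T_s)
    times <- stats::runif(n_base, 0, T_s)
    if (i %in% modulated_ids && spec$effect_gain > 1 && length(cue_t)) {
      extra_rate <- (spec$effect_gain - 1) * spec$baseline_rate_hz
      for (ct in cue_t) {
        w_hi <- min(ct + W, T_s)
        if (w_hi <= ct) next
        n_extra <- stats::rpois(1, extra_rate * (w_hi - ct))
        times <- c(times, stats::runif(n_extra, ct, w_hi))
      }
    }
    times <- sort(times)
    event_times[[i]] <- times
    counts <- tabulate(pmin(nf, floor(times * fps) + 1L), nbins = nf)
    signal <- if (length(times)) .convolve_events(counts, kernel)
              else numeric(nf)
    values[i, ] <- (spec$baseline_f0 +
                      spec$transient_amplitude * signal +
                      stats::rnorm(nf, 0, spec$noise_sd)) * bleach
  }
  rownames(values) <- sprintf("neuron_%03d", seq_len(n))

  cue_events <- NULL
  if (length(spec$cue_frames)) {
    labels <- spec$cue_labels
    if (is.null(labels)) {
      tt <- rep(c("go", "nogo"), length.out = length(spec$cue_frames))
      labels <- data.frame(
        trial_type = tt,
        outcome = ifelse(tt == "go", "hit", "correct_rejection"),
        day = 1L, stringsAsFactors = FALSE)
    }
    cue_events <- cbind(data.frame(frame_index = spec$cue_frames), labels)
  }
  rate_gain <- rep(1, n)
  rate_gain[modulated_ids] <- spec$effect_gain
  truth <- structure(list(modulated_ids = modulated_ids,
                          rate_gain = rate_gain,
                          event_times = event_times,
                          bleach_tau_s = spec$bleach_tau_s,
                          baseline_f0 = spec$baseline_f0,
                          spec = spec),
                     class = "calcium_truth")
  list(trace = trace_matrix(values, fps, cue_events), truth = truth)
}

#' @export
print.calcium_truth <- function(x, ...) {
  cat(sprintf("Synthetic calcium truth: %d/%d modulated neurons, gain %.2g\n",
              length(x$modulated_ids), x$spec$n_neurons, x$spec$effect_gain))
  invisible(x)
}
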