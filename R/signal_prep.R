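# Signal preparation: raw sEMG + gait events -> per-stride, amplitude
# normalized envelope matrices and 200-point time-normalized profiles.

#' Multichannel sEMG recording
#'
#' @param samples numeric matrix, muscles x time samples.
#' @param muscle_labels one label per channel.
#' @param fs sampling rate in Hz.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, muscle_labels = rownames(samples), fs = 1000) {
  abort_if(!is.matrix(samples) || !is.numeric(samples),
           "samples must be a numeric matrix (muscles x time)")
  abort_if(is.null(muscle_labels), "muscle labels are required")
  abort_if(length(muscle_labels) != nrow(samples),
           "got %d labels for %d channels", length(muscle_labels), nrow(samples))
  abort_if(fs <= 0, "fs must be positive")
  rownames(samples) <- muscle_labels
  structure(list(samples = samples, muscle_labels = muscle_labels, fs = fs),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Stride-wise gait event table
#'
#' Each stride of the reference (instrumented) leg is described by five
#' event times in seconds: reference heel strike (`HS_ref`), contralateral
#' toe off (`TO_contra`), contralateral heel strike (`HS_contra`), reference
#' toe off (`TO_ref`) and the next reference heel strike (`HS_ref_next`).
#'
#' @param df data.frame with columns `stride_id`, `HS_ref`, `TO_contra`,
#'   `HS_contra`, `TO_ref`, `HS_ref_next`.
#' @return an object of class `gait_events`.
#' @export
gait_events <- function(df) {
  cols <- c("stride_id", "HS_ref", "TO_contra", "HS_contra", "TO_ref", "HS_ref_next")
  abort_if(!all(cols %in% names(df)), "event table must have columns: %s",
           paste(cols, collapse = ", "))
  df <- as.data.frame(df)[cols]
  abort_if(nrow(df) == 0, "event table is empty")
  for (i in seq_len(nrow(df))) {
    tms <- as.numeric(df[i, -1])
    abort_if(any(diff(tms) <= 0),
             "events of stride %s are not strictly increasing", df$stride_id[i])
  }
  starts <- df$HS_ref
  ends <- df$HS_ref_next
  abort_if(nrow(df) > 1 && any(starts[-1] < ends[-nrow(df)] - 1e-12),
           "strides overlap")
  structure(df, class = c("gait_events", "data.frame"))
}

#' Split gait events into the four sub-phases of each stride
#'
#' Phases are half-open, contiguous intervals: DS1 = `[HS_ref, TO_contra)`,
#' Stance = `[TO_contra, HS_contra)`, DS2 = `[HS_contra, TO_ref)`, Swing =
#' `[TO_ref, HS_ref_next)`.
#'
#' @param events a [gait_events()] table.
#' @return an object of class `stride_phases`: a data.frame with one row per
#'   (stride, phase) holding `stride_id`, `phase`, `start`, `end` (seconds).
#' @export
parse_phases <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  phase_names <- c("DS1", "Stance", "DS2", "Swing")
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    tms <- as.numeric(events[i, c("HS_ref", "TO_contra", "HS_contra",
                                  "TO_ref", "HS_ref_next")])
    data.frame(stride_id = events$stride_id[i],
               phase = factor(phase_names, levels = phase_names),
               start = tms[1:4], end = tms[2:5])
  }))
  structure(out, class = c("stride_phases", "data.frame"))
}

#' Zero-phase Butterworth band-pass filter an sEMG recording
#'
#' Each channel is filtered forward and backward with a Butterworth
#' band-pass (default 35-450 Hz, 4th-order prototype), removing motion
#' artefact and out-of-band noise without phase distortion — timing of the
#' envelopes feeds phase-resolved statistics downstream, so zero phase
#' matters.
#'
#' @param rec an [emg_recording()].
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth prototype order.
#' @return a filtered [emg_recording()] of identical dimensions.
#' @export
bandpass_filter <- function(rec, low_hz = 35, high_hz = 450, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  flt <- butter_bandpass(order, low_hz, high_hz, rec$fs)
  out <- rec
  for (m in seq_len(nrow(rec$samples))) {
    out$samples[m, ] <- filtfilt_sos(rec$samples[m, ], flt)
  }
  out
}

# Moving RMS with a centered window; edges use the truncated window.
moving_rms <- function(x, w) {
  n <- length(x)
  abort_if(w > n, "RMS window (%d samples) is longer than the signal (%d)", w, n)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Estimate sEMG envelopes
#'
#' `fixed_rms` is a moving RMS with the stated window. `adaptive_rms`
#' selects, per sample, a window from the dyadic ladder 25/50/100/200/400 ms
#' minimizing an estimated bias^2 + variance criterion: bias is estimated as
#' the squared difference from the shortest-window (least biased) estimate,
#' and the variance of an RMS estimate over N samples is approximated by
#' RMS^2 / (2N). Longer windows are thus preferred where the amplitude is
#' stationary and shorter ones where it changes quickly.
#'
#' @param rec a band-pass filtered [emg_recording()].
#' @param method `"fixed_rms"` (default) or `"adaptive_rms"`.
#' @param window_ms RMS window for `fixed_rms`, in milliseconds.
#' @return an [emg_recording()] whose channels are nonnegative envelopes.
#' @export
compute_envelope <- function(rec, method = c("fixed_rms", "adaptive_rms"),
                             window_ms = 100) {
  stopifnot(inherits(rec, "emg_recording"))
  method <- match.arg(method)
  out <- rec
  n <- ncol(rec$samples)
  if (method == "fixed_rms") {
    w <- max(round(window_ms / 1000 * rec$fs), 1)
    for (m in seq_len(nrow(rec$samples))) {
      out$samples[m, ] <- moving_rms(rec$samples[m, ], w)
    }
  } else {
    ladder_ms <- c(25, 50, 100, 200, 400)
    ws <- pmax(round(ladder_ms / 1000 * rec$fs), 1)
    ws <- ws[ws <= n]
    abort_if(length(ws) == 0, "signal shorter than the smallest RMS window")
    for (m in seq_len(nrow(rec$samples))) {
      x <- rec$samples[m, ]
      est <- vapply(ws, function(w) moving_rms(x, w), numeric(n))
      crit <- vapply(seq_along(ws), function(j) {
        (est[, j] - est[, 1])^2 + est[, j]^2 / (2 * ws[j])
      }, numeric(n))
      pick <- max.col(-crit, ties.method = "first")
      out$samples[m, ] <- est[cbind(seq_len(n), pick)]
    }
  }
  out
}

#' Cut an envelope recording into a concatenated per-stride matrix
#'
#' @param rec an [emg_recording()] holding envelopes.
#' @param events a [gait_events()] table.
#' @return an object of class `envelope_matrix`: `values` (muscles x
#'   samples, strides concatenated), `stride_boundaries` (cumulative end
#'   index of each stride), `stride_starts_s` (original stride start times),
#'   `fs`, `muscle_labels`.
#' @export
segment_strides <- function(rec, events) {
  stopifnot(inherits(rec, "emg_recording"), inherits(events, "gait_events"))
  n <- ncol(rec$samples)
  blocks <- list()
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$HS_ref[i] * rec$fs) + 1
    i1 <- round(events$HS_ref_next[i] * rec$fs)
    abort_if(i0 < 1 || i1 > n,
             "stride %s [%g, %g] s lies outside the recording",
             events$stride_id[i], events$HS_ref[i], events$HS_ref_next[i])
    blocks[[i]] <- rec$samples[, i0:i1, drop = FALSE]
  }
  values <- do.call(cbind, blocks)
  structure(list(values = values,
                 stride_boundaries = cumsum(vapply(blocks, ncol, integer(1))),
                 stride_starts_s = events$HS_ref,
                 fs = rec$fs, muscle_labels = rec$muscle_labels),
            class = "envelope_matrix")
}

# Wrap an already-concatenated matrix (e.g. activation coefficients aligned
# with an envelope_matrix) in the same container.
as_envelope_matrix <- function(values, like, labels = rownames(values)) {
  stopifnot(inherits(like, "envelope_matrix"))
  abort_if(ncol(values) != utils::tail(like$stride_boundaries, 1),
           "matrix width does not match the stride boundaries")
  structure(list(values = values, stride_boundaries = like$stride_boundaries,
                 stride_starts_s = like$stride_starts_s, fs = like$fs,
                 muscle_labels = labels %||% paste0("row", seq_len(nrow(values)))),
            class = "envelope_matrix")
}

stride_index_ranges <- function(env) {
  ends <- env$stride_boundaries
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(a, b) a:b, starts, ends)
}

#' Normalize envelope amplitude to the median per-stride peak
#'
#' Each muscle's envelope is divided by the median, across strides, of that
#' muscle's per-stride maximum, so a typical stride peaks at 1 for every
#' muscle.
#'
#' @param env an [segment_strides()] envelope matrix.
#' @return the normalized `envelope_matrix`; the divisors are attached as
#'   attribute `"divisors"`.
#' @export
normalize_amplitude <- function(env) {
  stopifnot(inherits(env, "envelope_matrix"))
  ranges <- stride_index_ranges(env)
  peaks <- vapply(ranges, function(idx)
    apply(env$values[, idx, drop = FALSE], 1, max), numeric(nrow(env$values)))
  if (is.null(dim(peaks))) peaks <- matrix(peaks, nrow = nrow(env$values))
  div <- apply(peaks, 1, stats::median)
  zero <- div <= 0
  abort_if(any(zero), "muscle(s) %s have an all-zero envelope (median peak 0)",
           paste(env$muscle_labels[zero], collapse = ", "))
  env$values <- env$values / div
  attr(env, "divisors") <- stats::setNames(div, env$muscle_labels)
  env
}

#' Time-normalize strides onto the 200-sample gait-cycle scale
#'
#' Each sub-phase of each stride is linearly resampled to a fixed sample
#' count (DS1 = 20, Stance = 80, DS2 = 20, Swing = 80) and the blocks are
#' concatenated to a 200-point profile; the subject's mean profile is the
#' average across strides.
#'
#' @param env an `envelope_matrix` (envelopes or activation coefficients).
#' @param phases a [parse_phases()] table covering the same strides.
#' @param samples_per_phase sample counts for DS1, Stance, DS2, Swing.
#' @return an object of class `normalized_profile`: `profiles` (array rows x
#'   200 x strides), `mean` (rows x 200), `samples_per_phase`, `labels`.
#' @export
time_normalize <- function(env, phases, samples_per_phase = c(20, 80, 20, 80)) {
  stopifnot(inherits(env, "envelope_matrix"), inherits(phases, "stride_phases"))
  abort_if(length(samples_per_phase) != 4 || any(samples_per_phase < 2),
           "samples_per_phase must be 4 counts >= 2")
  ranges <- stride_index_ranges(env)
  stride_ids <- unique(phases$stride_id)
  abort_if(length(stride_ids) != length(ranges),
           "phase table covers %d strides but the matrix has %d",
           length(stride_ids), length(ranges))
  total <- sum(samples_per_phase)
  nr <- nrow(env$values)
  prof <- array(NA_real_, dim = c(nr, total, length(ranges)))
  for (s in seq_along(ranges)) {
    idx <- ranges[[s]]
    ph <- phases[phases$stride_id == stride_ids[s], ]
    t0 <- env$stride_starts_s[s]
    # phase boundaries as local sample offsets within the stride block
    bnd <- round((c(ph$start[1], ph$end) - t0) * env$fs)
    bnd[1] <- 0L
    bnd[5] <- length(idx)
    abort_if(any(diff(bnd) < 2),
             "stride %s has an empty or single-sample phase segment", stride_ids[s])
    col0 <- 0L
    for (p in 1:4) {
      seg <- idx[(bnd[p] + 1):bnd[p + 1]]
      m <- samples_per_phase[p]
      grid <- seq(1, length(seg), length.out = m)
      for (r in seq_len(nr)) {
        prof[r, (col0 + 1):(col0 + m), s] <-
          stats::approx(seq_along(seg), env$values[r, seg], xout = grid)$y
      }
      col0 <- col0 + m
    }
  }
  structure(list(profiles = prof,
                 mean = apply(prof, c(1, 2), mean),
                 samples_per_phase = samples_per_phase,
                 labels = env$muscle_labels),
            class = "normalized_profile")
}
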