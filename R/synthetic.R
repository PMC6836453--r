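# Synthetic gait sEMG generator.
#
# Produces multi-subject, multi-stride recordings from known ground-truth
# synergies so that every downstream stage (envelope estimation, NNMF,
# cross-validation, phase statistics) can be verified against a known
# answer. Muscle activity follows the synchronous synergy model: a fixed
# 12 x N matrix of nonnegative spatial weights W, activated by per-stride
# time profiles H built from Gaussian bumps locked to the gait cycle.

MUSCLES_12 <- c("RF", "VL", "VM", "GLU_MED", "TFL", "ST",
                "BF", "TA", "PL", "SOL", "GL", "GAS_MED")

#' Construct a ground-truth synergy template
#'
#' @param W nonnegative matrix, muscles x synergies; columns are rescaled to
#'   unit Euclidean norm.
#' @param bumps list with one element per synergy; each element a data.frame
#'   with columns `center` (fraction of the gait cycle in `[0, 1)`), `width`
#'   (fraction, the Gaussian SD) and `amplitude` (nonnegative).
#' @param muscle_labels character vector of muscle names (rows of `W`).
#' @return an object of class `synergy_template`.
#' @export
synergy_template <- function(W, bumps, muscle_labels = rownames(W)) {
  abort_if(!is.matrix(W) || any(W < 0), "W must be a nonnegative matrix")
  abort_if(length(muscle_labels) != nrow(W), "one label per row of W is required")
  abort_if(length(bumps) != ncol(W), "one bump list per synergy is required")
  for (b in bumps) {
    abort_if(!all(c("center", "width", "amplitude") %in% names(b)),
             "each bump table needs center, width, amplitude columns")
    abort_if(any(b$center < 0 | b$center >= 1), "bump centers must lie in [0, 1)")
    abort_if(any(b$width <= 0), "bump widths must be positive")
    abort_if(any(b$amplitude < 0), "bump amplitudes must be nonnegative")
  }
  nrm <- sqrt(colSums(W^2))
  abort_if(any(nrm == 0), "W has an all-zero synergy column")
  W <- sweep(W, 2, nrm, "/")
  dimnames(W) <- list(muscle_labels, paste0("S", seq_len(ncol(W))))
  structure(list(W = W, bumps = bumps, muscle_labels = muscle_labels),
            class = "synergy_template")
}

#' Packaged 12-muscle, 4-synergy gait template
#'
#' The default ground truth encodes the canonical functional groupings of
#' level walking: synergy 1 loads the knee extensors (RF, VL, VM) and
#' gluteus medius with a bump in early stance (weight acceptance); synergy 2
#' loads the calf muscles (PL, SOL, GL, GAS_MED) with a bump in late stance
#' (support and propulsion before toe-off); synergy 3 loads TFL with minor
#' knee-extensor, TA and PL contributions and bumps in early stance and
#' swing; synergy 4 loads the hamstrings (ST, BF) and TA with a bump in late
#' swing (leg deceleration). Bump amplitudes are chosen so that the four
#' synergies contribute commensurate signal energy, making the generative
#' order recoverable by a variance criterion.
#'
#' Note on labels: gluteus medius and gastrocnemius medialis share the
#' abbreviation "GM" in parts of the gait literature; here they are kept
#' distinct as `GLU_MED` and `GAS_MED`.
#'
#' @return a [synergy_template()].
#' @export
default_template <- function() {
  W <- matrix(0, nrow = 12, ncol = 4, dimnames = list(MUSCLES_12, NULL))
  #            S1    S2    S3    S4
  W["RF", ]      <- c(0.85, 0.00, 0.08, 0.00)
  W["VL", ]      <- c(0.90, 0.00, 0.00, 0.00)
  W["VM", ]      <- c(0.90, 0.00, 0.00, 0.00)
  W["GLU_MED", ] <- c(0.65, 0.00, 0.00, 0.00)
  W["TFL", ]     <- c(0.00, 0.00, 1.00, 0.00)
  W["ST", ]      <- c(0.00, 0.00, 0.00, 0.85)
  W["BF", ]      <- c(0.00, 0.00, 0.00, 0.90)
  W["TA", ]      <- c(0.00, 0.00, 0.10, 0.55)
  W["PL", ]      <- c(0.00, 0.80, 0.15, 0.00)
  W["SOL", ]     <- c(0.00, 0.90, 0.00, 0.00)
  W["GL", ]      <- c(0.00, 0.90, 0.00, 0.00)
  W["GAS_MED", ] <- c(0.00, 0.90, 0.00, 0.00)
  bumps <- list(
    # early stance, weight acceptance
    data.frame(center = 0.11, width = 0.05, amplitude = 1.0),
    # late stance, propulsion before toe-off
    data.frame(center = 0.44, width = 0.05, amplitude = 1.0),
    # biphasic: brief weight-acceptance burst + broad swing activity
    data.frame(center = c(0.01, 0.65), width = c(0.025, 0.12),
               amplitude = c(0.2, 1.2)),
    # late swing deceleration
    data.frame(center = 0.94, width = 0.055, amplitude = 1.0)
  )
  synergy_template(W, bumps)
}

# Periodic Gaussian bump evaluated at cycle fractions phi in [0, 1): the
# bump is wrapped at the cycle boundary so late-swing activity continues
# into the next stride's first samples.
bump_profile <- function(phi, center, width, amplitude) {
  amplitude * (exp(-(phi - center)^2 / (2 * width^2)) +
               exp(-(phi - center - 1)^2 / (2 * width^2)) +
               exp(-(phi - center + 1)^2 / (2 * width^2)))
}

#' Generate one stride of ground-truth activations and envelopes
#'
#' @param template a [synergy_template()].
#' @param phase_durations numeric length-4 vector of sub-phase durations in
#'   seconds (DS1, Stance, DS2, Swing).
#' @param fs sampling rate in Hz.
#' @return list with `H` (synergies x samples activation matrix), `envelope`
#'   (muscles x samples, equal to `W %*% H`), `n_samples`, and
#'   `phase_boundaries` (sample counts at the ends of the four phases).
#' @export
generate_stride <- function(template, phase_durations, fs = 1000) {
  abort_if(length(phase_durations) != 4 || any(phase_durations <= 0),
           "phase_durations must be 4 positive durations in seconds")
  total <- sum(phase_durations)
  n <- round(total * fs)
  abort_if(n < 4, "stride too short at this sampling rate")
  phi <- (seq_len(n) - 1) / n
  k <- ncol(template$W)
  H <- matrix(0, nrow = k, ncol = n)
  for (i in seq_len(k)) {
    b <- template$bumps[[i]]
    for (j in seq_len(nrow(b))) {
      H[i, ] <- H[i, ] + bump_profile(phi, b$center[j], b$width[j], b$amplitude[j])
    }
  }
  rownames(H) <- colnames(template$W)
  bounds <- round(cumsum(phase_durations) / total * n)
  bounds[4] <- n
  list(H = H, envelope = template$W %*% H, n_samples = n,
       phase_boundaries = bounds)
}

#' Cohort simulation settings
#'
#' Defaults describe a realistic desk-scale gait study: 12 subjects, 8
#' analysable strides each (matching the roughly 8 clean central strides per
#' subject a short walkway yields), strides of 1.2 +/- 0.1 s (typical of
#' slow-to-comfortable adult walking), sub-phases at 12/38/12/38% of the
#' cycle, envelopes at 1000 Hz and 20 dB SNR.
#'
#' @param n_subjects subjects in the group.
#' @param strides_per_subject strides recorded per subject.
#' @param stride_duration_mean,stride_duration_sd stride duration (s).
#' @param phase_fractions 4 nonnegative fractions summing to 1 (DS1, Stance,
#'   DS2, Swing).
#' @param snr_db per-channel signal-to-noise ratio in dB; `Inf` for clean.
#' @param subject_perturbation_sd SD of the Gaussian perturbation applied to
#'   the template weights per subject (entries are rectified and columns
#'   renormalized).
#' @param group_effect `"none"` or `"tf_like"`; the latter prolongs the calf
#'   synergy's activity across stance and both double supports and adds a
#'   hamstrings bump around the contralateral heel strike, mimicking the
#'   activation changes reported for trans-femoral prosthetic gait.
#' @param sampling_rate_hz sampling rate.
#' @param mode `"envelope"` (channels are envelopes) or `"raw"` (envelopes
#'   amplitude-modulate a 35-450 Hz Gaussian carrier).
#' @param seed integer seed; the generated cohort is a pure function of the
#'   configuration and template.
#' @param group_label label stored with every subject (e.g. "TF", "C_SS").
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12, strides_per_subject = 8,
                          stride_duration_mean = 1.2, stride_duration_sd = 0.1,
                          phase_fractions = c(0.12, 0.38, 0.12, 0.38),
                          snr_db = 20, subject_perturbation_sd = 0.05,
                          group_effect = c("none", "tf_like"),
                          sampling_rate_hz = 1000,
                          mode = c("envelope", "raw"),
                          seed = 1, group_label = "G1") {
  group_effect <- match.arg(group_effect)
  mode <- match.arg(mode)
  abort_if(n_subjects < 1, "n_subjects must be >= 1")
  abort_if(strides_per_subject < 1, "strides_per_subject must be >= 1")
  abort_if(stride_duration_mean <= 0 || stride_duration_sd < 0,
           "stride durations must be positive")
  abort_if(length(phase_fractions) != 4 || any(phase_fractions <= 0),
           "phase_fractions must be 4 positive fractions")
  abort_if(abs(sum(phase_fractions) - 1) > 1e-9, "phase_fractions must sum to 1")
  structure(list(n_subjects = n_subjects,
                 strides_per_subject = strides_per_subject,
                 stride_duration_mean = stride_duration_mean,
                 stride_duration_sd = stride_duration_sd,
                 phase_fractions = phase_fractions,
                 snr_db = snr_db,
                 subject_perturbation_sd = subject_perturbation_sd,
                 group_effect = group_effect,
                 sampling_rate_hz = sampling_rate_hz,
                 mode = mode, seed = seed, group_label = group_label),
            class = "cohort_config")
}

# The tf_like preset: fixed alterations of the bump tables. Synergy 2's
# stance bump is widened and flanked by bumps centred in DS1 and DS2
# (prolonged calf activity whenever the instrumented limb is loaded);
# synergy 4 gains a bump at the contralateral heel strike (cycle fraction
# DS1 + Stance).
apply_group_effect <- function(template, effect, phase_fractions) {
  if (effect == "none") return(template)
  b <- template$bumps
  main2 <- max(b[[2]]$amplitude)
  ds1_c <- phase_fractions[1] / 2
  ds2_c <- phase_fractions[1] + phase_fractions[2] + phase_fractions[3] / 2
  b[[2]]$width <- b[[2]]$width * 1.8
  b[[2]] <- rbind(b[[2]],
                  data.frame(center = c(ds1_c, ds2_c), width = c(0.05, 0.05),
                             amplitude = c(0.5, 0.6) * main2))
  hs_contra <- phase_fractions[1] + phase_fractions[2]
  main4 <- max(b[[4]]$amplitude)
  b[[4]] <- rbind(b[[4]],
                  data.frame(center = hs_contra, width = 0.05,
                             amplitude = 0.6 * main4))
  template$bumps <- b
  template
}

perturb_weights <- function(W, sd) {
  if (sd == 0) return(W)
  Wp <- pmax(W + matrix(stats::rnorm(length(W), sd = sd), nrow(W)), 0)
  nrm <- sqrt(colSums(Wp^2))
  bad <- nrm < 1e-8
  if (any(bad)) { Wp[, bad] <- W[, bad]; nrm[bad] <- 1 }
  sweep(Wp, 2, nrm, "/")
}

# Band-limited unit-RMS Gaussian carrier for raw mode.
make_carrier <- function(n, fs, flt) {
  x <- filtfilt_sos(stats::rnorm(n), flt)
  x / sqrt(mean(x^2))
}

#' Simulate a cohort of synthetic gait sEMG recordings
#'
#' Per subject, the ground-truth weights are a rectified, renormalized
#' Gaussian perturbation of the template; stride durations are jittered;
#' envelopes are `W %*% H` plus rectified Gaussian noise scaled to the
#' requested per-channel SNR. In `mode = "raw"` each noisy envelope channel
#' amplitude-modulates an independent zero-mean 35-450 Hz Gaussian carrier,
#' so the full filter + envelope chain can be exercised.
#'
#' @param config a [cohort_config()].
#' @param template a [synergy_template()]; defaults to [default_template()].
#' @return an object of class `gait_cohort`: a list with `subjects` (each
#'   holding `id`, `group`, `W_true`, `H_true`, `events`, `recording`,
#'   `envelope_clean`, `stride_boundaries`), plus the `template` and
#'   `config` used.
#' @export
generate_cohort <- function(config, template = default_template()) {
  stopifnot(inherits(config, "cohort_config"), inherits(template, "synergy_template"))
  fs <- config$sampling_rate_hz
  eff_template <- apply_group_effect(template, config$group_effect,
                                     config$phase_fractions)
  flt <- if (config$mode == "raw") butter_bandpass(4, 35, 450, fs) else NULL

  with_seed(config$seed, {
    subjects <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      W_s <- perturb_weights(eff_template$W, config$subject_perturbation_sd)
      tpl_s <- eff_template
      tpl_s$W <- W_s

      env_list <- list(); H_list <- list(); ev <- NULL
      t0_samples <- 0L
      for (st in seq_len(config$strides_per_subject)) {
        dur <- max(stats::rnorm(1, config$stride_duration_mean,
                                config$stride_duration_sd),
                   0.5 * config$stride_duration_mean)
        stride <- generate_stride(tpl_s, dur * config$phase_fractions, fs)
        env_list[[st]] <- stride$envelope
        H_list[[st]] <- stride$H
        bnd <- stride$phase_boundaries
        ev <- rbind(ev, data.frame(
          stride_id = st,
          HS_ref = t0_samples / fs,
          TO_contra = (t0_samples + bnd[1]) / fs,
          HS_contra = (t0_samples + bnd[2]) / fs,
          TO_ref = (t0_samples + bnd[3]) / fs,
          HS_ref_next = (t0_samples + bnd[4]) / fs))
        t0_samples <- t0_samples + stride$n_samples
      }
      env_clean <- do.call(cbind, env_list)
      H_true <- do.call(cbind, H_list)
      boundaries <- cumsum(vapply(env_list, ncol, integer(1)))

      env <- env_clean
      if (is.finite(config$snr_db)) {
        rms <- sqrt(rowMeans(env_clean^2))
        noise_sd <- rms / 10^(config$snr_db / 20)
        noise <- matrix(stats::rnorm(length(env)), nrow(env)) * noise_sd
        env <- pmax(env + noise, 0)
      }

      samples <- env
      if (config$mode == "raw") {
        for (m in seq_len(nrow(env))) {
          samples[m, ] <- env[m, ] * make_carrier(ncol(env), fs, flt)
        }
      }
      rec <- emg_recording(samples, muscle_labels = template$muscle_labels, fs = fs)
      subjects[[s]] <- list(id = sprintf("%s_%02d", config$group_label, s),
                            group = config$group_label,
                            W_true = W_s, H_true = H_true,
                            events = gait_events(ev),
                            recording = rec,
                            envelope_clean = env_clean,
                            stride_boundaries = boundaries)
    }
    structure(list(subjects = subjects, template = template,
                   effective_template = eff_template, config = config),
              class = "gait_cohort")
  })
}
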