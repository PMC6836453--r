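# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small (few subjects, few strides) so the default run stays
# well inside its time budget.

tiny_cohort <- function(n_subjects = 2, strides = 3, seed = 42, snr_db = 20,
                        group_effect = "none", mode = "envelope",
                        perturb = 0.05, label = "G1") {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, strides_per_subject = strides,
    snr_db = snr_db, subject_perturbation_sd = perturb,
    group_effect = group_effect, mode = mode, seed = seed,
    group_label = label))
}

# normalized envelope matrix of one synthetic subject
subject_envelope <- function(subject) {
  normalize_amplitude(segment_strides(subject$recording, subject$events))
}

# a small random nonnegative matrix
rand_nonneg <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(nr * nc), nr, nc)
}

# time-normalized mean activation profiles straight from the generator's
# ground-truth H (bypasses factorization; fast path for statistics tests)
true_h_profiles <- function(cohort) {
  lapply(cohort$subjects, function(s) {
    M <- segment_strides(s$recording, s$events)
    Henv <- gaitsynergy:::as_envelope_matrix(s$H_true, M)
    time_normalize(Henv, parse_phases(s$events))$mean
  })
}
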