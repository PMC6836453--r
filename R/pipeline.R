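# End-to-end orchestration: simulate or load recordings, preprocess,
# extract synergies, cross-validate against the reference group's average
# synergies, and run the phase-resolved group statistics.

#' Analysis run configuration
#'
#' @param groups named list describing the groups. Each element is either a
#'   [cohort_config()] (the group is simulated) or a list of subjects, each
#'   a `list(emg = <path>, events = <path>)` read from disk.
#' @param input_is_envelope for file-based groups: `TRUE` when the files
#'   already contain envelopes (skips filtering and envelope estimation).
#' @param filter_low,filter_high,filter_order Butterworth band-pass design.
#' @param envelope_method,envelope_window_ms see [compute_envelope()].
#' @param vaf_threshold VAF threshold for order selection (default 0.90).
#' @param restarts,max_iter,tol,sparse_frac NNMF settings.
#' @param n_shuffles,percentile cross-validation null settings.
#' @param alpha significance level for the group statistics.
#' @param reference_group name of the group whose average synergies serve
#'   as the fixed reference `W_ctrl` (default `"C_SS"`, i.e. controls at
#'   self-selected speed; falls back to the first group if absent).
#' @param posthoc post-hoc procedure, `"wilcoxon"` or `"dunn"`.
#' @param seed master seed; all per-subject seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(groups, input_is_envelope = FALSE,
                       filter_low = 35, filter_high = 450, filter_order = 4,
                       envelope_method = "fixed_rms", envelope_window_ms = 100,
                       vaf_threshold = 0.90, restarts = 20, max_iter = 1000,
                       tol = 1e-5, sparse_frac = 0.5,
                       n_shuffles = 1000, percentile = 95, alpha = 0.05,
                       reference_group = "C_SS",
                       posthoc = "wilcoxon", seed = 1) {
  abort_if(length(groups) == 0 || is.null(names(groups)),
           "groups must be a non-empty named list")
  abort_if(vaf_threshold <= 0 || vaf_threshold >= 1, "vaf_threshold must be in (0,1)")
  abort_if(percentile <= 0 || percentile >= 100, "percentile must be in (0,100)")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0,1)")
  if (!reference_group %in% names(groups)) reference_group <- names(groups)[1]
  structure(list(groups = groups, input_is_envelope = input_is_envelope,
                 filter_low = filter_low, filter_high = filter_high,
                 filter_order = filter_order,
                 envelope_method = envelope_method,
                 envelope_window_ms = envelope_window_ms,
                 vaf_threshold = vaf_threshold, restarts = restarts,
                 max_iter = max_iter, tol = tol, sparse_frac = sparse_frac,
                 n_shuffles = n_shuffles, percentile = percentile,
                 alpha = alpha, reference_group = reference_group,
                 posthoc = posthoc, seed = seed),
            class = "run_config")
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

load_group_subjects <- function(name, spec, config) {
  if (inherits(spec, "cohort_config")) {
    spec$group_label <- name
    cohort <- generate_cohort(spec)
    lapply(cohort$subjects, function(s) {
      list(id = s$id, group = name, recording = s$recording,
           events = s$events,
           is_envelope = cohort$config$mode == "envelope")
    })
  } else {
    lapply(seq_along(spec), function(i) {
      list(id = sprintf("%s_%02d", name, i), group = name,
           recording = read_emg(spec[[i]]$emg),
           events = read_events(spec[[i]]$events),
           is_envelope = isTRUE(config$input_is_envelope))
    })
  }
}

#' Run the full synergy analysis pipeline
#'
#' Stages, in order: (1) acquire recordings (simulated or from disk);
#' (2) band-pass filter and estimate envelopes (skipped when inputs are
#' envelopes already); (3) segment into strides and normalize amplitude;
#' (4) per-subject VAF model-order selection, then the ceil-of-mean group
#' rule (the common order across groups is the maximum of the group
#' orders); (5) fixed-order extraction, normalization, ordering, and
#' group averaging; the reference group's average is `W_ctrl`; (6)
#' cross-validation of `W_ctrl` per subject against a shuffled-synergy
#' null; (7) activation coefficients from the `W_ctrl` reconstruction,
#' time-normalized to the 200-point cycle; (8) phase activities, centers
#' of activity, Kruskal-Wallis per (synergy, phase) with post-hoc tests,
#' and the exact synergy-count test.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created if needed. All intermediate
#'   tables and a manifest with file digests are written there.
#' @param verbose print stage progress.
#' @return (invisibly) a list with `orders`, `group_orders`, `n_syn`,
#'   `W_ctrl`, `group_sets`, `crossval`, `activity_table`, `tests`,
#'   `count_test`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gaitsynergy_run_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/8: acquiring recordings")
  subjects <- list()
  for (g in names(config$groups)) {
    subjects <- c(subjects, load_group_subjects(g, config$groups[[g]], config))
  }
  n_sub <- length(subjects)

  say("stage 2-3/8: envelopes, stride segmentation, amplitude normalization")
  for (i in seq_len(n_sub)) {
    s <- subjects[[i]]
    rec <- s$recording
    if (!s$is_envelope) {
      rec <- bandpass_filter(rec, config$filter_low, config$filter_high,
                             config$filter_order)
      rec <- compute_envelope(rec, config$envelope_method,
                              config$envelope_window_ms)
    }
    env <- normalize_amplitude(segment_strides(rec, s$events))
    subjects[[i]]$M <- env
    subjects[[i]]$phases <- parse_phases(s$events)
  }

  say("stage 4/8: model order selection")
  orders <- integer(n_sub)
  sel_dec <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sel <- select_order(subjects[[i]]$M, threshold = config$vaf_threshold,
                        restarts = config$restarts, max_iter = config$max_iter,
                        tol = config$tol, sparse_frac = config$sparse_frac,
                        seed = derive_seed(config$seed, i))
    orders[i] <- sel
    sel_dec[[i]] <- attr(sel, "decomposition")
  }
  group_of <- vapply(subjects, `[[`, character(1), "group")
  group_orders <- vapply(split(orders, group_of), group_order, integer(1))
  n_syn <- max(group_orders)

  say("stage 5/8: fixed-order extraction at n_syn = %d", n_syn)
  decs <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    decs[[i]] <- if (orders[i] == n_syn) sel_dec[[i]] else
      nnmf_extract(subjects[[i]]$M, n_syn, restarts = config$restarts,
                   max_iter = config$max_iter, tol = config$tol,
                   sparse_frac = config$sparse_frac,
                   seed = derive_seed(config$seed, 10000 + i))
    decs[[i]] <- normalize_synergies(decs[[i]])
  }

  ref <- config$reference_group
  ref_idx <- which(group_of == ref)
  ref_set <- group_synergy_set(lapply(decs[ref_idx], `[[`, "W"))
  W_ctrl <- ref_set$W_mean
  rownames(W_ctrl) <- subjects[[1]]$recording$muscle_labels
  group_sets <- lapply(split(seq_len(n_sub), group_of), function(idx) {
    group_synergy_set(lapply(decs[idx], `[[`, "W"), W_reference = W_ctrl)
  })

  say("stage 6/8: cross-validation against W_ctrl (%d shuffles)",
      config$n_shuffles)
  cv <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    cv[[i]] <- cross_validate(subjects[[i]]$M, W_ctrl,
                              n_shuffles = config$n_shuffles,
                              seed = derive_seed(config$seed, 20000 + i),
                              percentile = config$percentile,
                              max_iter = config$max_iter, tol = config$tol)
  }

  say("stage 7/8: time-normalized activation profiles")
  profiles <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    H <- cv[[i]]$H
    Henv <- as_envelope_matrix(H, subjects[[i]]$M,
                               labels = paste0("S", seq_len(nrow(H))))
    profiles[[i]] <- time_normalize(Henv, subjects[[i]]$phases)$mean
  }
  names(profiles) <- vapply(subjects, `[[`, character(1), "id")

  say("stage 8/8: group statistics")
  act_tab <- phase_activity_table(profiles, group_of)
  tests <- if (length(unique(group_of)) >= 2)
    kruskal_wallis_by_cell(act_tab, alpha = config$alpha,
                           posthoc = config$posthoc) else NULL
  counts <- table(group_of, factor(orders, levels = sort(unique(orders))))
  count_test <- if (length(unique(group_of)) >= 2 && ncol(counts) >= 2)
    synergy_count_test(unclass(counts)) else NULL

  # outputs + manifest
  paths <- character(0)
  wr <- function(obj, file, writer) {
    p <- file.path(out_dir, file); writer(obj, p); paths <<- c(paths, p)
  }
  wr(W_ctrl, "W_ctrl.csv", write_matrix_labeled)
  for (g in names(group_sets)) {
    Wg <- group_sets[[g]]$W_mean
    rownames(Wg) <- rownames(W_ctrl)
    wr(Wg, sprintf("W_mean_%s.csv", g), write_matrix_labeled)
  }
  wr(act_tab, "phase_activity.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  if (!is.null(tests)) {
    wr(tests$cells, "kruskal_wallis_cells.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(tests$posthoc, "posthoc.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  cv_tab <- data.frame(
    subject = names(profiles), group = group_of, order_selected = orders,
    vaf_recon = vapply(cv, `[[`, numeric(1), "vaf_recon"),
    vaf_threshold = vapply(cv, `[[`, numeric(1), "vaf_threshold"),
    representative = vapply(cv, `[[`, logical(1), "representative"))
  wr(cv_tab, "crossval.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(utils::capture.output(utils::str(config, give.attr = FALSE)), cfg_path)
  paths <- c(paths, cfg_path)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  invisible(list(orders = stats::setNames(orders, names(profiles)),
                 group_orders = group_orders, n_syn = n_syn,
                 W_ctrl = W_ctrl, group_sets = group_sets,
                 crossval = cv, crossval_table = cv_tab,
                 activity_table = act_tab, tests = tests,
                 count_test = count_test, manifest = manifest,
                 out_dir = out_dir))
}
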