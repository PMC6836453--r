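# Phase-resolved activation analysis: per-phase activity indices and the
# circular center of activity of time-normalized activation profiles, plus
# the nonparametric group statistics run on them.

PHASE_NAMES <- c("DS1", "Stance", "DS2", "Swing")

phase_blocks <- function(samples_per_phase = c(20, 80, 20, 80)) {
  ends <- cumsum(samples_per_phase)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(a, b) a:b, starts, ends)
}

#' Per-phase activity of a 200-sample activation profile
#'
#' Sums the profile over the sub-phase sample blocks of the normalized gait
#' cycle (DS1 = samples 1-20, Stance = 21-100, DS2 = 101-120, Swing =
#' 121-200 in 1-based indexing).
#'
#' @param profile numeric vector of length 200 (one row of a
#'   `normalized_profile`).
#' @param samples_per_phase phase block lengths (default 20/80/20/80).
#' @return named numeric vector `(DS1, Stance, DS2, Swing)`.
#' @export
phase_activity <- function(profile, samples_per_phase = c(20, 80, 20, 80)) {
  total <- sum(samples_per_phase)
  abort_if(length(profile) != total,
           "profile has %d samples; expected %d", length(profile), total)
  vapply(phase_blocks(samples_per_phase), function(idx) sum(profile[idx]),
         numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(PHASE_NAMES)
}

#' Circular center of activity of an activation profile
#'
#' The profile is treated as a mass distribution on the gait cycle mapped
#' to the circle (360 degrees = 1 cycle): sample `t` (0-based) sits at
#' angle `360 * t / n`. The CoA is the direction of the circular resultant
#' `sum_t H_t exp(i theta_t)`, in degrees in `[0, 360)`.
#'
#' @param profile nonnegative numeric vector (length 200 by convention).
#' @return CoA in degrees.
#' @export
center_of_activity <- function(profile) {
  n <- length(profile)
  abort_if(n < 1 || all(profile == 0), "CoA undefined for an all-zero profile")
  theta <- 2 * pi * (seq_len(n) - 1) / n
  s <- sum(profile * sin(theta))
  c_ <- sum(profile * cos(theta))
  abort_if(sqrt(s^2 + c_^2) < 1e-12 * sum(abs(profile)),
           "CoA undefined: circular resultant is zero (uniform profile)")
  (atan2(s, c_) * 180 / pi) %% 360
}

#' Build a phase-activity table from per-subject activation profiles
#'
#' @param profiles named list (one element per subject) of matrices
#'   `n_syn x 200` — each subject's mean time-normalized activation
#'   profiles.
#' @param groups character vector of group labels, one per subject.
#' @return a data.frame of class `phase_activity_table` with columns
#'   `subject`, `group`, `synergy`, `activity_DS1`, `activity_Stance`,
#'   `activity_DS2`, `activity_Swing`, `coa_deg` (`NA` where undefined).
#' @export
phase_activity_table <- function(profiles, groups) {
  abort_if(length(profiles) != length(groups),
           "one group label per subject is required")
  subj <- names(profiles) %||% paste0("S", seq_along(profiles))
  rows <- list()
  for (i in seq_along(profiles)) {
    P <- profiles[[i]]
    for (k in seq_len(nrow(P))) {
      act <- phase_activity(P[k, ])
      coa <- if (all(P[k, ] == 0)) NA_real_ else center_of_activity(P[k, ])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj[i], group = groups[i], synergy = k,
        activity_DS1 = act[["DS1"]], activity_Stance = act[["Stance"]],
        activity_DS2 = act[["DS2"]], activity_Swing = act[["Swing"]],
        coa_deg = coa)
    }
  }
  structure(do.call(rbind, rows),
            class = c("phase_activity_table", "data.frame"))
}

# Dunn's z-based post-hoc test on pooled ranks, Bonferroni-adjusted.
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
    data.frame(group1 = pr[1], group2 = pr[2], statistic = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, res)
}

wilcox_posthoc <- function(values, groups) {
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]; y <- values[groups == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2], statistic = unname(wt$statistic),
               p_raw = wt$p.value)
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis comparison of phase activities, per synergy and phase
#'
#' For every (synergy, sub-phase) cell, runs a Kruskal-Wallis rank test
#' with group as factor (tie-corrected H, chi-square reference with
#' `groups - 1` degrees of freedom), followed by Bonferroni-adjusted
#' pairwise post-hoc tests (two-sided Mann-Whitney by default, or Dunn's
#' z-based procedure).
#'
#' @param table a [phase_activity_table()].
#' @param alpha significance level (default 0.05).
#' @param posthoc `"wilcoxon"` (default) or `"dunn"`.
#' @return an object of class `group_test_result`: `cells` (data.frame with
#'   one row per synergy x phase: H statistic, df, p-value, significance
#'   flag), `posthoc` (data.frame of pairwise Bonferroni-adjusted p-values),
#'   `alpha`.
#' @export
kruskal_wallis_by_cell <- function(table, alpha = 0.05,
                                   posthoc = c("wilcoxon", "dunn")) {
  stopifnot(inherits(table, "phase_activity_table"))
  posthoc <- match.arg(posthoc)
  groups <- factor(table$group)
  abort_if(nlevels(groups) < 2, "need at least two groups")
  counts <- base::table(table$group[table$synergy == table$synergy[1]])
  abort_if(any(counts < 2), "group(s) %s have fewer than 2 observations",
           paste(names(counts)[counts < 2], collapse = ", "))
  cells <- list(); ph_rows <- list()
  for (k in sort(unique(table$synergy))) {
    for (p in PHASE_NAMES) {
      sub <- table[table$synergy == k, ]
      vals <- sub[[paste0("activity_", p)]]
      g <- factor(sub$group)
      if (length(unique(vals)) == 1) {
        # every observation tied: no rank information, H = 0 by convention
        kw <- list(statistic = 0, parameter = nlevels(g) - 1, p.value = 1)
      } else {
        kw <- stats::kruskal.test(vals, g)
      }
      cells[[length(cells) + 1L]] <- data.frame(
        synergy = k, phase = p, H = unname(kw$statistic),
        df = unname(kw$parameter), p_value = kw$p.value,
        significant = kw$p.value < alpha)
      ph <- if (length(unique(vals)) == 1) {
        prs <- utils::combn(levels(g), 2, simplify = FALSE)
        do.call(rbind, lapply(prs, function(pr) data.frame(
          group1 = pr[1], group2 = pr[2], statistic = NA_real_, p_raw = 1)))
      } else if (posthoc == "wilcoxon") wilcox_posthoc(vals, g) else dunn_posthoc(vals, g)
      n_comp <- nrow(ph)
      ph$p_adj <- pmin(1, ph$p_raw * n_comp)
      ph$significant <- ph$p_adj < alpha
      ph <- cbind(data.frame(synergy = k, phase = p), ph)
      ph_rows[[length(ph_rows) + 1L]] <- ph
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 posthoc = do.call(rbind, ph_rows),
                 alpha = alpha, posthoc_method = posthoc),
            class = "group_test_result")
}

# log probability of a contingency table under the fixed-margins
# (multiple hypergeometric) null.
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

enumerate_tables <- function(row_sums, col_sums) {
  r <- length(row_sums)
  out <- list()
  # all ways to write s as an ordered sum of length(bounds) parts, each part
  # bounded above by the corresponding entry of bounds
  compositions <- function(s, bounds) {
    if (length(bounds) == 1) {
      return(if (s <= bounds[1]) list(s) else list())
    }
    res <- list()
    for (v in 0:min(s, bounds[1])) {
      for (rest in compositions(s - v, bounds[-1])) {
        res[[length(res) + 1L]] <- c(v, rest)
      }
    }
    res
  }
  recurse <- function(rows_done, col_rem, i) {
    if (i == r) {  # final row is forced by the column remainders
      out[[length(out) + 1L]] <<- unname(rbind(rows_done, col_rem))
      return(invisible(NULL))
    }
    for (row in compositions(row_sums[i], col_rem)) {
      recurse(rbind(rows_done, row), col_rem - row, i + 1L)
    }
  }
  recurse(NULL, as.numeric(col_sums), 1L)
  out
}

#' Exact test of association in an r x c contingency table
#'
#' Freeman-Halton extension of Fisher's exact test: enumerates every table
#' with the observed margins and sums the multiple-hypergeometric
#' probabilities of all tables no more probable than the observed one. Used
#' to test equivalence of the synergy-count distributions across groups
#' (groups x order categories).
#'
#' @param counts nonnegative integer matrix (e.g. 3 groups x 3 categories).
#' @return list with `p_value`, `observed_log_prob`, `n_tables`.
#' @export
synergy_count_test <- function(counts) {
  counts <- as.matrix(counts)
  abort_if(any(counts < 0) || any(counts != round(counts)),
           "counts must be nonnegative integers")
  abort_if(sum(counts) == 0, "empty table")
  lp_obs <- log_table_prob(counts)
  tabs <- enumerate_tables(rowSums(counts), colSums(counts))
  lps <- vapply(tabs, log_table_prob, numeric(1))
  # tolerance absorbs floating noise in the "no more probable" comparison
  p <- sum(exp(lps[lps <= lp_obs + 1e-7]))
  list(p_value = min(p, 1), observed_log_prob = lp_obs,
       n_tables = length(tabs))
}
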