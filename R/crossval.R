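# Cross-validation of a fixed reference synergy set: non-negative
# reconstruction (NNR) of a subject's envelopes with W held fixed, compared
# against a null distribution built from within-column shuffles of W.

#' Non-negative reconstruction with fixed synergy vectors
#'
#' Fits the activation matrix `H` by the standard multiplicative update
#' `H <- H * (W' M) / (W' W H)` while never updating `W`. `H` is
#' initialized with uniform positive entries; iteration stops when the VAF
#' change drops below `tol` or at `max_iter`. Denominators are floored at
#' 1e-12 so exact-zero activation regions cannot divide by zero.
#'
#' @param M nonnegative muscles x samples matrix or `envelope_matrix`.
#' @param W_fixed nonnegative muscles x n_syn matrix with no zero column.
#' @param max_iter,tol stopping rule.
#' @param seed integer seed for the initialization.
#' @return the fitted `H` (n_syn x samples) with attributes `"vaf"`,
#'   `"objective"` (squared-error trajectory) and `"iterations"`.
#' @export
nnr_fit <- function(M, W_fixed, max_iter = 1000, tol = 1e-5, seed = NULL) {
  M <- as_values_matrix(M)
  assert_nonneg_matrix(W_fixed, "W_fixed")
  abort_if(nrow(W_fixed) != nrow(M), "W_fixed rows (%d) != M rows (%d)",
           nrow(W_fixed), nrow(M))
  zero_col <- colSums(W_fixed) == 0
  abort_if(any(zero_col), "W_fixed column(s) %s are all-zero",
           paste(which(zero_col), collapse = ", "))
  with_seed(seed, {
    H0 <- matrix(stats::runif(ncol(W_fixed) * ncol(M), 0.1, 1),
                 ncol(W_fixed), ncol(M))
    fit <- run_mu(M, W_fixed, H0, max_iter, tol, update_w = FALSE)
    structure(fit$H, vaf = fit$vaf, objective = fit$objective,
              iterations = fit$iterations)
  })
}

#' Shuffle the components of each synergy vector
#'
#' Independently permutes the entries within every column of `W`: the
#' multiset of weights per synergy (and hence each column norm) is
#' preserved while the muscle-to-weight pairing is destroyed. This is the
#' null model for the cross-validation threshold.
#'
#' @param W numeric matrix.
#' @param seed optional integer seed.
#' @return the shuffled matrix.
#' @export
shuffle_synergy_vectors <- function(W, seed = NULL) {
  abort_if(!is.matrix(W), "W must be a matrix")
  with_seed(seed, {
    for (j in seq_len(ncol(W))) W[, j] <- W[sample.int(nrow(W)), j]
    W
  })
}

#' Cross-validate a reference synergy set against a subject's envelopes
#'
#' Computes the NNR reconstruction VAF with `W_ref` fixed, then builds a
#' null distribution of VAFs from reconstructions with within-column
#' shuffles of `W_ref`. The reference is deemed representative of the
#' subject's muscle coordination when its VAF exceeds the 95th percentile
#' (linear-interpolation definition) of the null distribution.
#'
#' @param M nonnegative envelope matrix (or `envelope_matrix`).
#' @param W_ref reference synergy matrix.
#' @param n_shuffles size of the null distribution (>= 20; default 1000).
#' @param seed integer seed controlling both the NNR initializations and
#'   the shuffles.
#' @param percentile null percentile used as threshold (default 95).
#' @param max_iter,tol passed to [nnr_fit()].
#' @return an object of class `crossval_result`: `vaf_recon`, `null_vafs`,
#'   `vaf_threshold`, `representative`, `n_shuffles`, `seed`, and `H` (the
#'   fitted activations for `W_ref`).
#' @export
cross_validate <- function(M, W_ref, n_shuffles = 1000, seed = NULL,
                           percentile = 95, max_iter = 1000, tol = 1e-5) {
  abort_if(n_shuffles < 20,
           "n_shuffles = %d is too small for a stable percentile (need >= 20)",
           n_shuffles)
  Mv <- as_values_matrix(M)
  with_seed(seed, {
    H <- nnr_fit(Mv, W_ref, max_iter = max_iter, tol = tol)
    vaf_recon <- attr(H, "vaf")
    null_vafs <- vapply(seq_len(n_shuffles), function(i) {
      Ws <- shuffle_synergy_vectors(W_ref)
      attr(nnr_fit(Mv, Ws, max_iter = max_iter, tol = tol), "vaf")
    }, numeric(1))
    thr <- as.numeric(stats::quantile(null_vafs, percentile / 100, type = 7))
    structure(list(vaf_recon = vaf_recon, null_vafs = null_vafs,
                   vaf_threshold = thr,
                   representative = vaf_recon > thr,
                   n_shuffles = as.integer(n_shuffles), seed = seed,
                   percentile = percentile, H = H),
              class = "crossval_result")
  })
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(
    "<crossval_result> VAF %.4f vs null %dth pct %.4f over %d shuffles -> %s\n",
    x$vaf_recon, x$percentile, x$vaf_threshold, x$n_shuffles,
    if (x$representative) "representative" else "not representative"))
  invisible(x)
}
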