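# Synergy extraction: non-negative matrix factorization with multiplicative
# updates, VAF-based model order selection, and normalization / ordering /
# averaging of synergy vectors across subjects.

EPS_DENOM <- 1e-12

as_values_matrix <- function(M) {
  if (inherits(M, "envelope_matrix")) M <- M$values
  assert_nonneg_matrix(M)
}

#' Variance accounted for by a factorization
#'
#' Global, uncentered VAF: `1 - ||M - W H||_F^2 / ||M||_F^2`.
#'
#' @param M nonnegative data matrix (or an `envelope_matrix`).
#' @param W,H factor matrices with conforming shapes.
#' @return a fraction, 1 when the reconstruction is exact.
#' @export
vaf <- function(M, W, H) {
  M <- as_values_matrix(M)
  abort_if(nrow(W) != nrow(M) || ncol(H) != ncol(M) || ncol(W) != nrow(H),
           "W (%dx%d) and H (%dx%d) do not conform with M (%dx%d)",
           nrow(W), ncol(W), nrow(H), ncol(H), nrow(M), ncol(M))
  denom <- sum(M^2)
  abort_if(denom == 0, "VAF undefined: M is identically zero")
  1 - sum((M - W %*% H)^2) / denom
}

# Per-muscle VAF (diagnostic; not used for order selection).
vaf_per_row <- function(M, W, H) {
  M <- as_values_matrix(M)
  R <- M - W %*% H
  1 - rowSums(R^2) / pmax(rowSums(M^2), EPS_DENOM)
}

mu_update_H <- function(M, W, H) {
  H * crossprod(W, M) / pmax(crossprod(W) %*% H, EPS_DENOM)
}

mu_update_W <- function(M, W, H) {
  W * tcrossprod(M, H) / pmax(W %*% tcrossprod(H), EPS_DENOM)
}

# Sparse start: a fraction of each column is suppressed to a negligible
# seed value (not exact zero — zeros are absorbing under multiplicative
# updates, so an unlucky support pattern could never be repaired).
sparse_init <- function(nr, nc, sparse_frac) {
  X <- matrix(stats::runif(nr * nc, min = 0.1, max = 1), nr, nc)
  if (sparse_frac > 0 && nr > 1) {
    nzero <- min(floor(sparse_frac * nr), nr - 1)  # keep >= 1 live entry/col
    for (j in seq_len(nc)) {
      X[sample.int(nr, nzero), j] <- 1e-6
    }
  }
  X
}

run_mu <- function(M, W, H, max_iter, tol, update_w = TRUE) {
  denom <- sum(M^2)
  obj <- numeric(0)
  v_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- mu_update_H(M, W, H)
    if (update_w) W <- mu_update_W(M, W, H)
    err <- sum((M - W %*% H)^2)
    obj[it] <- err
    v <- 1 - err / denom
    if (it > 1 && abs(v - v_prev) < tol) { converged <- TRUE; break }
    v_prev <- v
  }
  list(W = W, H = H, vaf = 1 - obj[length(obj)] / denom,
       objective = obj, converged = converged, iterations = length(obj))
}

#' Extract muscle synergies by NNMF
#'
#' Minimizes the squared Frobenius reconstruction error with multiplicative
#' (Lee-Seung) updates of both factors. Each restart draws nonnegative
#' uniform `W` and `H` with a fraction `sparse_frac` of each column
#' suppressed to a negligible seed value (sparse initialization; exact
#' zeros are avoided because they are absorbing under multiplicative
#' updates); the restart reaching the highest final VAF wins. Iteration
#' stops when the VAF improvement drops below `tol` or at `max_iter`.
#'
#' @param M nonnegative muscles x samples matrix or `envelope_matrix`.
#' @param n_syn number of synergies (1 to `nrow(M)`).
#' @param restarts random restarts (default 20).
#' @param max_iter,tol stopping rule per restart.
#' @param sparse_frac fraction of each initial column set to zero.
#' @param seed integer seed; extraction is deterministic given it.
#' @param warm_start optional list `(W, H)` from an (n_syn - 1) solution;
#'   an extra restart is run from it with one random column appended, which
#'   makes VAF monotone non-decreasing in `n_syn` across nested calls.
#' @return an object of class `synergy_decomposition`: `W` (muscles x
#'   n_syn), `H` (n_syn x samples), `vaf`, `vaf_per_muscle`, `n_syn`,
#'   `converged`, `restarts_used`, `objective` (error trajectory of the
#'   winning restart), `seed`.
#' @export
nnmf_extract <- function(M, n_syn, restarts = 20, max_iter = 1000, tol = 1e-5,
                         sparse_frac = 0.5, seed = NULL, warm_start = NULL) {
  M <- as_values_matrix(M)
  abort_if(n_syn < 1, "n_syn must be >= 1")
  abort_if(n_syn > nrow(M), "n_syn (%d) exceeds the number of muscles (%d)",
           n_syn, nrow(M))
  abort_if(sum(M^2) == 0, "cannot factorize an all-zero matrix")
  nr <- nrow(M); nc <- ncol(M)

  with_seed(seed, {
    best <- NULL
    used <- 0L
    starts <- replicate(restarts, list(W = sparse_init(nr, n_syn, sparse_frac),
                                       H = sparse_init(n_syn, nc, sparse_frac)),
                        simplify = FALSE)
    if (!is.null(warm_start)) {
      abort_if(ncol(warm_start$W) != n_syn - 1,
               "warm start must have n_syn - 1 columns")
      starts <- c(starts, list(list(
        W = cbind(warm_start$W, stats::runif(nr, 0.1, 1)),
        H = rbind(warm_start$H, stats::runif(nc, 0.1, 1)))))
    }
    for (st in starts) {
      used <- used + 1L
      fit <- run_mu(M, st$W, st$H, max_iter, tol)
      if (is.null(best) || fit$vaf > best$vaf) best <- fit
    }
    structure(list(W = best$W, H = best$H, vaf = best$vaf,
                   vaf_per_muscle = vaf_per_row(M, best$W, best$H),
                   n_syn = as.integer(n_syn), converged = best$converged,
                   restarts_used = used, objective = best$objective,
                   seed = seed),
              class = "synergy_decomposition")
  })
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("<synergy_decomposition> %d synergies, VAF %.4f (%s, %d restarts)\n",
              x$n_syn, x$vaf, if (x$converged) "converged" else "max_iter",
              x$restarts_used))
  invisible(x)
}

#' Select the number of synergies by the global VAF criterion
#'
#' Runs NNMF for increasing model orders and returns the smallest order
#' whose global VAF exceeds `threshold`. Successive orders are warm-started
#' from the previous best solution (plus one random component) so the VAF
#' curve is monotone non-decreasing.
#'
#' @param M nonnegative matrix or `envelope_matrix`.
#' @param threshold VAF threshold (default 0.90, strict `>`).
#' @param n_range orders to try, ascending (default `1:nrow(M)`).
#' @param seed integer seed.
#' @inheritParams nnmf_extract
#' @return the selected order (integer), with attributes `"vaf"` (named VAF
#'   per order tried) and `"decomposition"` (the fit at the selected order).
#' @export
select_order <- function(M, threshold = 0.90, n_range = NULL, restarts = 20,
                         max_iter = 1000, tol = 1e-5, sparse_frac = 0.5,
                         seed = NULL) {
  Mv <- as_values_matrix(M)
  if (is.null(n_range)) n_range <- seq_len(nrow(Mv))
  abort_if(any(diff(n_range) <= 0), "n_range must be strictly increasing")
  abort_if(threshold >= 1, "threshold must be < 1")
  vafs <- stats::setNames(numeric(0), character(0))
  warm <- NULL
  res <- NULL
  with_seed(seed, {
    for (n in n_range) {
      dec <- nnmf_extract(Mv, n, restarts = restarts, max_iter = max_iter,
                          tol = tol, sparse_frac = sparse_frac, seed = NULL,
                          warm_start = if (!is.null(warm) && ncol(warm$W) == n - 1) warm)
      vafs[as.character(n)] <- dec$vaf
      warm <- list(W = dec$W, H = dec$H)
      if (dec$vaf > threshold) {
        res <- structure(as.integer(n), vaf = vafs, decomposition = dec)
        break
      }
    }
  })
  if (is.null(res)) {
    stop(sprintf("VAF threshold %.2f not reached at any order up to %d (max VAF %.4f)",
                 threshold, max(n_range), max(vafs)), call. = FALSE)
  }
  res
}

#' Group-level synergy count: ceiling of the mean subject order
#'
#' @param per_subject_orders integer vector of per-subject selected orders.
#' @return the smallest integer >= the mean; an exactly integer mean is
#'   returned unchanged.
#' @export
group_order <- function(per_subject_orders) {
  abort_if(length(per_subject_orders) == 0, "empty order list")
  abort_if(any(per_subject_orders < 1), "orders must be positive integers")
  as.integer(ceiling(mean(per_subject_orders)))
}

#' Normalize synergy vectors to unit norm, rescaling activations
#'
#' Column `i` of `W` is divided by its Euclidean norm and row `i` of `H`
#' multiplied by the same quantity, leaving the reconstruction `W %*% H`
#' unchanged.
#'
#' @param dec a `synergy_decomposition`.
#' @return the normalized decomposition.
#' @export
normalize_synergies <- function(dec) {
  stopifnot(inherits(dec, "synergy_decomposition"))
  nrm <- sqrt(colSums(dec$W^2))
  abort_if(any(nrm == 0), "synergy column(s) %s are all-zero",
           paste(which(nrm == 0), collapse = ", "))
  dec$W <- sweep(dec$W, 2, nrm, "/")
  dec$H <- dec$H * nrm
  dec
}

#' Cosine similarity between two synergy vectors
#'
#' @param w1,w2 nonzero numeric vectors of equal length.
#' @return `dot(w1, w2) / (||w1|| ||w2||)`; in `[0, 1]` for nonnegative
#'   inputs.
#' @export
cosine_similarity <- function(w1, w2) {
  abort_if(length(w1) != length(w2), "vectors differ in length")
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  abort_if(n1 == 0 || n2 == 0, "cosine similarity undefined for a zero vector")
  sum(w1 * w2) / (n1 * n2)
}

cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  crossprod(An, Bn)  # rows: columns of A, cols: columns of B
}

# Exact maximum-total-similarity assignment by depth-first search with an
# upper bound (sum of per-row maxima). Deterministic lowest-index preference
# on ties; exact for any size, fast for the N_syn <= 12 used here.
best_assignment <- function(S) {
  k <- nrow(S)
  best_perm <- seq_len(k)
  best_val <- sum(S[cbind(seq_len(k), best_perm)])
  row_max <- apply(S, 1, max)
  recurse <- function(i, used, acc, perm) {
    if (i > k) {
      if (acc > best_val + 1e-12) { best_val <<- acc; best_perm <<- perm }
      return(invisible(NULL))
    }
    if (acc + sum(row_max[i:k]) <= best_val + 1e-12) return(invisible(NULL))
    for (j in seq_len(k)) {
      if (!used[j]) {
        used[j] <- TRUE; perm[i] <- j
        recurse(i + 1, used, acc + S[i, j], perm)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(k), 0, integer(k))
  list(perm = best_perm, value = best_val)
}

#' Order a subject's synergies against a reference set
#'
#' Finds the one-to-one matching of columns of `W_subject` to columns of
#' `W_reference` that maximizes the total cosine similarity (optimal
#' assignment, not greedy), and applies it to `W_subject` (and to the rows
#' of `H` if supplied).
#'
#' @param W_subject,W_reference matrices with the same number of columns.
#' @param H optional activation matrix whose rows are permuted alongside.
#' @return list with `permutation` (`W_ordered[, j] = W_subject[, permutation[j]]`),
#'   `similarities` (cosine of each matched pair), `W` (ordered subject
#'   matrix) and `H` (ordered activations, if supplied).
#' @export
order_synergies <- function(W_subject, W_reference, H = NULL) {
  abort_if(ncol(W_subject) != ncol(W_reference),
           "synergy counts differ (%d vs %d)", ncol(W_subject), ncol(W_reference))
  S <- cosine_matrix(W_reference, W_subject)  # S[r, s]: ref col r vs subj col s
  asg <- best_assignment(S)
  perm <- asg$perm
  sims <- S[cbind(seq_len(nrow(S)), perm)]
  list(permutation = perm,
       similarities = as.numeric(sims),
       W = W_subject[, perm, drop = FALSE],
       H = if (!is.null(H)) H[perm, , drop = FALSE])
}

#' Average ordered synergy sets into a group-characteristic set
#'
#' @param W_list list of ordered W matrices (same dimensions).
#' @return list with `W_mean` (entrywise mean with columns renormalized to
#'   unit norm) and `n_sets`.
#' @export
average_synergies <- function(W_list) {
  abort_if(length(W_list) == 0, "no synergy sets to average")
  dims <- vapply(W_list, dim, integer(2))
  abort_if(any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]),
           "synergy sets have mismatched dimensions")
  W_mean <- Reduce(`+`, W_list) / length(W_list)
  nrm <- sqrt(colSums(W_mean^2))
  abort_if(any(nrm == 0), "mean synergy column is all-zero")
  list(W_mean = sweep(W_mean, 2, nrm, "/"), n_sets = length(W_list))
}

#' Order a set of subject synergy matrices against a reference and average
#'
#' Convenience wrapper producing a group-characteristic synergy set: every
#' member is ordered against the reference member, then averaged and
#' renormalized.
#'
#' @param W_list list of per-subject W matrices (same dimensions).
#' @param reference_id index of the member used as ordering reference, or a
#'   reference matrix itself via `W_reference`.
#' @param W_reference optional external reference matrix (overrides
#'   `reference_id`).
#' @return an object of class `group_synergy_set`: `W_list` (ordered),
#'   `W_mean`, `reference_id`, `similarity_matrix` (subjects x synergies,
#'   cosine of each matched pair against the reference).
#' @export
group_synergy_set <- function(W_list, reference_id = 1, W_reference = NULL) {
  abort_if(length(W_list) == 0, "no synergy sets supplied")
  ref <- W_reference %||% W_list[[reference_id]]
  ordered <- lapply(W_list, function(W) order_synergies(W, ref))
  sims <- do.call(rbind, lapply(ordered, `[[`, "similarities"))
  structure(list(W_list = lapply(ordered, `[[`, "W"),
                 W_mean = average_synergies(lapply(ordered, `[[`, "W"))$W_mean,
                 reference_id = if (is.null(W_reference)) reference_id else NA_integer_,
                 similarity_matrix = sims),
            class = "group_synergy_set")
}
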