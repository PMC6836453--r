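test_that("vaf implements the global uncentered definition", {
  M <- matrix(c(1, 3, 2, 4), 2)           # [[1,2],[3,4]] row-wise
  W <- diag(2); H <- matrix(c(1, 3, 2, 0), 2)
  expect_equal(vaf(M, W, H), 1 - 16 / 30)  # residual only in the (2,2) cell
  expect_equal(vaf(M, diag(2), M), 1)
  expect_equal(vaf(M, diag(2), M * 0), 0)
  expect_error(vaf(M * 0, diag(2), M), "identically zero")
  expect_error(vaf(M, diag(3), rbind(M, 0)), "conform")
})

test_that("NNMF recovers well-separated ground-truth synergies", {
  co <- generate_cohort(cohort_config(n_subjects = 1, strides_per_subject = 3,
                                      snr_db = Inf, subject_perturbation_sd = 0,
                                      seed = 2))
  s <- co$subjects[[1]]
  M <- s$recording$samples
  dec <- nnmf_extract(M, 4, restarts = 10, seed = 7)
  expect_gt(dec$vaf, 0.999)
  ord <- order_synergies(dec$W, co$template$W)
  expect_true(all(ord$similarities > 0.99))
  expect_true(all(dec$W >= 0) && all(dec$H >= 0))

  expect_error(nnmf_extract(M, 0), ">= 1")
  expect_error(nnmf_extract(M, 13), "exceeds")
  expect_error(nnmf_extract(-M, 2), "negative")
  expect_error(nnmf_extract(M * 0, 2), "all-zero")
})

test_that("multiplicative updates never increase the objective", {
  M <- rand_nonneg(8, 40, seed = 11)
  dec <- nnmf_extract(M, 3, restarts = 3, max_iter = 300, seed = 5)
  expect_true(all(diff(dec$objective) <= 1e-10))
})

test_that("order selection applies the VAF-exceeds-threshold rule", {
  co <- generate_cohort(cohort_config(n_subjects = 1, strides_per_subject = 2,
                                      snr_db = Inf, subject_perturbation_sd = 0,
                                      seed = 14))
  M <- co$subjects[[1]]$recording$samples
  sel <- select_order(M, threshold = 0.90, restarts = 8, seed = 3)
  expect_equal(as.integer(sel), 4L)
  vafs <- attr(sel, "vaf")
  expect_true(all(diff(vafs) >= -1e-9))        # warm-started monotone curve
  expect_true(vafs[length(vafs)] > 0.90)
  expect_true(all(vafs[-length(vafs)] <= 0.90))

  # threshold 0: a single synergy always exceeds it
  expect_equal(as.integer(select_order(M, threshold = 0, restarts = 2, seed = 1)), 1L)

  # exact nonnegative rank-1 matrix at any threshold < 1
  M1 <- outer(runif(5) + 0.1, runif(30) + 0.1)
  expect_equal(as.integer(select_order(M1, threshold = 0.99, restarts = 3,
                                       seed = 2)), 1L)
})

test_that("group order is the ceiling of the mean subject order", {
  expect_equal(group_order(c(3, 4, 4, 3)), 4L)
  expect_equal(group_order(c(4, 4, 4)), 4L)
  expect_equal(group_order(c(3, 3, 5)), 4L)
  expect_error(group_order(integer(0)), "empty")
})

test_that("synergy normalization rescales H and preserves the reconstruction", {
  W <- cbind(c(3, 4, rep(0, 10)), c(0, 0, 2, rep(0, 9)))
  H <- rand_nonneg(2, 30, seed = 3)
  dec <- structure(list(W = W, H = H, vaf = NA, n_syn = 2L),
                   class = "synergy_decomposition")
  nd <- normalize_synergies(dec)
  expect_equal(nd$W[1:2, 1], c(0.6, 0.8))
  expect_equal(nd$H[1, ], 5 * H[1, ])
  expect_equal(nd$W %*% nd$H, W %*% H, tolerance = 1e-12)
  # idempotence
  nd2 <- normalize_synergies(nd)
  expect_equal(nd2$W, nd$W, tolerance = 1e-12)
  dec$W[, 1] <- 0
  expect_error(normalize_synergies(dec), "all-zero")
})

test_that("cosine similarity matches hand values", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("synergy ordering is an optimal assignment", {
  set.seed(21)
  W <- matrix(runif(12 * 4), 12)
  # reference vs itself: identity, all similarities 1
  self <- order_synergies(W, W)
  expect_equal(self$permutation, 1:4)
  expect_equal(self$similarities, rep(1, 4))
  # undo a known column swap
  swapped <- W[, c(3, 2, 1, 4)]
  ord <- order_synergies(swapped, W)
  expect_equal(ord$W, W)
  expect_equal(ord$permutation, c(3, 2, 1, 4))
  expect_error(order_synergies(W[, 1:3], W), "differ")

  # exhaustive-permutation oracle on random pairs, k = 3..5
  perms <- function(k) {
    if (k == 1) return(list(1L))
    do.call(c, lapply(seq_len(k), function(i)
      lapply(perms(k - 1), function(p) c(i, p + (p >= i)))))
  }
  for (k in 3:5) {
    for (rep in 1:3) {
      A <- rand_nonneg(10, k, seed = 100 * k + rep)
      B <- rand_nonneg(10, k, seed = 200 * k + rep)
      got <- order_synergies(A, B)
      S <- gaitsynergy:::cosine_matrix(B, A)
      best <- max(vapply(perms(k), function(p)
        sum(S[cbind(seq_len(k), p)]), numeric(1)))
      expect_equal(sum(got$similarities), best, tolerance = 1e-12)
    }
  }
})

test_that("averaging ordered sets renormalizes the entrywise mean", {
  W1 <- cbind(c(0.2, sqrt(1 - 0.04), 0, 0))
  W2 <- cbind(c(0.4, sqrt(1 - 0.16), 0, 0))
  avg <- average_synergies(list(W1, W2))
  raw_mean <- (W1 + W2) / 2
  expect_equal(raw_mean[1, 1], 0.3)
  expect_equal(avg$W_mean, raw_mean / sqrt(sum(raw_mean^2)), tolerance = 1e-12)
  expect_equal(sum(avg$W_mean^2), 1, tolerance = 1e-12)
  # identical sets average to any member
  same <- average_synergies(list(W1, W1, W1))
  expect_equal(same$W_mean, W1, tolerance = 1e-12)
  expect_error(average_synergies(list()), "no synergy sets")
})

test_that("synergies recovered from noisy cohorts match ground truth", {
  co <- tiny_cohort(n_subjects = 2, strides = 3, seed = 33, snr_db = 20)
  sims <- unlist(lapply(co$subjects, function(s) {
    M <- subject_envelope(s)
    dec <- nnmf_extract(M, 4, restarts = 8, seed = 5)
    order_synergies(dec$W, s$W_true)$similarities
  }))
  expect_gte(median(sims), 0.9)
})
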