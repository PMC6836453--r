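test_that("phase activity sums the documented sample blocks", {
  expect_equal(phase_activity(rep(1, 200)),
               c(DS1 = 20, Stance = 80, DS2 = 20, Swing = 80))

  # support confined to 0-based samples 100..119 -> activity only in DS2
  p <- numeric(200); p[101:120] <- 2
  act <- phase_activity(p)
  expect_equal(unname(act), c(0, 0, 40, 0))

  # random profile vs index-loop oracle
  set.seed(31)
  r <- runif(200)
  blocks <- list(1:20, 21:100, 101:120, 121:200)
  oracle <- vapply(blocks, function(ix) {
    s <- 0
    for (i in ix) s <- s + r[i]
    s
  }, numeric(1))
  expect_equal(unname(phase_activity(r)), oracle)
  # activities partition the total profile activity
  expect_equal(sum(phase_activity(r)), sum(r))

  expect_error(phase_activity(rep(1, 199)), "expected 200")
})

test_that("center of activity is the circular resultant direction", {
  imp <- function(at, w = 1) { p <- numeric(200); p[at + 1] <- w; p }
  expect_equal(center_of_activity(imp(50)), 90)
  expect_equal(center_of_activity(imp(40) + imp(60)), 90)

  # two unequal impulses: frozen complex-resultant value
  p <- 2 * imp(30) + imp(90)
  z <- 2 * exp(1i * 2 * pi * 30 / 200) + exp(1i * 2 * pi * 90 / 200)
  expect_equal(center_of_activity(p), (Arg(z) * 180 / pi) %% 360,
               tolerance = 1e-12)
  expect_equal(center_of_activity(p), 83.35463, tolerance = 1e-4)

  expect_error(center_of_activity(numeric(200)), "all-zero")
  expect_error(center_of_activity(rep(1, 200)), "resultant")
})

test_that("CoA is equivariant under cyclic shifts and matches a brute-force oracle", {
  set.seed(77)
  for (rep in 1:5) {
    p <- runif(200)^2
    # brute-force complex sum oracle
    zs <- 0 + 0i
    for (t in 0:199) zs <- zs + p[t + 1] * exp(1i * 2 * pi * t / 200)
    expect_equal(center_of_activity(p), (Arg(zs) * 180 / pi) %% 360,
                 tolerance = 1e-9)
    k <- sample(1:199, 1)
    shifted <- c(p[(200 - k + 1):200], p[1:(200 - k)])  # delay by k samples
    expect_equal(center_of_activity(shifted),
                 (center_of_activity(p) + 360 * k / 200) %% 360,
                 tolerance = 1e-8)
  }
})

mk_table <- function(values_by_group, synergy = 1) {
  rows <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(subject = paste0(g, seq_along(v)), group = g, synergy = synergy,
               activity_DS1 = v, activity_Stance = v, activity_DS2 = v,
               activity_Swing = v, coa_deg = 90)
  }))
  structure(rows, class = c("phase_activity_table", "data.frame"))
}

test_that("Kruskal-Wallis per cell matches the closed-form rank computation", {
  tab <- mk_table(list(A = c(1, 2, 3), B = c(4, 5, 6), C = c(7, 8, 9)))
  res <- kruskal_wallis_by_cell(tab)
  # no ties: H = 12/(N(N+1)) * sum(R_i^2 / n_i) - 3(N+1) with rank sums 6,15,24
  H_hand <- 12 / (9 * 10) * (36 + 225 + 576) / 3 - 3 * 10
  expect_equal(H_hand, 7.2)
  expect_equal(res$cells$H, rep(7.2, 4))
  expect_equal(res$cells$df, rep(2, 4))
  expect_equal(nrow(res$posthoc), 12)  # 3 pairs x 4 phases
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw))
  expect_true(all(res$posthoc$p_adj <= 1))

  # all observations tied: H = 0, p = 1
  tied <- mk_table(list(A = c(2, 2, 2), B = c(2, 2, 2), C = c(2, 2, 2)))
  rest <- kruskal_wallis_by_cell(tied)
  expect_equal(rest$cells$H, rep(0, 4))
  expect_equal(rest$cells$p_value, rep(1, 4))

  # Dunn variant runs and agrees qualitatively on a clear separation
  resd <- kruskal_wallis_by_cell(tab, posthoc = "dunn")
  expect_true(all(c("statistic", "p_adj") %in% names(resd$posthoc)))

  expect_error(kruskal_wallis_by_cell(mk_table(list(A = c(1, 2, 3)))),
               "two groups")
})

test_that("the exact synergy-count test reproduces hypergeometric references", {
  # 2x2 worked example: two-sided p = 34/70
  res <- synergy_count_test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)

  # identical rows form the most probable table -> p = 1
  expect_equal(synergy_count_test(matrix(c(2, 1, 1, 2, 1, 1), 2,
                                         byrow = TRUE))$p_value, 1)

  # r x c enumeration agrees with the reference implementation
  set.seed(12)
  for (rep in 1:4) {
    tab <- matrix(rpois(9, 3), 3)
    if (sum(tab) == 0) tab[1] <- 1
    expect_equal(synergy_count_test(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(synergy_count_test(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("tf_like cohorts separate the calf synergy's DS2 activity", {
  rejections <- vapply(1:3, function(r) {
    groups <- list(
      TF = tiny_cohort(10, strides = 2, seed = 100 + r,
                       group_effect = "tf_like", label = "TF"),
      C_SS = tiny_cohort(8, strides = 2, seed = 200 + r, label = "C_SS"),
      C_SL = tiny_cohort(8, strides = 2, seed = 300 + r, label = "C_SL"))
    profiles <- unlist(lapply(groups, true_h_profiles), recursive = FALSE)
    labels <- rep(names(groups), times = vapply(groups, function(g)
      length(g$subjects), integer(1)))
    tab <- phase_activity_table(profiles, labels)
    res <- kruskal_wallis_by_cell(tab)
    cell <- res$cells[res$cells$synergy == 2 & res$cells$phase == "DS2", ]
    post <- res$posthoc[res$posthoc$synergy == 2 & res$posthoc$phase == "DS2" &
                          (res$posthoc$group1 == "TF" | res$posthoc$group2 == "TF"), ]
    cell$significant && any(post$significant)
  }, logical(1))
  expect_gte(sum(rejections), 2)
})
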