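test_that("identical seeds reproduce panels and traces exactly", {
  tpl <- make_template(8, 1, 0.3, 0.3)
  p1 <- simulate_panel(tpl, seed = 11)
  p2 <- simulate_panel(tpl, seed = 11)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values, simulate_panel(tpl, seed = 12)$values))
  t1 <- simulate_motion("HC", 600, 0.08, seed = 5)
  expect_identical(t1, simulate_motion("HC", 600, 0.08, seed = 5))
})

test_that("zero-coherence targets yield coherence near the estimator bias floor", {
  # empirical bias oracle: independent white-noise coefficient pairs
  bias <- mean(sapply(1:20, function(i) {
    set.seed(4000 + i)
    wavelet_coherence(modwt_scale(rnorm(600)), modwt_scale(rnorm(600)))
  }))
  ms <- sapply(1:20, function(i) {
    tpl <- make_template(6, 0, 0, 0)
    cm <- build_connectivity_matrix(simulate_panel(tpl, seed = 500 + i))
    mean(cm$weights[upper.tri(cm$weights)])
  })
  expect_lt(mean(ms), bias + 0.05)
})

test_that("a strong coherence target separates from independence across seeds", {
  wins <- sapply(1:100, function(i) {
    hi <- build_connectivity_matrix(
      simulate_panel(matrix(c(0, .9, .9, 0), 2), seed = 2000 + i))$weights[1, 2]
    lo <- build_connectivity_matrix(
      simulate_panel(matrix(0, 2, 2), seed = 3000 + i))$weights[1, 2]
    hi > lo
  })
  expect_gte(mean(wins), 0.95)
})

test_that("panel simulation enforces its preconditions", {
  tpl <- make_template(4, 1, 0.3, 0.3)
  expect_error(simulate_panel(tpl, n_samples = 100), ">= 256")
})

test_that("motion traces hit the requested mean and reject a zero mean", {
  ms <- sapply(1:50, function(i) mean(simulate_motion("HC", 600, 0.08, seed = i)))
  expect_lt(abs(mean(ms) - 0.08), 0.01)
  expect_true(all(simulate_motion("BD", 600, 0.1, seed = 1) >= 0))
  expect_error(simulate_motion("HC", 600, 0), "positive")
})

test_that("generate_cohort is reproducible and respects group sizes", {
  cfg <- cohort_config(group_sizes = c(HC = 3L, SCZ = 3L), n_nodes = 10L,
                       seed = 21L)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_equal(nrow(co1$subjects), 6L)
  expect_length(co1$panels, 6L)
  expect_length(co1$motion, 6L)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$panels, co2$panels)
  expect_identical(co1$motion, co2$motion)
  expect_true(all(co1$subjects$age >= 18))
  expect_true(all(co1$subjects$group %in% c("HC", "SCP", "SCZ", "BD")))
})

test_that("per-subject seed streams are stable when subjects are added", {
  cfg_small <- cohort_config(group_sizes = c(HC = 2L), n_nodes = 8L, seed = 5L)
  cfg_big <- cohort_config(group_sizes = c(HC = 4L), n_nodes = 8L, seed = 5L)
  small <- generate_cohort(cfg_small)
  big <- generate_cohort(cfg_big)
  expect_identical(small$panels[["sub-HC001"]], big$panels[["sub-HC001"]])
  expect_identical(small$motion[["sub-HC002"]], big$motion[["sub-HC002"]])
})
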