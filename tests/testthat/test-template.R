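test_that("core-periphery template puts base+boost on hub edges and base elsewhere", {
  tpl <- make_template(4, 1, 0.3, 0.4, jitter_sd = 0)
  C <- tpl$target_coherence
  expect_equal(unname(C[1, 2:4]), rep(0.7, 3))
  expect_equal(unname(C[2, 3]), 0.3)
  expect_equal(unname(C[3, 4]), 0.3)
  # hand count: 3 hub edges at 0.7, 3 peripheral at 0.3 -> mean 0.5
  expect_equal(mean(C[upper.tri(C)]), 0.5)
})

test_that("templates are symmetric, zero-diagonal and bounded in [0, 1]", {
  tpl <- make_template(264, 26, 0.25, 0.35, jitter_sd = 0.02, seed = 9)
  C <- tpl$target_coherence
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(0, 264))
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(tpl$hub_nodes, 1:26)
})

test_that("template construction rejects invalid arguments", {
  expect_error(make_template(0, 0), "positive")
  expect_error(make_template(10, 10), "hub_count")
  expect_error(make_template(10, 2, 0.6, 0.5), "0.95")
  expect_error(make_template(10, 2, -0.1, 0.5), "base_level")
})

test_that("HC leaves the target untouched and SCZ scales it multiplicatively", {
  tpl <- make_template(12, 2, 0.3, 0.4, jitter_sd = 0.01, seed = 4)
  hc <- apply_group_effect(tpl, "HC", 0.2, 0.5)
  expect_identical(hc$target_coherence, tpl$target_coherence)
  scz <- apply_group_effect(tpl, "SCZ", strength_deficit = 0.1)
  expect_equal(scz$target_coherence, tpl$target_coherence * 0.9)
  # a mean-0.5 template loses exactly its deficit fraction
  tpl4 <- make_template(4, 1, 0.3, 0.4, jitter_sd = 0)
  scz4 <- apply_group_effect(tpl4, "SCP", strength_deficit = 0.1)
  expect_equal(mean(scz4$target_coherence[upper.tri(scz4$target_coherence)]), 0.45)
})

test_that("BD flattening halves the edge spread but preserves the mean exactly", {
  tpl <- make_template(4, 1, 0.3, 0.4, jitter_sd = 0)
  bd <- apply_group_effect(tpl, "BD", topology_flattening = 0.5)
  C <- bd$target_coherence
  off <- C[upper.tri(C)]
  expect_equal(mean(off), 0.5)
  # spread 0.4 -> 0.2 before the (here neutral) rescale
  expect_equal(max(off) - min(off), 0.2, tolerance = 1e-10)
})

test_that("flattening preserves the off-diagonal mean to machine precision", {
  for (seed in 1:5) {
    C <- rand_sym_matrix(15, seed)
    for (f in c(0.2, 0.6, 0.9)) {
      C2 <- flatten_topology(C, f)
      expect_lt(abs(mean(C2[upper.tri(C2)]) - mean(C[upper.tri(C)])), 1e-12)
      expect_equal(C2, t(C2))
    }
  }
})

test_that("unknown group labels and out-of-range fractions are rejected", {
  tpl <- make_template(5, 1, 0.3, 0.3)
  expect_error(apply_group_effect(tpl, "XX"), "unknown group")
  expect_error(apply_group_effect(tpl, "SCZ", strength_deficit = 1), "\\[0, 1\\)")
})

test_that("nearest-correlation projection returns a unit-diagonal PD matrix", {
  # deliberately infeasible core-periphery target
  tpl <- make_template(30, 4, 0.3, 0.45, jitter_sd = 0)
  R <- sqrt(tpl$target_coherence); diag(R) <- 1
  Rp <- nearest_correlation(R)
  expect_equal(unname(diag(Rp)), rep(1, 30))
  expect_gt(min(eigen(Rp, symmetric = TRUE, only.values = TRUE)$values), 0)
})
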