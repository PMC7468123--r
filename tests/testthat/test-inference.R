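test_that("ANCOVA group F matches a direct normal-equations computation", {
  # 12-row hand-built table, 2 groups, age covariate
  tab <- data.frame(
    group = rep(c("A", "B"), each = 6),
    age = c(25, 30, 35, 40, 45, 50, 28, 33, 38, 43, 48, 53),
    y = c(1.2, 1.5, 1.1, 1.9, 1.4, 1.7, 2.1, 2.4, 2.0, 2.6, 2.2, 2.9)
  )
  fit <- fit_ancova(tab, "y", covariates = "age")
  # independent oracle: explicit least squares via solve(t(X) X)
  X_full <- cbind(1, tab$group == "B", tab$age)
  b_full <- solve(crossprod(X_full), crossprod(X_full, tab$y))
  sse_full <- sum((tab$y - X_full %*% b_full)^2)
  X_red <- cbind(1, tab$age)
  b_red <- solve(crossprod(X_red), crossprod(X_red, tab$y))
  sse_red <- sum((tab$y - X_red %*% b_red)^2)
  F_oracle <- ((sse_red - sse_full) / 1) / (sse_full / 9)
  grp <- fit$effects[fit$effects$effect == "group", ]
  expect_equal(grp$F, F_oracle, tolerance = 1e-10)
  expect_equal(grp$df_effect, 1)
  expect_equal(grp$df_error, 9)
  expect_equal(grp$partial_eta_sq, (sse_red - sse_full) / sse_red,
               tolerance = 1e-10)
})

test_that("with no covariates the group test reproduces the one-way ANOVA F", {
  for (i in 1:100) {
    tab <- simulate_metric_table(8, groups = c("A", "B", "C"), seed = 3000 + i)
    fit <- fit_ancova(tab, "y", covariates = character(0))
    ref <- summary(aov(y ~ group, data = tab))[[1]]
    expect_equal(fit$effects$F[1], ref$`F value`[1], tolerance = 1e-8)
    expect_equal(fit$effects$p[1], ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("a pure covariate effect loads on the covariate, not the group", {
  tab <- simulate_metric_table(40, groups = c("A", "B"), age_effect = 0.1,
                               sd = 0.5, seed = 11)
  fit <- fit_ancova(tab, "y", covariates = c("age", "sex", "education"))
  eff <- fit$effects
  expect_gt(eff$F[eff$effect == "age"], 50)
  expect_lt(eff$F[eff$effect == "group"], 10)
})

test_that("ANCOVA validates groups, sizes and design rank", {
  tab <- simulate_metric_table(5)
  tab1 <- tab[tab$group == "A", ]
  expect_error(fit_ancova(tab1, "y", covariates = "age"), "2 groups")
  tab2 <- rbind(tab[tab$group == "A", ], tab[tab$group == "B", ][1, ])
  expect_error(fit_ancova(tab2, "y", covariates = "age"), "at least 2 subjects")
  tab3 <- tab
  tab3$dup <- as.numeric(tab3$group == "B")  # aliased with the group factor
  expect_error(fit_ancova(tab3, "y", covariates = "dup"), "rank-deficient")
})

test_that("LSD contrasts are antisymmetric in the factor ordering", {
  tab <- simulate_metric_table(15, groups = c("A", "B"), shifts = c(0, 0.8),
                               seed = 9)
  pc1 <- posthoc_pairwise(tab, "y")
  tab_flip <- tab
  tab_flip$group <- factor(tab_flip$group, levels = c("B", "A"))
  pc2 <- posthoc_pairwise(tab_flip, "y")
  expect_equal(pc1$estimate, -pc2$estimate, tolerance = 1e-10)
  expect_equal(pc1$p, pc2$p, tolerance = 1e-10)
})

test_that("BH flags match worked examples and a brute-force cutoff scan", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.2), 0.05), c(TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  for (i in 1:200) {
    set.seed(i)
    m <- sample(2:8, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, q), brute_force_bh(p, q))
  }
})

test_that("permutation p values are deterministic and bounded away from zero", {
  set.seed(2)
  M <- matrix(rnorm(40 * 12), 40, 12)
  labs <- rep(c("X", "Y"), each = 20)
  r1 <- nodal_permutation_test(M, labs, n_perm = 300, seed = 5)
  r2 <- nodal_permutation_test(M, labs, n_perm = 300, seed = 5)
  expect_identical(r1$p_fwe, r2$p_fwe)
  expect_true(all(r1$p_fwe >= 1 / 301 & r1$p_fwe <= 1))
  expect_error(nodal_permutation_test(M, rep(c("X", "Y", "Z"), length.out = 40),
                                      n_perm = 300), "two groups")
  expect_error(nodal_permutation_test(M, labs, n_perm = 50), ">= 100")
})

test_that("a planted large nodal shift is detected with high power", {
  hits <- sapply(1:20, function(i) {
    set.seed(7000 + i)
    M <- matrix(rnorm(40 * 10), 40, 10)
    M[21:40, 4] <- M[21:40, 4] + 3      # >= 3 SD shift at one node
    res <- nodal_permutation_test(M, rep(c("g1", "g2"), each = 20),
                                  n_perm = 500, seed = i)
    res$p_fwe[4] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("permutation p values are invariant to node relabeling and rescaling", {
  set.seed(3)
  M <- matrix(rnorm(30 * 8), 30, 8)
  colnames(M) <- paste0("n", 1:8)
  labs <- rep(c("X", "Y"), each = 15)
  r <- nodal_permutation_test(M, labs, n_perm = 200, seed = 9)
  perm <- sample(8)
  r_perm <- nodal_permutation_test(M[, perm], labs, n_perm = 200, seed = 9)
  expect_equal(r_perm$p_fwe, r$p_fwe[perm])
  r_scaled <- nodal_permutation_test(M * 4.2, labs, n_perm = 200, seed = 9)
  expect_identical(r_scaled$p_fwe, r$p_fwe)
})

test_that("medication contrasts reuse the ANCOVA machinery and reject bad designs", {
  tab <- simulate_metric_table(20, groups = c("BD", "BD2"), shifts = c(0, 1),
                               seed = 13)
  tab$antipsychotic <- tab$group == "BD2"
  tab$group <- "BD"
  fit <- medication_contrast(tab, "y", "antipsychotic",
                             covariates = c("age", "sex", "education"))
  expect_lt(fit$effects$p[fit$effects$effect == "antipsychotic"], 0.01)
  tab$flag_copy <- as.numeric(tab$antipsychotic)
  expect_error(medication_contrast(tab, "y", "antipsychotic",
                                   covariates = c("age", "flag_copy")),
               "rank-deficient")
  tab$antipsychotic <- TRUE
  expect_error(medication_contrast(tab, "y", "antipsychotic"),
               "two values")
})
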