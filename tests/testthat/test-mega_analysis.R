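two_study <- data.frame(study_id = c("a", "b"), gene = "G",
                        lfc = c(1, 3), se = c(0.5, 0.5))

test_that("heterogeneity matches the hand-computed DerSimonian-Laird values", {
  h <- heterogeneity(two_study)
  expect_equal(h$Q, 8, tolerance = 1e-10)
  expect_equal(h$df, 1L)
  expect_equal(h$ISq_pct, 87.5, tolerance = 1e-10)
  expect_equal(h$tau2, 1.75, tolerance = 1e-10)
  expect_equal(h$p_Q, pchisq(8, 1, lower.tail = FALSE))
})

test_that("zero dispersion and the Q <= df case truncate to zero", {
  flat <- data.frame(lfc = c(2, 2, 2), se = c(0.5, 0.3, 0.4))
  h <- heterogeneity(flat)
  expect_equal(h$Q, 0)
  expect_equal(h$ISq_pct, 0)
  expect_equal(h$tau2, 0)
  near <- data.frame(lfc = c(1.0, 1.05), se = c(2, 2))
  h2 <- heterogeneity(near)
  expect_lte(h2$Q, h2$df)
  expect_equal(h2$ISq_pct, 0)
  expect_equal(h2$tau2, 0)
})

test_that("fixed-effects pooling matches the inverse-variance closed form", {
  res <- pool_effects(two_study, "fixed")
  expect_equal(res$pooled_lfc, 2, tolerance = 1e-10)
  expect_equal(res$se, 1 / sqrt(8), tolerance = 1e-10)
  expect_equal(res$ci95,
               c(2 - qnorm(0.975) / sqrt(8), 2 + qnorm(0.975) / sqrt(8)))
  expect_equal(res$p_value, 2 * pnorm(-abs(2 / res$se)))
  expect_equal(max(res$weights), 1)
  expect_true(all(res$weights > 0))
})

test_that("homogeneous effects pool identically under both models", {
  rep3 <- data.frame(lfc = c(2, 2, 2), se = c(0.5, 0.5, 0.5))
  expect_equal(pool_effects(rep3, "fixed")$pooled_lfc, 2)
  expect_equal(pool_effects(rep3, "random")$pooled_lfc, 2)
  ## tau2 = 0 makes random identical to fixed
  expect_equal(pool_effects(rep3, "random")$se,
               pool_effects(rep3, "fixed")$se)
})

test_that("pooled estimates match a brute-force oracle for small k", {
  set.seed(7)
  for (k in 2:4) {
    eff <- data.frame(lfc = rnorm(k), se = runif(k, 0.2, 1))
    fx <- pool_effects(eff, "fixed")
    o <- oracle_pool(eff$lfc, eff$se)
    expect_equal(fx$pooled_lfc, o$est, tolerance = 1e-12)
    expect_equal(fx$se, o$se, tolerance = 1e-12)
    rd <- pool_effects(eff, "random")
    o2 <- oracle_pool(eff$lfc, eff$se, tau2 = heterogeneity(eff)$tau2)
    expect_equal(rd$pooled_lfc, o2$est, tolerance = 1e-12)
  }
})

test_that("random-effects results agree with an independent DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(31)
  eff <- data.frame(lfc = rnorm(8, -0.5, 0.7), se = runif(8, 0.15, 0.6))
  mine <- pool_effects(eff, "random")
  ref <- metafor::rma(yi = eff$lfc, sei = eff$se, method = "DL")
  expect_equal(mine$pooled_lfc, unname(ref$b[1, 1]), tolerance = 1e-10)
  expect_equal(mine$se, ref$se, tolerance = 1e-10)
  expect_equal(mine$het$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(mine$het$Q, ref$QE, tolerance = 1e-10)
})

test_that("model selection follows the Q vs df rule", {
  expect_equal(mega_analyze(two_study)$model, "random")  # Q = 8 > df = 1
  near <- data.frame(lfc = c(1.0, 1.05), se = c(2, 2))
  expect_equal(mega_analyze(near)$model, "fixed")
  ## under strong simulated heterogeneity the random model dominates
  st <- simulated_study_table(k = 11, n_control = 30, n_case = 30)
  picks <- vapply(1:200, function(r) {
    truth <- simulation_truth(c(G1 = 0), tau2 = 0.6, seed = 70000 + r)
    mega_analyze(simulate_effect_table(truth, st))$model
  }, character(1))
  expect_gte(mean(picks == "random"), 0.95)
})

test_that("top-dataset selection ranks by |lfc| with stable ties", {
  eff <- data.frame(study_id = sprintf("s%d", 1:4), gene = "G",
                    lfc = c(3, -1, 2, 0.5), se = rep(0.5, 4))
  top <- select_top_datasets(eff, 0.5)
  expect_equal(top$study_id, c("s1", "s3"))
  ## tie for the last slot: earlier input row retained
  tie <- data.frame(study_id = sprintf("s%d", 1:4), gene = "G",
                    lfc = c(3, 2, -2, 1), se = rep(0.5, 4))
  expect_equal(select_top_datasets(tie, 0.5)$study_id, c("s1", "s2"))
  ## 11 studies at 50% retain exactly 5
  eff11 <- data.frame(study_id = sprintf("s%d", 1:11), gene = "G",
                      lfc = rnorm(11), se = rep(0.3, 11))
  expect_equal(nrow(select_top_datasets(eff11, 0.5)), 5L)
  expect_error(select_top_datasets(eff, 0.25),
               class = "megax_insufficient_studies")
})

test_that("the partial mega-analysis reduces to known limits", {
  eff11 <- data.frame(study_id = sprintf("s%d", 1:11), gene = "G",
                      lfc = c(rep(-2, 5), rep(0.01, 6)),
                      se = rep(0.3, 11))
  part <- partial_mega_analyze(eff11, 0.5)
  expect_equal(part$studies_used, sprintf("s%d", 1:5))
  expect_equal(part$het$Q, 0)           # homogeneous subset
  expect_equal(part$model, "fixed")     # Q = 0 <= df
  full <- mega_analyze(eff11)
  expect_lt(part$pooled_lfc, full$pooled_lfc)  # more negative by design
  ## fraction = 1 is the full analysis
  expect_equal(partial_mega_analyze(eff11, 1)$pooled_lfc,
               full$pooled_lfc)
})

test_that("partial selection inflates |pooled| under the null", {
  st <- simulated_study_table(k = 11)
  d <- vapply(1:1000, function(r) {
    truth <- simulation_truth(c(G1 = 0), tau2 = 0.3, seed = 40000 + r)
    eff <- simulate_effect_table(truth, st)
    c(abs(mega_analyze(eff)$pooled_lfc),
      abs(partial_mega_analyze(eff, 0.5)$pooled_lfc))
  }, numeric(2))
  expect_gt(mean(d[2, ]), mean(d[1, ]))
  expect_gt(mean(d[2, ] > d[1, ]), 0.5)
})

test_that("pooling is scale equivariant", {
  set.seed(13)
  eff <- data.frame(lfc = rnorm(6), se = runif(6, 0.2, 0.8))
  a <- mega_analyze(eff)
  eff2 <- transform(eff, lfc = 3 * lfc, se = 3 * se)
  b <- mega_analyze(eff2)
  expect_equal(b$pooled_lfc, 3 * a$pooled_lfc, tolerance = 1e-12)
  expect_equal(b$se, 3 * a$se, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("the DL tau2 estimator recovers the truth at many studies", {
  st50 <- simulated_study_table(k = 50)
  tau2hat <- vapply(1:2000, function(r) {
    truth <- simulation_truth(c(G1 = 0), tau2 = 0.2, seed = 5000 + r)
    heterogeneity(simulate_effect_table(truth, st50))$tau2
  }, numeric(1))
  expect_equal(mean(tau2hat), 0.2, tolerance = 0.1)
})

test_that("degenerate pooling inputs are rejected", {
  expect_error(heterogeneity(data.frame(lfc = 1, se = 0.5)),
               class = "megax_insufficient_studies")
  expect_error(heterogeneity(data.frame(lfc = c(1, 2), se = c(0.5, 0))),
               class = "megax_validation_error")
  expect_error(pool_effects(data.frame(lfc = c(1, 2), se = c(0.5, 0.5),
                                       gene = c("A", "B"))),
               class = "megax_validation_error")
})
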