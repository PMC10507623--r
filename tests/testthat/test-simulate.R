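test_that("the generator is deterministic and honors the rater plan", {
  spec <- simulation_spec(n_p = 10, n_i = 4, seed = 5)
  t1 <- generate_complete(spec)
  t2 <- generate_complete(spec)
  expect_identical(t1$scores, t2$scores)
  expect_identical(attr(t1, "effects"), attr(t2, "effects"))
  # fixed plan
  t3 <- generate_complete(simulation_spec(n_p = 3, n_i = 2,
                                          raters = c(2L, 5L, 3L), seed = 1))
  expect_identical(unname(t3$counts$n_r_by_person), c(2L, 5L, 3L))
  expect_identical(t3$counts$N, 10L)
  # default plan guarantees at least two raters per person
  t4 <- generate_complete(simulation_spec(seed = 2))
  expect_true(all(t4$counts$n_r_by_person >= 2L))
  expect_identical(t4$counts$n_p, 145L)
  expect_identical(t4$counts$n_i, 10L)
})

test_that("zero components give a constant table at the grand mean", {
  spec <- simulation_spec(n_p = 4, n_i = 3, raters = 3, mu = 3,
                          components = c(p = 0, i = 0, pi = 0, rp = 0,
                                         res = 0), seed = 1)
  tab <- generate_complete(spec)
  expect_true(all(tab$scores$score == 3))
})

test_that("likert mode clamps and rounds to the 1-4 codes", {
  spec <- simulation_spec(n_p = 20, n_i = 5, raters = 10, mu = 3,
                          likert = TRUE, seed = 4)
  tab <- generate_complete(spec)
  expect_true(all(tab$scores$score %in% 1:4))
  # round-half-away-from-zero at the boundary
  expect_identical(gtnest:::likert_discretize(c(2.5, 3.49, 0.2, 9)),
                   c(3, 3, 1, 4))
})

test_that("effect variances approach their targets at generator scale", {
  spec <- simulation_spec(n_p = 200, n_i = 10, raters = 50,
                          components = table4_components(), seed = 6)
  eff <- attr(generate_complete(spec), "effects")
  truth <- table4_components()
  sizes <- c(p = 200, i = 10, pi = 2000, rp = 10000, res = 100000)
  emp <- c(p = var(eff$a_p), i = var(eff$b_i), pi = var(as.numeric(eff$c_pi)),
           rp = var(eff$d_rp), res = var(eff$e))
  # sampling bound: 3 standard errors of a normal sample variance
  for (s in c("p", "pi", "rp", "res")) {
    se <- truth[[s]] * sqrt(2 / (sizes[[s]] - 1))
    expect_lt(abs(emp[[s]] - truth[[s]]), 3 * se)
  }
  # the many-draw sources are within 5% of truth
  for (s in c("pi", "rp", "res")) {
    expect_lt(abs(emp[[s]] - truth[[s]]) / truth[[s]], 0.05)
  }
})

test_that("non-response removes whole raters only, at the stated rate", {
  tab <- generate_complete(simulation_spec(n_p = 30, n_i = 5, raters = 20,
                                           seed = 7))
  sim <- apply_nonresponse(tab, mcar_mechanism(0.4), seed = 11)
  obs <- sim$observed
  # unit granularity: every surviving rater keeps the full item set
  pr <- table(paste(obs$scores$person, obs$scores$rater))
  expect_true(all(pr == obs$counts$n_i))
  expect_true(obs$counts$N < tab$counts$N)
  # roster accounting
  ov <- sim$roster[sim$roster$stratum == "Overall", ]
  expect_equal(ov$expected, tab$counts$N)
  expect_equal(ov$received, obs$counts$N)
  # determinism
  sim2 <- apply_nonresponse(tab, mcar_mechanism(0.4), seed = 11)
  expect_identical(sim2$observed$scores, obs$scores)
})

test_that("boundary removal rates behave as documented", {
  tab <- generate_complete(simulation_spec(n_p = 5, n_i = 3, raters = 4,
                                           seed = 3))
  keep_all <- apply_nonresponse(tab, mcar_mechanism(0), seed = 1)
  expect_identical(keep_all$observed$scores, tab$scores)
  drop_all <- apply_nonresponse(tab, mcar_mechanism(1), seed = 1)
  expect_null(drop_all$observed)
  expect_true(all(drop_all$roster$received == 0))
})

test_that("selection bias favors raters with higher own effects", {
  tab <- generate_complete(simulation_spec(n_p = 50, n_i = 3, raters = 20,
                                           seed = 12))
  mech <- selection_mechanism(alpha = 0, beta = 2, weight_rater = 1,
                              weight_noise = 1)
  sim <- apply_nonresponse(tab, mech, seed = 13)
  d <- attr(tab, "effects")$d_rp
  resp <- sim$responded[names(d)]
  # one-sided Monte-Carlo comparison of means at alpha = 0.01
  tt <- t.test(d[resp], d[!resp], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("a flat propensity (beta = 0) behaves like MCAR", {
  tab <- generate_complete(simulation_spec(n_p = 60, n_i = 3, raters = 25,
                                           seed = 14))
  mech <- selection_mechanism(alpha = qlogis(0.7), beta = 0)
  sim <- apply_nonresponse(tab, mech, seed = 15)
  rate <- mean(sim$responded)
  n <- length(sim$responded)
  expect_lt(abs(rate - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  # no association with the rater's own effect
  d <- attr(tab, "effects")$d_rp[names(sim$responded)]
  tt <- t.test(d[sim$responded], d[!sim$responded])
  expect_gt(tt$p.value, 0.01)
})

test_that("selection requires generator effects", {
  tab <- toy_table()
  expect_error(apply_nonresponse(tab, selection_mechanism(), seed = 1),
               "generator effects")
})

test_that("recovery under no removal matches the complete-data analysis", {
  spec <- simulation_spec(n_p = 25, n_i = 5, raters = 10, seed = 2)
  rec <- recovery_experiment(spec, mcar_mechanism(0), replications = 5,
                             seed = 3)
  expect_false(any(rec$failed))
  expect_equal(rec$g_obs, rec$g_full)
  expect_equal(rec$phi_obs, rec$phi_full)
})

test_that("recovery records failed replications instead of aborting", {
  spec <- simulation_spec(n_p = 4, n_i = 3, raters = 3, seed = 2)
  rec <- recovery_experiment(spec, mcar_mechanism(1), replications = 3,
                             seed = 4)
  expect_true(all(rec$failed))
  expect_identical(nrow(rec), 3L)
})
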