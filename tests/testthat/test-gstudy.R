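test_that("uncorrected totals match hand-computed values on the toy design", {
  tt <- uncorrected_totals(toy_table())
  # grand total 24 over 8 cells; person totals 10/14; item totals 10/14;
  # cell totals 4,6,6,8; rater totals 3,7,5,9; sum of squares 84
  expect_equal(unname(tt[c("T_mu", "T_p", "T_i", "T_pi", "T_r", "T_pri")]),
               c(72, 74, 74, 76, 82, 84))
})

test_that("a constant table has every T equal to c^2 N n_i and zero SS", {
  ct <- constant_table(value = 3)
  tt <- uncorrected_totals(ct)
  expect_equal(as.numeric(tt), rep(9 * ct$counts$N * ct$counts$n_i, 6L))
  an <- ss_decomposition(tt)
  expect_equal(an$SS, rep(0, 5L))
  fit <- solve_components(an)
  expect_equal(unname(as_comp <- unclass(fit$components)[1:5]), rep(0, 5L))
})

test_that("Cauchy-Schwarz ordering of totals holds on generator output", {
  for (seed in c(2, 11, 23)) {
    tab <- generate_complete(simulation_spec(n_p = 10, n_i = 4, seed = seed))
    tt <- uncorrected_totals(tab)
    expect_true(tt[["T_pri"]] >= tt[["T_pi"]])
    expect_true(tt[["T_pi"]] >= tt[["T_p"]])
    expect_true(tt[["T_p"]] >= tt[["T_mu"]])
    expect_true(tt[["T_r"]] >= tt[["T_p"]])
  }
})

test_that("degrees of freedom follow the design counts", {
  tab <- generate_complete(simulation_spec(n_p = 3, n_i = 5,
                                           raters = c(2L, 3L, 4L), seed = 1))
  an <- ss_decomposition(uncorrected_totals(tab))
  expect_identical(an$df, c(2L, 4L, 8L, 6L, 24L))
  expect_equal(an$MS, an$SS / an$df)
})

test_that("SS match a naive mean-deviation oracle on balanced designs", {
  tab <- generate_complete(simulation_spec(n_p = 6, n_i = 4, raters = 5,
                                           seed = 13))
  an <- ss_decomposition(uncorrected_totals(tab))
  oracle <- mean_deviation_ss(tab$scores)
  expect_equal(an$SS, unname(oracle[an$source]), tolerance = 1e-9)
  # and the five SS add up to the total corrected SS
  tt <- uncorrected_totals(tab)
  expect_equal(sum(an$SS), tt[["T_pri"]] - tt[["T_mu"]], tolerance = 1e-9)
})

test_that("SS match aov's sequential decomposition on a balanced design", {
  tab <- generate_complete(simulation_spec(n_p = 5, n_i = 3, raters = 4,
                                           seed = 99))
  sc <- tab$scores
  sc$person <- factor(sc$person); sc$item <- factor(sc$item)
  sc$rater <- factor(paste(sc$person, sc$rater))
  fit <- stats::aov(score ~ person + item + person:item + rater, data = sc)
  ss_aov <- summary(fit)[[1L]][["Sum Sq"]]
  names(ss_aov) <- trimws(rownames(summary(fit)[[1L]]))
  an <- ss_decomposition(uncorrected_totals(tab))
  expect_equal(an$SS[an$source == "p"], ss_aov[["person"]], tolerance = 1e-8)
  expect_equal(an$SS[an$source == "i"], ss_aov[["item"]], tolerance = 1e-8)
  expect_equal(an$SS[an$source == "rp"], ss_aov[["rater"]],
               tolerance = 1e-8)
  expect_equal(an$SS[an$source == "pi"], ss_aov[["person:item"]],
               tolerance = 1e-8)
  expect_equal(an$SS[an$source == "res"], ss_aov[["Residuals"]],
               tolerance = 1e-8)
})

test_that("balanced EMS rows divided by df give the textbook coefficients", {
  counts <- generate_complete(simulation_spec(n_p = 10, n_i = 3, raters = 4,
                                              seed = 1))$counts
  C <- ems_coefficients(counts)
  ems <- C / matrix(c(9, 2, 18, 30, 60), 5L, 5L)  # divide rows by df
  expect_equal(unname(ems["pi", ]), c(0, 0, 4, 0, 1))
  expect_equal(unname(ems["rp", ]), c(0, 0, 0, 3, 1))
  expect_equal(unname(ems["res", ]), c(0, 0, 0, 0, 1))
  # EMS(p) carries the n_r * sigma2_pi cross term: n_r n_i, n_r, n_i, 1
  expect_equal(unname(ems["p", ]), c(12, 0, 4, 3, 1))
  expect_equal(unname(ems["i", ]), c(0, 40, 4, 0, 1))
})

test_that("Monte-Carlo mean SS matches predicted E[SS] on unbalanced counts", {
  spec <- simulation_spec(n_p = 6, n_i = 3, raters = c(2L, 3L, 4L, 2L, 5L, 3L),
                          components = c(p = 0.4, i = 0.2, pi = 0.3,
                                         rp = 0.5, res = 1),
                          seed = 1)
  counts <- generate_complete(spec)$counts
  predicted <- ems_coefficients(counts) %*% spec$components
  nsim <- 600L
  ss <- matrix(0, nsim, 5L)
  for (k in seq_len(nsim)) {
    sp <- spec
    sp$seed <- 1000L + k
    ss[k, ] <- ss_decomposition(uncorrected_totals(generate_complete(sp)))$SS
  }
  se <- apply(ss, 2L, sd) / sqrt(nsim)
  expect_true(all(abs(colMeans(ss) - predicted) < 3 * se))
})

test_that("solving the EMS system round-trips chosen components exactly", {
  counts <- generate_complete(simulation_spec(n_p = 12, n_i = 10, raters = 4,
                                              seed = 1))$counts
  theta <- c(p = 0.150, i = 0.011, pi = 0.063, rp = 0.250, res = 1.167)
  C <- ems_coefficients(counts)
  ss <- as.numeric(C %*% theta)
  an <- data.frame(source = c("p", "i", "pi", "rp", "res"),
                   df = c(11L, 9L, 99L, 36L, 324L), SS = ss, MS = ss)
  attr(an, "ems") <- C
  attr(an, "counts") <- counts
  class(an) <- c("anova_table", "data.frame")
  fit <- solve_components(an)
  expect_equal(unclass(fit$components)[1:5], theta, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_false(any(attr(fit$components, "clipped")))
})

test_that("negative solutions are clipped to zero and flagged", {
  fit <- gstudy(toy_table())
  raw <- attr(fit$components, "raw")
  expect_true(raw[["p"]] < 0)
  expect_identical(unclass(fit$components)[["p"]], 0)
  expect_true(attr(fit$components, "clipped")[["p"]])
  # closed-form values of the toy: rp = 2, i = 0.5, rest 0
  expect_equal(unclass(fit$components)[["rp"]], 2)
  expect_equal(unclass(fit$components)[["i"]], 0.5)
})

test_that("unbalanced estimates equal closed-form inversion when balanced", {
  tab <- generate_complete(simulation_spec(n_p = 8, n_i = 5, raters = 6,
                                           seed = 21))
  fit <- gstudy(tab)
  ms <- fit$anova$MS
  names(ms) <- fit$anova$source
  cf <- balanced_closed_form(ms, n_p = 8, n_r = 6, n_i = 5)
  expect_equal(attr(fit$components, "raw"), cf, tolerance = 1e-9)
})

test_that("estimates are unbiased over repeated small-design simulations", {
  truth <- c(p = 0.3, i = 0.1, pi = 0.2, rp = 0.4, res = 1)
  spec <- simulation_spec(n_p = 15, n_i = 4, raters = 8,
                          components = truth, seed = 1)
  nsim <- 400L
  est <- matrix(0, nsim, 5L)
  for (k in seq_len(nsim)) {
    sp <- spec
    sp$seed <- 5000L + k
    fit <- gstudy(generate_complete(sp))
    est[k, ] <- attr(fit$components, "raw")  # unclipped, for unbiasedness
  }
  se <- apply(est, 2L, sd) / sqrt(nsim)
  expect_true(all(abs(colMeans(est) - truth) < 3 * se))
})

test_that("relabeling persons, raters and items leaves the fit unchanged", {
  tab <- generate_complete(simulation_spec(n_p = 6, n_i = 3,
                                           raters = c(3L, 2L, 4L, 2L, 3L, 5L),
                                           seed = 8))
  sc <- tab$scores
  perm <- sc
  perm$person <- chartr("0123456789", "9876543210", sc$person)
  perm$rater <- paste0("zz", sc$rater)
  perm$item <- chartr("0123456789", "9876543210", sc$item)
  fit1 <- gstudy(tab)
  fit2 <- gstudy(rating_table(perm))
  expect_equal(sort(fit1$anova$SS), sort(fit2$anova$SS), tolerance = 1e-9)
  expect_equal(unclass(fit1$components)[1:5], unclass(fit2$components)[1:5],
               tolerance = 1e-9)
})

test_that("percentages sum to 100 and match published shares", {
  comp <- table4_components()
  pc <- variance_percentages(comp)
  expect_equal(sum(pc), 100)
  expect_equal(round(pc[["res"]], 1L), 71.1)
  expect_equal(round(pc[["rp"]], 1L), 15.2)
  expect_equal(variance_percentages(c(p = 0, i = 0, pi = 0, rp = 2,
                                      res = 0))[["rp"]], 100)
  expect_error(variance_percentages(c(p = 0, i = 0, pi = 0, rp = 0,
                                      res = 0)), "zero")
})

test_that("degenerate designs raise explicit errors", {
  one_item <- data.frame(person = c("A", "A", "B", "B"),
                         rater = c("r1", "r2", "r1", "r2"),
                         item = "i1", score = 1:4)
  expect_error(ss_decomposition(uncorrected_totals(
    rating_table(one_item))), "degenerate")
  one_rater <- data.frame(person = rep(c("A", "B"), each = 2L),
                          rater = "r1", item = rep(c("i1", "i2"), 2L),
                          score = 1:4)
  expect_error(ss_decomposition(uncorrected_totals(
    rating_table(one_rater))), "degenerate")
})
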