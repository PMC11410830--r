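test_that("rescaled deviations are standardized z-like distances", {
  expect_equal(rescaled_deviation(5, 5, 2), 0)
  expect_equal(rescaled_deviation(9, 5, 2), 2)
  set.seed(1)
  z <- rnorm(1e5)
  expect_lt(abs(rescaled_deviation(1.96, mean(z), sd(z)) - 1.96), 0.02)
  expect_equal(rescaled_deviation(3, 3, 0), 0)
  expect_error(rescaled_deviation(4, 3, 0), "zero spread")
})

test_that("classification respects the interval and response direction", {
  expect_equal(classify_interaction(5, 4, 6, 2, "positive"), "none")
  expect_equal(classify_interaction(7, 4, 6, 2, "positive"), "synergistic")
  expect_equal(classify_interaction(3, 4, 6, -2, "positive"),
               "antagonistic")
  # negative-direction responses mirror the rule
  expect_equal(classify_interaction(3, 4, 6, -2, "negative"),
               "synergistic")
  expect_equal(classify_interaction(7, 4, 6, 2, "negative"),
               "antagonistic")
  expect_error(classify_interaction(7, 4, 6, 2, "up"), "direction")
})

test_that("direction flips swap labels; joint data+direction flips do not", {
  swap <- c(synergistic = "antagonistic", antagonistic = "synergistic")
  set.seed(2)
  for (i in 1:30) {
    mu <- rnorm(1); s <- runif(1, 0.5, 2)
    obs <- mu + sample(c(-1, 1), 1) * runif(1, 2.2, 4) * s
    dn <- (obs - mu) / s
    lo <- mu - 1.96 * s; hi <- mu + 1.96 * s
    a <- classify_interaction(obs, lo, hi, dn, "positive")
    # same data, opposite declared direction: the label swaps
    b <- classify_interaction(obs, lo, hi, dn, "negative")
    expect_equal(b, unname(swap[a]))
    # negated data (reflected about the prediction) plus flipped
    # direction describe the same physical state: the label is invariant
    cc <- classify_interaction(2 * mu - obs, 2 * mu - hi, 2 * mu - lo,
                               -dn, "negative")
    expect_equal(cc, a)
  }
})

test_that("interaction calls label the synthetic world correctly", {
  tr <- tiny_truth(sigma = 0.2)
  de <- tiny_design(n_per_level = 5,
                    plan = c(control = 20, single = 8, multi = 8))
  resp <- simulate_experiment(tr, de, seed = 5)
  np <- null_predictions(de, resp, K = 200, seed = 6, kinds = "multi")
  calls <- interaction_calls(np, resp, de,
                             c(y = "positive", z = "negative"))
  expect_setequal(unique(calls$label),
                  intersect(unique(calls$label),
                            c("none", "synergistic", "antagonistic")))
  expect_equal(nrow(calls), 10 * 2 * 3)  # treatments x responses x models
  expect_true(all(is.finite(calls$dn)))
  # label consistency with interval membership
  inside <- calls$observed >= calls$ci_low & calls$observed <= calls$ci_high
  expect_true(all(calls$label[inside] == "none"))
  expect_true(all(calls$label[!inside] != "none"))
})

test_that("SSD selection prefers the generating rule and breaks ties", {
  calls <- data.frame(
    response = "y",
    model = rep(c("additive", "multiplicative", "dominative"), each = 3),
    observed = rep(c(1, 2, 3), 3),
    pred_mean = c(1, 2, 3, 1.5, 2.5, 3.5, 0, 0, 0))
  best <- select_best_null(calls)
  expect_equal(best$ssd[best$model == "additive"], 0)
  expect_equal(best$model[best$is_best], "additive")

  tie <- calls
  tie$pred_mean <- rep(c(1, 2, 3), 3)
  best2 <- select_best_null(tie)
  expect_equal(best2$model[best2$is_best], "additive")
  expect_error(select_best_null(calls[calls$model == "bogus", ]),
               "no null models")
})

test_that("per-level t statistics behave like one-sample t-tests", {
  calls <- data.frame(response = "y", model = "additive",
                      level = rep(2, 6), dn = rep(0, 6))
  out <- deviation_group_tests(calls)
  expect_equal(out$t, 0)
  expect_equal(out$p_raw, 1)

  set.seed(3)
  calls2 <- data.frame(response = "y", model = "additive", level = 2,
                       dn = 1 + rnorm(50, 0, 0.05))
  out2 <- deviation_group_tests(calls2)
  expect_lt(out2$p_raw, 0.001)
  expect_equal(out2$p_raw,
               t.test(calls2$dn, mu = 0)$p.value)

  degen <- data.frame(response = "y", model = "additive", level = 2,
                      dn = c(1, 1))
  expect_true(is.na(deviation_group_tests(degen)$p_raw))
})

test_that("t-test rejection is calibrated at the nominal rate", {
  set.seed(4)
  rej <- mean(replicate(800, t.test(rnorm(50), mu = 0)$p.value < 0.05))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("deviation-dissimilarity correlations track monotone signals", {
  calls <- data.frame(treatment_id = paste0("N2_", 1:6), response = "y",
                      model = "additive", level = 2, dn = 1:6)
  idx <- data.frame(treatment_id = paste0("N2_", 1:6), level = 2,
                    di_raw = 1:6, di_norm = (0:5) / 5)
  out <- dn_vs_di_correlation(calls, idx)
  expect_equal(out$rho, 1)
  expect_error(dn_vs_di_correlation(calls[1:2, ], idx), "fewer than 3")
})
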