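test_that("point predictions follow the three combination rules", {
  expect_equal(predict_additive(c(2, 3)), 5)
  expect_equal(predict_additive(c(2, -3, 1)), 0)
  expect_equal(predict_multiplicative(c(2, 3), 10), 5.6)
  expect_equal(predict_dominative(c(2, -5, 1)), -5)
  expect_equal(predict_dominative(c(2, -2)), 2)  # first-occurrence tie

  # all three coincide on single factors
  for (x in c(-3.2, 0, 4.7)) {
    expect_equal(predict_additive(x), x)
    expect_equal(predict_multiplicative(x, 12.5), x)
    expect_equal(predict_dominative(x), x)
  }
  expect_error(predict_multiplicative(c(1, 2), 0), "zero control")
  expect_warning(predict_multiplicative(c(-15, 1), 10), "flips sign")
})

test_that("multiplicative converges to additive with the exact cross term", {
  # two factors: the gap equals ES1*ES2/CT to machine precision
  for (ct in c(10, 1000)) {
    gap <- predict_multiplicative(c(2, 3), ct) - predict_additive(c(2, 3))
    expect_equal(gap, 2 * 3 / ct)
  }
  expect_equal(predict_multiplicative(c(2, 3), 1000), 5.006)
})

test_that("dominative magnitude bounded by additive under shared signs", {
  set.seed(1)
  for (i in 1:25) {
    es <- abs(rnorm(sample(2:8, 1))) * sample(c(-1, 1), 1)
    expect_lte(abs(predict_dominative(es)), abs(predict_additive(es)))
  }
})

combine_analytic <- function(mo) {
  switch(mo,
         additive = 2 - 3,
         multiplicative = 10 * (1 + 2 / 10) * (1 - 3 / 10) - 10,
         dominative = -3)
}

test_that("degenerate bootstrap distributions equal analytic predictions", {
  ctrl <- rep(10, 20)
  singles <- list(rep(12, 8), rep(7, 8))  # effects +2, -3
  for (mo in c("additive", "multiplicative", "dominative")) {
    bn <- bootstrap_null_distribution(ctrl, singles, mo, K = 200, seed = 1)
    analytic <- 10 + combine_analytic(mo)
    expect_equal(unique(bn$draws), analytic)
    expect_equal(bn$ci_high - bn$ci_low, 0)
  }
})

test_that("bootstrap distributions are seeded and consistent", {
  set.seed(2)
  ctrl <- rnorm(20, 10)
  singles <- list(rnorm(8, 12), rnorm(8, 9))
  a <- bootstrap_null_distribution(ctrl, singles, "additive", K = 300,
                                   seed = 5)
  b <- bootstrap_null_distribution(ctrl, singles, "additive", K = 300,
                                   seed = 5)
  expect_identical(a$draws, b$draws)
  expect_error(bootstrap_null_distribution(ctrl, list(numeric(0)),
                                           "additive"), "non-empty")

  # with large groups the distribution mean approaches the analytic point
  set.seed(3)
  big_c <- rnorm(1000, 10)
  big_s <- list(rnorm(1000, 12), rnorm(1000, 9))
  bn <- bootstrap_null_distribution(big_c, big_s, "additive", K = 2000,
                                    seed = 6)
  analytic <- mean(big_s[[1]]) + mean(big_s[[2]]) - mean(big_c)
  expect_lt(abs(bn$mean - analytic), 0.1)
})

test_that("prediction tables keep bookkeeping and coincide on singles", {
  tr <- tiny_truth()
  de <- tiny_design(n_per_level = 5)
  resp <- simulate_experiment(tr, de, seed = 4)
  np <- null_predictions(de, resp, K = 100, seed = 9)
  # draws per level x model: n_per_level treatments x K iterations
  multi <- np[np$level == 2 & np$model == "additive" &
                np$response == "y", ]
  expect_equal(sum(multi$n_draws), 5 * 100)
  # the three models share resamples, so they agree exactly on singles
  sing <- np[np$level == 1 & np$response == "y", ]
  wide <- reshape(sing[, c("treatment_id", "model", "pred_mean")],
                  idvar = "treatment_id", timevar = "model",
                  direction = "wide")
  expect_equal(wide$pred_mean.additive, wide$pred_mean.multiplicative,
               tolerance = 1e-10)
  expect_equal(wide$pred_mean.additive, wide$pred_mean.dominative,
               tolerance = 1e-10)
})
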