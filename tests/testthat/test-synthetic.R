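test_that("ground truth honors explicit matrices and is deterministic", {
  pool <- tiny_pool()
  em <- matrix(seq_len(10), 5, 2,
               dimnames = list(pool, c("y", "z")))
  tr <- tiny_truth(effect_matrix = em)
  expect_equal(unname(tr$effect_matrix), unname(em))

  t1 <- tiny_truth(seed = 42)
  t2 <- tiny_truth(seed = 42)
  expect_identical(t1$effect_matrix, t2$effect_matrix)

  t0 <- tiny_truth(sigma = 0)
  expect_true(all(t0$control_sd == 0))

  expect_error(
    make_ground_truth(pool, c("y", "z"),
                      effect_matrix = matrix(0, 2, 2),
                      directions = c(y = "positive", z = "positive")),
    "5 x 2")
})

test_that("noiseless simulation reproduces the combination rule exactly", {
  tr <- tiny_truth(sigma = 0)
  de <- tiny_design()
  resp <- simulate_experiment(tr, de, seed = 1)
  # a 2-factor unit value equals control mean + ES_a + ES_b exactly
  multi2 <- de[de$kind == "multi" & de$level == 2, ][1, ]
  members <- strsplit(multi2$factors, ";")[[1]]
  v <- resp$value[resp$treatment_id == multi2$treatment_id &
                    resp$response == "y"]
  expect_equal(unique(v),
               10 + sum(tr$effect_matrix[members, "y"]))
  # control units sit exactly at the control mean
  expect_equal(unique(resp$value[resp$treatment_id == "control" &
                                   resp$response == "z"]), 10)
})

test_that("distance-proportional injection adds gamma * d_ab by construction", {
  tr <- make_ground_truth(tiny_pool(), c("y", "z"), control_mean = 10,
                          control_sd = 0, effect_sd = 1.5,
                          interaction = interaction_distance(1, sign = 1),
                          directions = c(y = "positive", z = "positive"),
                          seed = 2)
  de <- tiny_design()
  resp <- simulate_experiment(tr, de, seed = 1)
  multi2 <- de[de$kind == "multi" & de$level == 2, ][1, ]
  members <- strsplit(multi2$factors, ";")[[1]]
  v <- unique(resp$value[resp$treatment_id == multi2$treatment_id &
                           resp$response == "y"])
  additive_pred <- 10 + sum(tr$effect_matrix[members, "y"])
  expect_equal(v - additive_pred, tr$distance[members[1], members[2]])
})

test_that("noise follows the declared normal model", {
  tr <- tiny_truth(sigma = 1)
  de <- sample_design(tiny_pool(), levels = 2, n_per_level = 2,
                      replicate_plan = c(control = 100, single = 4,
                                         multi = 64),
                      seed = 2)
  ok <- 0L
  for (s in 1:20) {
    resp <- simulate_experiment(tr, de, seed = s)
    m <- mean(resp$value[resp$treatment_id == "control" &
                           resp$response == "y"])
    ok <- ok + (abs(m - 10) <= 4 / sqrt(100))
  }
  expect_gte(ok, 19L)  # 4-sigma band holds in >= 99.9% of draws
  # multi group mean within 4*sigma/sqrt(n) of its noiseless value
  resp <- simulate_experiment(tr, de, seed = 99)
  t1 <- de$treatment_id[de$kind == "multi"][1]
  members <- strsplit(de$factors[de$treatment_id == t1], ";")[[1]]
  expect_lt(abs(mean(resp$value[resp$treatment_id == t1 &
                                  resp$response == "y"]) -
                  (10 + sum(tr$effect_matrix[members, "y"]))),
            4 / sqrt(64))
})

test_that("designs with unknown factors are rejected", {
  tr <- tiny_truth()
  de <- tiny_design(pool = LETTERS[3:8], seed = 1)
  expect_error(simulate_experiment(tr, de, seed = 1), "unknown")
})

test_that("response tables round-trip through CSV", {
  tr <- tiny_truth()
  de <- tiny_design()
  resp <- simulate_experiment(tr, de, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses_csv(resp, path)
  back <- read_responses_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(resp))
  writeLines("unit_id,response,value\nu1,y,1", path)
  expect_error(read_responses_csv(path), "treatment_id")
})
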