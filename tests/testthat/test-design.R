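test_that("enumeration yields every subset exactly once, in pool order", {
  pool <- gcf_factors()
  combos <- enumerate_combinations(pool, 5)
  expect_length(combos, 792)
  ids <- vapply(combos, combination_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  # lexicographic by pool order: first and last subsets are the extremes
  expect_identical(combos[[1]], pool[1:5])
  expect_identical(combos[[792]], pool[8:12])

  expect_length(enumerate_combinations(c("a", "b"), 2), 1L)

  # brute-force pair count oracle
  pairs <- 0L
  for (i in 1:11) for (j in (i + 1):12) pairs <- pairs + 1L
  expect_length(enumerate_combinations(pool, 2), pairs)
})

test_that("enumeration counts match the factorial formula for all k", {
  pool <- gcf_factors()
  for (k in 1:12) {
    expected <- factorial(12) / (factorial(k) * factorial(12 - k))
    expect_length(enumerate_combinations(pool, k), expected)
  }
})

test_that("enumeration rejects out-of-range k, naming it", {
  expect_error(enumerate_combinations(tiny_pool(), 6), "6")
  expect_error(enumerate_combinations(tiny_pool(), 0), "k")
  expect_error(enumerate_combinations(c("a", "a"), 1), "duplicated")
})

test_that("sampled designs are reproducible, distinct and within the pool", {
  pool <- gcf_factors()
  d1 <- sample_design(pool, seed = 7)
  d2 <- sample_design(pool, seed = 7)
  expect_identical(d1, d2)
  d3 <- sample_design(pool, seed = 8)
  expect_false(identical(d1$factors, d3$factors))

  multi <- d1[d1$kind == "multi", ]
  expect_equal(nrow(multi), 150)
  expect_false(any(tapply(multi$factors, multi$level, anyDuplicated) > 0))

  # every sampled combination exists in the enumerated complete set
  for (lv in c(2, 5, 8)) {
    all_ids <- vapply(enumerate_combinations(pool, lv), combination_id,
                      character(1))
    got <- vapply(strsplit(multi$factors[multi$level == lv], ";"),
                  combination_id, character(1))
    expect_true(all(got %in% all_ids))
  }
})

test_that("sampling at capacity is exhaustive; beyond capacity errors", {
  pool <- gcf_factors()
  d <- sample_design(pool, levels = 2, n_per_level = 66,
                     replicate_plan = c(control = 2, single = 1, multi = 1),
                     seed = 3)
  got <- sort(vapply(strsplit(d$factors[d$kind == "multi"], ";"),
                     combination_id, character(1)))
  want <- sort(vapply(enumerate_combinations(pool, 2), combination_id,
                      character(1)))
  expect_identical(got, want)
  expect_error(
    sample_design(pool, levels = 2, n_per_level = 67, seed = 3),
    "infeasible")
})

test_that("design summary counts units and is idempotent", {
  d <- sample_design(gcf_factors(), seed = 1)
  s <- design_summary(d)
  expect_equal(s$total_units, 276)
  expect_equal(unname(s$units_by_kind["control"]), 20)
  expect_equal(unname(s$units_by_kind["water_control"]), 10)
  expect_equal(unname(s$units_by_kind["single"]), 96)
  expect_equal(unname(s$units_by_kind["multi"]), 150)
  expect_identical(design_summary(d), s)

  only_controls <- sample_design(tiny_pool(), levels = 2, n_per_level = 1,
                                 replicate_plan = c(control = 20, multi = 1),
                                 seed = 1)
  only_controls <- only_controls[only_controls$kind == "control", ]
  expect_equal(design_summary(only_controls)$total_units, 20)

  # independent second-pass recount
  d2 <- tiny_design(seed = 5)
  expect_equal(design_summary(d2)$total_units,
               sum(vapply(seq_len(nrow(d2)),
                          function(i) d2$n_replicates[i], integer(1))))
})

test_that("design tables round-trip through CSV", {
  d <- tiny_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  back <- read_design_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(d))
})
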