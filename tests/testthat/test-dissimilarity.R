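test_that("standardization centers and scales response columns", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rownames(m) <- c("f1", "f2", "f3")
  expect_warning(s <- standardize_effects(m), "zero-variance")
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(unname(s[, "b"]), c(0, 0, 0))

  set.seed(1)
  r <- matrix(rnorm(36, 5, 3), 12, 3)
  sr <- standardize_effects(r)
  expect_equal(unname(colMeans(sr)), rep(0, 3))
  expect_equal(unname(apply(sr, 2, sd)), rep(1, 3))

  expect_error(standardize_effects(r[1, , drop = FALSE]), "two factors")
})

test_that("distance matrices match an element-wise brute force oracle", {
  m <- rbind(p = c(0, 0), q = c(3, 4))
  expect_equal(distance_matrix(m)["p", "q"], 5)
  expect_equal(distance_matrix(rbind(a = 1:3, b = 1:3))["a", "b"], 0)

  set.seed(2)
  r <- matrix(rnorm(84), 12, 7,
              dimnames = list(gcf_factors(), gcf_responses()))
  expect_equal(distance_matrix(r), brute_distances(r))
})

test_that("dissimilarity index sums distances over all member pairs", {
  dm <- matrix(1, 5, 5, dimnames = list(tiny_pool(), tiny_pool()))
  diag(dm) <- 0
  expect_equal(dissimilarity_index(c("A", "B"), dm), dm["A", "B"])
  expect_equal(dissimilarity_index(c("A", "B", "C"), dm), 3)
  expect_error(dissimilarity_index(c("A", "Zz"), dm), "Zz")

  set.seed(3)
  r <- matrix(rnorm(84), 12, 7, dimnames = list(gcf_factors(), NULL))
  dm2 <- distance_matrix(r)
  mem <- gcf_factors()[c(1, 3, 5, 8, 11)]
  acc <- 0
  for (i in 1:4) for (j in (i + 1):5) acc <- acc + dm2[mem[i], mem[j]]
  expect_equal(dissimilarity_index(mem, dm2), acc)
})

test_that("the index is monotone in members and grows with level", {
  set.seed(4)
  dm <- distance_matrix(matrix(rnorm(84), 12, 7,
                               dimnames = list(gcf_factors(), NULL)))
  pool <- gcf_factors()
  for (rep in 1:20) {
    k <- sample(2:11, 1)
    mem <- sample(pool, k)
    extra <- sample(setdiff(pool, mem), 1)
    expect_gte(dissimilarity_index(c(mem, extra), dm),
               dissimilarity_index(mem, dm))
  }
  de <- sample_design(pool, seed = 5)
  di <- di_table(de, dm)
  means <- tapply(di$di_raw, di$level, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})

test_that("within-level normalization maps ranges onto [0, 1]", {
  idx <- data.frame(level = c(2, 2, 2), di_raw = c(2, 4, 6))
  expect_equal(normalize_within_level(idx)$di_norm, c(0, 0.5, 1))
  flat <- data.frame(level = 5, di_raw = c(3, 3))
  expect_warning(out <- normalize_within_level(flat), "zero")
  expect_equal(out$di_norm, c(0, 0))

  set.seed(6)
  idx2 <- data.frame(level = rep(c(2, 5), each = 10),
                     di_raw = runif(20, 1, 9))
  n1 <- normalize_within_level(idx2)
  for (lv in c(2, 5)) {
    expect_equal(min(n1$di_norm[n1$level == lv]), 0)
    expect_equal(max(n1$di_norm[n1$level == lv]), 1)
  }
  # invariant to affine rescaling of the raw index within a level
  idx3 <- idx2
  idx3$di_raw <- 3 * idx3$di_raw + 7
  expect_equal(normalize_within_level(idx3)$di_norm, n1$di_norm)
})

test_that("PCoA recovers low-rank configurations and round-trips", {
  line <- cbind(c(0, 1, 2, 5), c(0, 0, 0, 0))
  rownames(line) <- paste0("p", 1:4)
  res <- pcoa(distance_matrix(line), n_axes = 2)
  expect_equal(res$variance_explained[1], 1)

  set.seed(7)
  planar <- cbind(runif(8), runif(8))
  rownames(planar) <- paste0("q", 1:8)
  dm <- distance_matrix(planar)
  res2 <- pcoa(dm, n_axes = 2)
  expect_equal(sum(res2$variance_explained[1:2]), 1)
  expect_equal(distance_matrix(res2$points), dm, tolerance = 1e-8)
})

test_that("hierarchical clustering merges nearest factors first", {
  dm <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  hc <- hierarchical_cluster(dm)
  expect_equal(hc$height, 2)

  m <- rbind(A = c(0, 0), B = c(1, 0), C = c(10, 0))
  hc3 <- hierarchical_cluster(distance_matrix(m))
  first <- rownames(m)[-hc3$merge[1, ]]
  expect_setequal(first, c("A", "B"))

  # complete linkage against a naive O(n^3) agglomeration oracle
  set.seed(8)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  dm6 <- distance_matrix(pts)
  hc6 <- hierarchical_cluster(dm6, linkage = "complete")
  naive_heights <- local({
    groups <- as.list(rownames(dm6))
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (i >= j) next
        h <- max(dm6[groups[[i]], groups[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
      heights <- c(heights, best[1])
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    heights
  })
  expect_equal(hc6$height, naive_heights)

  nwk <- cluster_newick(hc6)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, letters[1:6])
})
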