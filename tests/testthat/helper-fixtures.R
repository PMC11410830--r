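# Small fixtures shared across tests; everything is built in code.

tiny_pool <- function(n = 5) LETTERS[seq_len(n)]

tiny_design <- function(pool = tiny_pool(), levels = c(2, 3),
                        n_per_level = 4, seed = 1,
                        plan = c(control = 8, water_control = 2,
                                 single = 4, multi = 2)) {
  sample_design(pool, levels = levels, n_per_level = n_per_level,
                replicate_plan = plan, seed = seed)
}

tiny_truth <- function(pool = tiny_pool(), responses = c("y", "z"),
                       sigma = 1, world = "additive",
                       interaction = interaction_none(), seed = 1,
                       effect_matrix = NULL) {
  make_ground_truth(pool, responses, control_mean = 10,
                    control_sd = sigma, effect_sd = 1.5, world = world,
                    interaction = interaction,
                    directions = stats::setNames(
                      c("positive", "negative"), responses),
                    effect_matrix = effect_matrix, seed = seed)
}

# brute-force pairwise Euclidean distances, independent of dist()
brute_distances <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  out
}

# hand step-up BH, written independently of p.adjust
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
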