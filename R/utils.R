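# Internal helpers: seeded evaluation and derived per-stage seed streams.

# Evaluate `expr` under a temporary RNG state; the caller's stream is
# restored afterwards. A NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed for one named stage (and optional index) derived from a
# master seed. Plain integer arithmetic kept exact in doubles and reduced
# mod 2^31 - 1 so the result is a valid R seed for any master < 2^31.
stage_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- 0
  for (cc in utf8ToInt(as.character(stage))) h <- (h * 131 + cc) %% 1000003
  (abs(master) %% 2147483647 + h * 2029 + index * 7919) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument checks
check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single string", what), call. = FALSE)
  x
}

check_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be an integer >= %s", what, min), call. = FALSE)
  as.integer(x)
}
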