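# Internal helpers shared across modules.

# Deterministic 32-bit substream seed derived from a master seed and a string
# key. Each module (and each attribute within a run) draws from its own
# substream so that changing the number of draws in one place does not shift
# the random numbers used elsewhere.
str_hash <- function(key) {
  h <- 0L
  for (i in utf8ToInt(key)) h <- (h * 31L + i) %% 1000003L
  h
}

substream_seed <- function(seed, key) {
  (abs(as.integer(seed)) %% 65011L) * 33013L + str_hash(key) %% 33013L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute column standard deviations")
  ctr <- sweep(x, 2L, colMeans(x), "-")
  sqrt(colSums(ctr * ctr) / (n - 1))
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}
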