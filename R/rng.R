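#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Hashes `(seed, key)` into an integer below 2^31 so that each patient
#' (or other labelled unit) gets its own random stream. Because the stream
#' depends only on the label, regenerating a cohort with more patients
#' leaves the existing patients' nuclei unchanged.
#'
#' @param seed master integer seed
#' @param key character scalar labelling the stream
#' @return integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps doubles exact (31*2 bits < 53)
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
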