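# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for sample i of a cohort; stays < 2^31.
substream_seed <- function(seed, i) {
  (as.double(seed) + 1000003 * as.double(i)) %% 2147483647
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

# numeric formatting used by all writers: full double precision
fmt_num <- function(x) formatC(x, digits = 17, format = "g")
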