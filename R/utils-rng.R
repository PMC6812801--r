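# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions never perturb the
# user's random stream.
withSeed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# One RNG stream per artifact (dataset / predictor / responses / pipeline),
# derived from the master seed so each stage can be regenerated
# independently. Kept strictly below 2^31 - 1.
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  offsets <- c(
    dataset = 0, predictor = 1, responses = 2, pipeline = 3, images = 4
  )
  stopifnot(stream %in% names(offsets))
  as.integer((abs(as.numeric(seed)) + offsets[[stream]] * 1000003) %%
    (2^31 - 1))
}
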