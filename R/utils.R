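# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state on exit, so seeded helpers do not perturb user code.
local_rng <- function(seed, env = parent.frame()) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort("seed must be a single number")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  expr <- if (is.null(old)) {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}
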