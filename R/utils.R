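# run expr with a locally seeded RNG, restoring global RNG state afterwards
.with_seed <- function(seed, expr) {
  env <- parent.frame()
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval(substitute(expr), envir = env)
}
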