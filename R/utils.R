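# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

deg2rad <- function(x) x * pi / 180

# Mirror a (slice, row, col) array across the column-axis midplane.
# Even column counts reflect about the half-integer grid center.
mirror_lr <- function(x) {
  nc <- dim(x)[3]
  x[, , nc:1, drop = FALSE]
}

stop_if_not_mask <- function(m, name) {
  if (!is.array(m) || length(dim(m)) != 3L || !is.logical(m))
    stop(name, " must be a 3-D logical array")
}
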