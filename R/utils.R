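# internal helpers

# evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched (seed = NULL runs in the current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# wrap angles (radians) into [0, 2*pi)
wrap_2pi <- function(x) {
  x <- x %% (2 * pi)
  x[x >= 2 * pi | x < 0] <- 0 # guard against floating 2*pi %% 2*pi
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
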