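# internal helpers shared across modules

# run code with a temporarily fixed RNG seed, restoring global state after
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# activation registry: f and its derivative evaluated at the pre-activation
activation_fns <- function(name) {
  switch(name,
    relu = list(
      f = function(x) pmax(x, 0),
      g = function(x) (x > 0) * 1
    ),
    identity = list(
      f = function(x) x,
      g = function(x) array(1, dim = if (is.null(dim(x))) length(x) else dim(x))
    ),
    tanh = list(
      f = tanh,
      g = function(x) 1 - tanh(x)^2
    ),
    leaky_relu = list(
      f = function(x) ifelse(x > 0, x, 0.2 * x),
      g = function(x) ifelse(x > 0, 1, 0.2)
    ),
    stop("unknown activation: ", name)
  )
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))

stopifnot_finite <- function(x, stage) {
  if (!all(is.finite(x))) stop("non-finite values at stage: ", stage)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
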