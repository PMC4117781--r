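`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral
trapz_int <- function(x, y) pracma::trapz(x, y)

# linear interpolation of a profile onto a new q grid; NA outside support
interp_profile <- function(profile, qnew) {
  stats::approx(profile$q, profile$I, xout = qnew, rule = 1)$y
}

# run an expression with a locally-set RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
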