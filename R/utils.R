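# Internal numerical helpers shared across the package.

# log(sum(exp(x))) along rows of a matrix or over a vector, guarding -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp for a list of equally-shaped matrices (mixture
# components): returns matrix log(sum_c exp(M_c)).
logsumexp_mats <- function(mats) {
  m <- Reduce(pmax, mats)
  m[!is.finite(m)] <- 0
  acc <- 0
  for (M in mats) acc <- acc + exp(M - m)
  m + log(acc)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic operations route their randomness through this,
# so identical seeds give identical results without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

# Quadratic interpolation of the crossing f(x) = target between scan
# points. `x`, `fx` are ordered scan points with the crossing bracketed
# between the last two; falls back to linear interpolation when the
# quadratic is degenerate or puts the root outside the bracket.
interp_crossing <- function(x, fx, target) {
  n <- length(x)
  stopifnot(n >= 2)
  x1 <- x[n - 1]; x2 <- x[n]
  f1 <- fx[n - 1]; f2 <- fx[n]
  lin <- x1 + (target - f1) * (x2 - x1) / (f2 - f1)
  if (n >= 3) {
    xs <- x[(n - 2):n]; fs <- fx[(n - 2):n]
    co <- try(solve(cbind(1, xs, xs^2), fs), silent = TRUE)
    if (!inherits(co, "try-error") && abs(co[3]) > 1e-12) {
      disc <- co[2]^2 - 4 * co[3] * (co[1] - target)
      if (disc >= 0) {
        co <- unname(co)
        r <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
        lo <- min(x1, x2); hi <- max(x1, x2)
        inside <- r[r >= lo - 1e-12 & r <= hi + 1e-12]
        if (length(inside)) return(inside[which.min(abs(inside - lin))])
      }
    }
  }
  lin
}
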