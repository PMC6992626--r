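# internal helpers shared across modules

# evaluate expr with a temporarily seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# pinball (check) loss; tau = 0.5 gives half the absolute loss, whose
# minimiser is the conditional median
.pinball <- function(r, tau = 0.5) sum(r * (tau - (r < 0)))

# L1 (median regression) fit of y ~ X %*% beta by Nelder-Mead from a
# least-squares start, with one restart from the first optimum
.l1Linear <- function(X, y, tau = 0.5) {
  X <- as.matrix(X)
  start <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
  if (is.null(start) || any(!is.finite(start))) start <- rep(0, ncol(X))
  obj <- function(beta) .pinball(y - drop(X %*% beta), tau)
  if (ncol(X) == 1L) {
    # exact solution: weighted median of y/x with weights |x|
    ok <- X[, 1L] != 0
    return(list(coefficients = .weightedMedian(y[ok] / X[ok, 1L], abs(X[ok, 1L])),
                value = obj(.weightedMedian(y[ok] / X[ok, 1L], abs(X[ok, 1L])))))
  }
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 5000L, reltol = 1e-13))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(maxit = 5000L, reltol = 1e-13))
  list(coefficients = o$par, value = o$value)
}

.weightedMedian <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

.checkNumeric <- function(x, name, positive = FALSE, nonNegative = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be numeric without NA", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonNegative && any(x < 0))
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
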