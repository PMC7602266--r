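# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps generators and fits deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Moore-Penrose pseudo-inverse with a relative singular-value cutoff.
# Returns the pseudo-inverse; the condition number (sigma_max / smallest
# retained sigma) is attached as attribute "condition" for diagnostics.
pinv <- function(A, rcond = 1e-10) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop("pinv: non-finite entries", call. = FALSE)
  s <- svd(A)
  if (length(s$d) == 0L || s$d[1] == 0) {
    out <- matrix(0, ncol(A), nrow(A))
    attr(out, "condition") <- Inf
    return(out)
  }
  keep <- s$d > rcond * s$d[1]
  d_inv <- ifelse(keep, 1 / s$d, 0)
  out <- s$v %*% (d_inv * t(s$u))
  attr(out, "condition") <- s$d[1] / min(s$d[keep])
  out
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
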