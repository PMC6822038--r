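# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream untouched".
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Stage-style log line; silenced via options(phyloniche.verbose = FALSE).
pn_log <- function(fmt, ...) {
  if (isTRUE(getOption("phyloniche.verbose", TRUE))) {
    message("[phyloniche] ", sprintf(fmt, ...))
  }
}

# Symmetric matrix square root (upper-triangular Cholesky when possible,
# eigenvalue fallback for semi-definite inputs). Returns S such that
# t(S) %*% S = M.
mat_sqrt <- function(M) {
  S <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(S)) return(S)
  eig <- eigen(M, symmetric = TRUE)
  vals <- eig$values
  if (any(vals < -1e-8 * max(abs(vals)))) {
    stop("matrix is not positive semidefinite")
  }
  vals[vals < 0] <- 0
  t(eig$vectors %*% (sqrt(vals) * t(eig$vectors)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
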