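#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the expected trait covariance of two species equals
#' the depth (root-to-node path length, in the tree's time units) of their
#' most recent common ancestor; the diagonal holds each tip's depth. For an
#' ultrametric tree all diagonal entries are equal.
#'
#' @param tree [ape::phylo] with branch lengths.
#' A root edge (e.g. the stem retained by [prune_tree()]) is shared history
#' of every tip and is added to all entries.
#'
#' @return Symmetric species-by-species matrix in `tree$tip.label` order.
#' @export
tree_vcv <- function(tree) {
  C <- ape::vcv.phylo(tree)
  if (!is.null(tree$root.edge) && tree$root.edge > 0) C <- C + tree$root.edge
  C[tree$tip.label, tree$tip.label]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal covariances by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is pure Brownian motion; `lambda = 0` removes all
#' phylogenetic covariance (species evolve independently).
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda value in \[0, 1\].
#' @return Transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  C2 <- C * lambda
  diag(C2) <- diag(C)
  C2
}

#' Brownian-motion log-likelihood of a trait vector
#'
#' Gaussian likelihood of a single trait on a (possibly lambda-transformed)
#' phylogenetic covariance `C`: the root state is the generalized
#' least-squares mean, the rate is its maximum-likelihood estimate
#' (denominator n), and the log-likelihood is the multivariate normal
#' log-density at those estimates.
#'
#' @param C phylogenetic covariance (positive definite).
#' @param x trait vector aligned to the rows of `C` (names checked when
#'   present).
#' @return list with `lnL`, `mu_hat`, `sigma2_hat`.
#' @export
bm_loglik <- function(C, x) {
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    if (!setequal(names(x), rownames(C))) stop("trait names do not match tip order")
    x <- x[rownames(C)]
  }
  n <- length(x)
  stopifnot(n == nrow(C))
  L <- tryCatch(chol(C), error = function(e) {
    stop("singular phylogenetic covariance; consider a small lower bound on lambda")
  })
  logdet <- 2 * sum(log(diag(L)))
  ones <- rep(1, n)
  Cix <- backsolve(L, forwardsolve(t(L), x))
  Ci1 <- backsolve(L, forwardsolve(t(L), ones))
  mu <- sum(Cix) / sum(Ci1)
  r <- x - mu
  Q <- sum(r * backsolve(L, forwardsolve(t(L), r)))
  if (Q <= n * 1e-14 * max(1, stats::var(x))) {
    stop("degenerate (zero-variance) trait: likelihood unbounded")
  }
  sigma2 <- Q / n
  lnL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(lnL = lnL, mu_hat = mu, sigma2_hat = sigma2)
}

#' Maximum-likelihood Pagel's lambda with likelihood-ratio test
#'
#' Profiles the Brownian log-likelihood over the lambda transform on
#' \[0, 1\] by bounded scalar (Brent-type) search, evaluating the boundary
#' values exactly so boundary maxima are found; tests lambda = 0 against the
#' fitted value with a likelihood-ratio test on the chi-squared distribution
#' with one degree of freedom. Because lambda = 0 sits on the boundary of
#' the parameter space the chi-squared reference is conservative.
#'
#' When the profile is flat in lambda (e.g. a star phylogeny, or fewer than
#' three tips), the estimate resolves to 0 by the tie-break rule and the
#' result is flagged `unidentifiable`.
#'
#' @param tree dated tree ([ape::phylo]).
#' @param x named trait vector (one value per tip) or vector in tip order.
#' @param tol absolute tolerance of the lambda search.
#' @return Object of class `lambda_fit`: `lambda`, `sigma2`, `mu`,
#'   `logLik`, `logLik0`, `statistic`, `p.value`, `n`, `unidentifiable`.
#' @export
fit_lambda <- function(tree, x, tol = 1e-8) {
  if (any(!is.finite(x))) stop("non-finite trait values")
  C <- tree_vcv(tree)
  if (!is.null(names(x))) {
    if (!setequal(names(x), rownames(C))) stop("trait names do not match tree tips")
    x <- x[rownames(C)]
  } else if (length(x) == nrow(C)) {
    names(x) <- rownames(C)
  } else {
    stop("trait vector length does not match number of tips")
  }
  if (stats::sd(x) == 0) stop("degenerate (zero-variance) trait")
  prof <- function(lam) bm_loglik(lambda_transform(C, lam), x)$lnL
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 1)
  lls <- vapply(cand, prof, numeric(1))
  if (any(!is.finite(lls))) stop("non-finite likelihood across the lambda interval")
  flat <- (max(lls) - min(c(lls, vapply(c(0.25, 0.5, 0.75), prof, numeric(1))))) < 1e-10
  if (flat) {
    lam_hat <- 0
  } else {
    lam_hat <- cand[which.max(lls)]
  }
  fit <- bm_loglik(lambda_transform(C, lam_hat), x)
  ll0 <- prof(0)
  stat <- max(0, 2 * (fit$lnL - ll0))
  structure(
    list(
      lambda = lam_hat,
      sigma2 = fit$sigma2_hat,
      mu = fit$mu_hat,
      logLik = fit$lnL,
      logLik0 = ll0,
      statistic = stat,
      p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      n = length(x),
      unidentifiable = flat
    ),
    class = "lambda_fit"
  )
}

#' @export
print.lambda_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic signal (Pagel's lambda, ML)\n")
  cat(sprintf("  lambda = %.*g  (sigma2 = %.*g, root state = %.*g, n = %d)\n",
              digits, x$lambda, digits, x$sigma2, digits, x$mu, x$n))
  cat(sprintf("  logLik = %.*f, logLik(lambda = 0) = %.*f\n",
              digits, x$logLik, digits, x$logLik0))
  cat(sprintf("  LRT = %.*g on 1 df, p = %.*g%s\n", digits, x$statistic,
              digits, x$p.value,
              if (x$unidentifiable) "  [lambda unidentifiable: flat likelihood]" else ""))
  invisible(x)
}

#' @export
logLik.lambda_fit <- function(object, ...) {
  structure(object$logLik, df = 3, nobs = object$n, class = "logLik")
}

#' @export
coef.lambda_fit <- function(object, ...) {
  c(lambda = object$lambda, sigma2 = object$sigma2, mu = object$mu)
}

#' Fit Pagel's lambda for every variable of a trait matrix
#'
#' @param tree dated tree.
#' @param tm trait matrix (rows = species matching tree tips).
#' @param summary_used label recorded in the output (which per-species
#'   summary statistic the traits are).
#' @return Data frame with one row per variable: `variable`,
#'   `summary_used`, `lambda`, `sigma2`, `logLik`, `logLik0`, `statistic`,
#'   `p.value`.
#' @export
fit_lambda_table <- function(tree, tm, summary_used = "median") {
  vars <- colnames(tm) %||% paste0("V", seq_len(ncol(tm)))
  rows <- lapply(seq_len(ncol(tm)), function(j) {
    v <- vars[j]
    f <- fit_lambda(tree, stats::setNames(tm[, j], rownames(tm)))
    data.frame(variable = v, summary_used = summary_used,
               lambda = f$lambda, sigma2 = f$sigma2, logLik = f$logLik,
               logLik0 = f$logLik0, statistic = f$statistic,
               p.value = f$p.value, row.names = NULL)
  })
  do.call(rbind, rows)
}
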