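#' Multivariate disparity of a set of species
#'
#' Disparity of a species set is the mean over all unordered pairs of the
#' Euclidean distance between their trait rows (`metric = "euclidean"`,
#' the default) or of the squared distance (`metric = "squared"`, the
#' convention of some disparity implementations; kept as an explicit
#' switch). A set with fewer than two rows has disparity 0.
#'
#' @param X numeric matrix, one row per species.
#' @param metric `"euclidean"` or `"squared"`.
#' @return Scalar mean pairwise distance.
#' @export
pairwise_disparity <- function(X, metric = c("euclidean", "squared")) {
  metric <- match.arg(metric)
  X <- rbind(X) # promote a single row
  if (nrow(X) < 2L) return(0)
  d <- stats::dist(X)
  if (metric == "squared") d <- d^2
  mean(d)
}

# Tip sets of every node (tips and internal), as indices into tree$tip.label.
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge # children before parents
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; c <- edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

#' Disparity-through-time curve
#'
#' Walks the internal nodes of the tree from the root toward the present.
#' At each node's age the lineages alive are the subtrees hanging from the
#' nodes already passed (the node whose age defines the time point has not
#' yet split, so its whole subtree counts as one lineage); the curve value
#' is the mean over those lineages of their subclade disparity divided by
#' the disparity of the whole clade. The first point, at the root, is
#' therefore 1 by construction. Node ages are reported as relative time in
#' \[0, 1\] from the root toward the tips; nodes of equal age are processed
#' in a fixed (node index) order.
#'
#' @param tree dated tree.
#' @param tm standardized trait matrix (rows named by tip label); an
#'   unstandardized matrix is an error because disparity would be dominated
#'   by the variable with the largest units.
#' @param metric passed to [pairwise_disparity()].
#' @return list of class `dtt_curve`: `times`, `disparity`,
#'   `total_disparity`.
#' @export
dtt_curve <- function(tree, tm, metric = c("euclidean", "squared")) {
  metric <- match.arg(metric)
  if (!isTRUE(attr(tm, "standardized"))) {
    stop("trait matrix must be standardized (see standardize_traits())")
  }
  if (!setequal(rownames(tm), tree$tip.label)) stop("trait rows do not match tree tips")
  tm <- tm[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  total <- pairwise_disparity(tm, metric = metric)
  if (total == 0) stop("zero total disparity")
  depths <- ape::node.depth.edgelength(tree)
  Tmax <- max(depths[seq_len(n)])
  sets <- node_tip_sets(tree)
  rel <- vapply(sets, function(s) {
    pairwise_disparity(tm[s, , drop = FALSE], metric = metric) / total
  }, numeric(1))
  internal <- (n + 1L):(n + tree$Nnode)
  ord <- internal[order(depths[internal], internal)]
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  active <- ord[1L] # the root: one lineage spanning the whole clade
  times <- numeric(length(ord))
  vals <- numeric(length(ord))
  for (i in seq_along(ord)) {
    nd <- ord[i]
    times[i] <- depths[nd] / Tmax
    vals[i] <- mean(rel[active])
    # node nd splits: replace it by its children for subsequent time points
    active <- c(setdiff(active, nd), children[[as.character(nd)]])
  }
  structure(list(times = times, disparity = vals, total_disparity = total),
            class = "dtt_curve")
}

#' Evolutionary rate matrix from phylogenetically independent contrasts
#'
#' Estimates the Brownian rate (co)variance matrix of the trait columns:
#' standardized independent contrasts are computed per variable by the
#' pruning algorithm, and the rate matrix is the cross-product of the
#' contrast matrix divided by (number of tips - 1).
#'
#' @param tree dated tree (a non-ultrametric tree triggers a warning only).
#' @param tm trait matrix, rows named by tip label.
#' @return Symmetric positive semidefinite variables-by-variables matrix.
#' @export
estimate_rate_matrix <- function(tree, tm) {
  if (identical(attr(tree, "ultrametric"), FALSE)) {
    warning("tree is not ultrametric; rate estimates assume a clock only loosely")
  }
  tm <- tm[tree$tip.label, , drop = FALSE]
  U <- vapply(seq_len(ncol(tm)),
              function(j) ape::pic(stats::setNames(tm[, j], rownames(tm)), tree),
              numeric(length(tree$tip.label) - 1L))
  Sigma <- crossprod(U) / nrow(U)
  dimnames(Sigma) <- list(colnames(tm), colnames(tm))
  Sigma
}

#' Simulate multivariate Brownian trait evolution on a tree
#'
#' Draws replicate tip trait matrices from the matrix normal distribution
#' with row covariance the phylogenetic covariance of the tree and column
#' covariance `Sigma` (root state 0 for every variable).
#'
#' @param tree dated tree.
#' @param Sigma rate matrix (positive semidefinite).
#' @param n_sim number of replicates (>= 1).
#' @param seed optional integer; fixed seed gives identical output.
#' @return list of `n_sim` matrices (tips x variables).
#' @export
simulate_bm <- function(tree, Sigma, n_sim, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  C <- tree_vcv(tree)
  LC <- mat_sqrt(C)
  LS <- mat_sqrt(Sigma)
  n <- nrow(C); p <- nrow(LS)
  with_seed(seed, {
    lapply(seq_len(n_sim), function(i) {
      Z <- matrix(stats::rnorm(n * p), n, p)
      X <- t(LC) %*% Z %*% LS
      dimnames(X) <- list(rownames(C), colnames(Sigma))
      X
    })
  })
}

#' Disparity-through-time with a Brownian-motion envelope
#'
#' Computes the observed DTT curve and a null envelope from `n_sim`
#' Brownian simulations on the same tree, using the rate matrix estimated
#' from the data by independent contrasts. Each simulated trait matrix is
#' re-standardized before its curve is computed, so simulated and observed
#' curves are weighted identically. The envelope is the pointwise median
#' and 2.5%/97.5% quantiles of the simulated curves.
#'
#' @param tree dated tree.
#' @param tm standardized trait matrix.
#' @param n_sim number of Brownian replicates (default 1000).
#' @param seed optional integer seed for the simulations.
#' @param metric passed to [pairwise_disparity()].
#' @return Object of class `dtt`: `times`, `observed`, `median`, `q025`,
#'   `q975`, `n_sim`, `seed`, `total_disparity`.
#' @export
dtt_envelope <- function(tree, tm, n_sim = 1000, seed = NULL,
                         metric = c("euclidean", "squared")) {
  metric <- match.arg(metric)
  obs <- dtt_curve(tree, tm, metric = metric)
  Sigma <- estimate_rate_matrix(tree, tm)
  sims <- simulate_bm(tree, Sigma, n_sim = n_sim, seed = seed)
  curves <- vapply(sims, function(X) {
    dtt_curve(tree, standardize_traits(X), metric = metric)$disparity
  }, numeric(length(obs$times)))
  curves <- rbind(curves) # k x n_sim (rbind keeps matrix for k = 1)
  structure(
    list(
      times = obs$times,
      observed = obs$disparity,
      median = apply(curves, 1L, stats::median),
      q025 = apply(curves, 1L, stats::quantile, probs = 0.025, names = FALSE),
      q975 = apply(curves, 1L, stats::quantile, probs = 0.975, names = FALSE),
      n_sim = n_sim,
      seed = seed,
      total_disparity = obs$total_disparity
    ),
    class = "dtt"
  )
}

#' @export
print.dtt <- function(x, ...) {
  inside <- mean(x$observed >= x$q025 & x$observed <= x$q975)
  cat("Disparity through time (mean pairwise Euclidean distance)\n")
  cat(sprintf("  %d time points, %d Brownian simulations\n",
              length(x$times), x$n_sim))
  cat(sprintf("  total clade disparity = %.4g\n", x$total_disparity))
  cat(sprintf("  observed curve inside the 95%% envelope at %.0f%% of points\n",
              100 * inside))
  invisible(x)
}

#' @export
plot.dtt <- function(x, xlab = "relative time", ylab = "mean relative disparity", ...) {
  ok <- order(x$times)
  graphics::plot(x$times[ok], x$observed[ok], type = "n",
                 ylim = range(0, x$observed, x$q975), xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$times[ok], rev(x$times[ok])), c(x$q025[ok], rev(x$q975[ok])),
                    col = "grey85", border = NA)
  graphics::lines(x$times[ok], x$median[ok], lty = 2)
  graphics::lines(x$times[ok], x$observed[ok], lwd = 2)
  invisible(x)
}
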