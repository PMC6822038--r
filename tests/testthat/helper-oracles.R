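# Independent oracles used across tests. Each reimplements the target
# quantity by a different route (brute force / generic matrix formulas),
# never by calling the code path under test.

options(phyloniche.verbose = FALSE)

# Brute-force phylogenetic covariance: C[i, j] = depth of MRCA(i, j),
# computed tip pair by tip pair from root-to-node path lengths.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m <- if (i == j) i else ape::getMRCA(tree, c(i, j))
      C[i, j] <- depths[m]
    }
  }
  C
}

# Generic dense multivariate normal log-density.
oracle_mvn_logdens <- function(x, mean, Sigma) {
  n <- length(x)
  r <- x - mean
  -0.5 * (n * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% solve(Sigma) %*% r))
}

# GLS mean and ML rate from first principles (dense solve, no Cholesky).
oracle_bm_fit <- function(C, x) {
  Ci <- solve(C)
  ones <- rep(1, length(x))
  mu <- drop(t(ones) %*% Ci %*% x) / drop(t(ones) %*% Ci %*% ones)
  Q <- drop(t(x - mu) %*% Ci %*% (x - mu))
  sigma2 <- Q / length(x)
  list(mu = mu, sigma2 = sigma2,
       lnL = oracle_mvn_logdens(x, rep(mu, length(x)), sigma2 * C))
}

# O(n^2) double-loop mean pairwise Euclidean distance.
oracle_disparity <- function(X) {
  X <- rbind(X)
  n <- nrow(X)
  if (n < 2) return(0)
  tot <- 0
  cnt <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sqrt(sum((X[i, ] - X[j, ])^2))
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# Independent disparity-through-time enumeration: for the i-th internal
# node in (age, index) order, the lineages alive are found by descending
# from the root through the set of previously processed ("split") nodes,
# with the current node itself unsplit. Recomputes every subclade tip set
# by recursion rather than incremental bookkeeping.
oracle_dtt <- function(tree, tm) {
  n <- length(tree$tip.label)
  tm <- tm[tree$tip.label, , drop = FALSE]
  depths <- ape::node.depth.edgelength(tree)
  internal <- (n + 1):(n + tree$Nnode)
  ord <- internal[order(depths[internal], internal)]
  kids <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  tipset <- function(nd) {
    if (nd <= n) return(nd)
    unlist(lapply(kids(nd), tipset))
  }
  total <- oracle_disparity(tm)
  times <- numeric(length(ord))
  vals <- numeric(length(ord))
  for (i in seq_along(ord)) {
    split <- ord[seq_len(i - 1)]
    lineages <- list()
    walk <- function(nd) {
      if (nd %in% split) lapply(kids(nd), walk) else lineages[[length(lineages) + 1]] <<- tipset(nd)
      invisible(NULL)
    }
    walk(ord[1])
    times[i] <- depths[ord[i]] / max(depths[seq_len(n)])
    vals[i] <- mean(vapply(lineages, function(s) {
      oracle_disparity(tm[s, , drop = FALSE]) / total
    }, numeric(1)))
  }
  list(times = times, disparity = vals)
}

# Write a temporary Newick file and read it back with the package reader.
read_tree_text <- function(txt) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(txt, f)
  f
}

# Small helper: random ultrametric tree via the package generator with a
# derived seed (tests that need trees but do not test the generator).
rand_tree <- function(n, seed) simulate_yule_tree(n, birth_rate = 1, seed = seed)

# Tiny raster stack: two or five variables on a shared grid built directly
# from matrices (bypasses make_synthetic_rasters).
tiny_rasters <- function() {
  lat_vals <- matrix(rep(seq(9.5, 0.5, by = -1), times = 10), 10, 10)
  lon_vals <- matrix(rep(seq(0.5, 9.5, by = 1), each = 10), 10, 10)
  list(
    V1 = climate_raster(lat_vals, c(0, 0, 10, 10), 1, "V1"),
    V2 = climate_raster(lon_vals, c(0, 0, 10, 10), 1, "V2")
  )
}
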