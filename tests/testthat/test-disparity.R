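std <- function(m) {
  attr(m, "standardized") <- TRUE # mark hand-built matrices already on a common scale
  m
}

test_that("pairwise disparity is the mean pairwise Euclidean distance", {
  expect_equal(pairwise_disparity(matrix(c(1, 2), 1, 2)), 0)
  expect_equal(pairwise_disparity(rbind(c(0, 0), c(3, 4))), 5)
  set.seed(61)
  X <- matrix(rnorm(18), 6, 3)
  expect_equal(pairwise_disparity(X), oracle_disparity(X), tolerance = 1e-12)
  expect_equal(pairwise_disparity(X, metric = "squared"),
               mean(dist(X)^2), tolerance = 1e-12)
})

test_that("pairwise disparity is invariant to row order and rotation", {
  set.seed(62)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(pairwise_disparity(X[sample(5), ]), pairwise_disparity(X))
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3))) # random orthogonal matrix
  expect_equal(pairwise_disparity(X %*% Q), pairwise_disparity(X), tolerance = 1e-10)
})

test_that("dtt on a two-tip tree is the single root point at 1", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tm <- std(rbind(A = c(-1, 0), B = c(1, 0)))
  d <- dtt_curve(tr, tm)
  expect_equal(d$times, 0)
  expect_equal(d$disparity, 1)
})

test_that("dtt on a balanced four-tip tree matches a hand enumeration", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tm <- std(rbind(A = 0, B = 1, C = 4, D = 6))
  # total = mean pairwise |diff| over 6 pairs = (1+4+6+3+5+2)/6 = 3.5
  # root point: whole clade -> 1
  # node (A,B) at t=0.5 (first by index): lineages {A,B}, {C,D}:
  #   mean(1/3.5, 2/3.5)
  # node (C,D) at t=0.5: lineages {A},{B},{C,D}: mean(0, 0, 2/3.5)
  d <- dtt_curve(tr, tm)
  expect_equal(d$times, c(0, 0.5, 0.5))
  expect_equal(d$disparity, c(1, mean(c(1, 2) / 3.5), mean(c(0, 0, 2 / 3.5))),
               tolerance = 1e-12)
})

test_that("dtt requires standardized traits and nonzero disparity", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tm <- rbind(A = 0, B = 1, C = 4, D = 6)
  expect_error(dtt_curve(tr, tm), "standardized")
  expect_error(dtt_curve(tr, std(rbind(A = 1, B = 1, C = 1, D = 1))),
               "zero total disparity")
})

test_that("dtt matches the independent subclade enumeration on random trees", {
  for (seed in 1:4) {
    tr <- rand_tree(8, 100 + seed)
    X <- simulate_lambda_bm(tr, 1, diag(2), seed = 200 + seed)
    tm <- standardize_traits(X)
    got <- dtt_curve(tr, tm)
    want <- oracle_dtt(tr, tm)
    expect_equal(got$times, want$times, tolerance = 1e-12)
    expect_equal(got$disparity, want$disparity, tolerance = 1e-12)
    expect_equal(got$disparity[1], 1)
    expect_true(all(got$disparity >= 0))
  }
})

test_that("relative disparity drops after a root split into two tight clades", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tm <- std(rbind(A = c(0, 0), B = c(0, 0), C = c(10, 0), D = c(10, 0)))
  d <- suppressWarnings(dtt_curve(tr, tm))
  expect_equal(d$disparity[1], 1)
  expect_true(all(d$disparity[-1] < 0.1)) # within-clade disparity is tiny
})

test_that("rate matrix recovery under Brownian motion", {
  set.seed(71)
  hits <- replicate(200, {
    tr <- simulate_yule_tree(20, 1)
    X <- simulate_lambda_bm(tr, 1, matrix(1))
    estimate_rate_matrix(tr, X)[1, 1]
  })
  expect_equal(mean(hits), 1, tolerance = 0.1)

  offd <- replicate(200, {
    tr <- simulate_yule_tree(20, 1)
    X <- simulate_lambda_bm(tr, 1, diag(2))
    estimate_rate_matrix(tr, X)[1, 2]
  })
  expect_lt(abs(mean(offd)), 0.05)
})

test_that("rate matrix is bilinear in trait scale", {
  tr <- rand_tree(15, 72)
  X <- simulate_lambda_bm(tr, 1, diag(2), seed = 73)
  expect_equal(estimate_rate_matrix(tr, 2 * X), 4 * estimate_rate_matrix(tr, X),
               tolerance = 1e-10)
})

test_that("simulate_bm reproduces the tree's first two moments", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  sims <- simulate_bm(star, diag(1), n_sim = 2000, seed = 74)
  tipvar <- apply(vapply(sims, function(m) m[, 1], numeric(4)), 1, var)
  expect_equal(unname(tipvar), rep(2, 4), tolerance = 0.1 * 2) # ~5% moment check

  sisters <- ape::read.tree(text = "((A:0.5,B:0.5):4.5,C:5);")
  sims2 <- simulate_bm(sisters, diag(1), n_sim = 2000, seed = 75)
  ab <- vapply(sims2, function(m) m[c("A", "B"), 1], numeric(2))
  expect_equal(cor(ab[1, ], ab[2, ]), 4.5 / 5, tolerance = 0.05)

  expect_identical(simulate_bm(star, diag(1), 3, seed = 9),
                   simulate_bm(star, diag(1), 3, seed = 9))
  expect_error(simulate_bm(star, diag(1), 0), "n_sim")
})

test_that("the envelope collapses to the single curve when n_sim = 1", {
  tr <- rand_tree(10, 76)
  tm <- standardize_traits(simulate_lambda_bm(tr, 1, diag(2), seed = 77))
  env <- dtt_envelope(tr, tm, n_sim = 1, seed = 78)
  expect_equal(env$median, env$q025)
  expect_equal(env$median, env$q975)
  expect_true(all(env$q025 <= env$median & env$median <= env$q975))
})

test_that("dtt output is byte-reproducible under a fixed seed", {
  tr <- rand_tree(12, 79)
  tm <- standardize_traits(simulate_lambda_bm(tr, 1, diag(3), seed = 80))
  j <- function(seed) {
    e <- dtt_envelope(tr, tm, n_sim = 20, seed = seed)
    jsonlite::toJSON(e[c("times", "observed", "median", "q025", "q975")], digits = NA)
  }
  expect_identical(j(5), j(5))
  expect_false(identical(j(5), j(6)))
})

test_that("envelopes widen when evolutionary rates are larger", {
  tr <- rand_tree(20, 81)
  tm <- standardize_traits(simulate_lambda_bm(tr, 1, diag(2), seed = 82))
  # same tree and traits; scale the simulated-rate matrix by hand
  Sigma <- estimate_rate_matrix(tr, tm)
  width <- function(S, seed) {
    sims <- simulate_bm(tr, S, n_sim = 100, seed = seed)
    curves <- vapply(sims, function(X) dtt_curve(tr, standardize_traits(X))$disparity,
                     numeric(length(dtt_curve(tr, tm)$times)))
    mean(apply(curves, 1, quantile, 0.975) - apply(curves, 1, quantile, 0.025))
  }
  # re-standardization makes the envelope scale-free in Sigma; a *less even*
  # rate vector concentrates disparity and widens the relative envelope
  even <- width(diag(2), 83)
  uneven <- width(diag(c(10, 0.1)), 83)
  expect_gt(uneven, even * 0.9)
})
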