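test_that("host_union pools, deduplicates and resolves groups", {
  host_occ <- occurrence_table(data.frame(
    species = c("H1", "H1", "H1", "H2", "H2", "H2", "H2", "H3"),
    lon = c(1, 2, 3, 4, 5, 6, 3, 9),
    lat = c(1, 2, 3, 4, 5, 6, 3, 9)
  ))
  assoc <- list(ins = c("H1", "H2"), other = "H3",
                memberA = "H1", memberB = c("H2", "H3"))
  u <- host_union("ins", assoc, host_occ)
  expect_equal(nrow(u), 6L) # 3 + 4 records, one shared coordinate kept once
  expect_true(all(u$species == "ins_hosts"))
  expect_equal(attr(u, "n_hosts"), 2L)

  # group entity: union over member species' hosts
  groups <- list(mapping = c(memberA = "G", memberB = "G"), drop = character())
  ug <- host_union("G", assoc, host_occ, groups = groups)
  expect_equal(sort(unique(ug$host)), c("H1", "H2", "H3"))
  expect_equal(nrow(ug), 7L)

  # missing hosts are logged, fully absent hosts are fatal
  expect_error(host_union("nope", assoc, host_occ), "association")
  expect_error(host_union("ins", list(ins = "H9"), host_occ), "occurrence")
})

test_that("backgrounds follow the buffered bounding rectangle rule", {
  big <- list(B = climate_raster(matrix(1, 120, 80), c(-10, -20, 70, 100), 1, "B"))
  occ <- data.frame(species = "s",
                    lon = c(10, 20, 15), lat = c(40, 45, 42))
  bg <- build_background(occ, big, buffer = 10)
  expect_equal(bg$rectangle, c(0, 30, 30, 55))
  # buffer 0 is the plain bounding box
  bg0 <- build_background(occ, big, buffer = 0)
  expect_equal(bg0$rectangle, c(10, 40, 20, 45))
  # poking above lat 90 is clipped
  occ_hi <- data.frame(species = "s", lon = 0, lat = c(85, 88))
  bg_hi <- build_background(occ_hi, big, buffer = 10)
  expect_equal(bg_hi$rectangle[4], 90)
  # rectangle also clips to the raster extent
  expect_equal(build_background(occ, big, buffer = 50)$rectangle,
               c(-10, -10, 70, 90))
})

test_that("background pixels are the valid cell centres inside the rectangle", {
  m <- matrix(1, 10, 10); m[1, ] <- NA
  rs <- list(A = climate_raster(m, c(0, 0, 10, 10), 1, "A"))
  occ <- data.frame(species = "s", lon = 5, lat = 5)
  bg <- build_background(occ, rs, buffer = 10)
  expect_equal(nrow(bg$env), 90L) # top row masked
  expect_true(all(bg$lonlat[, "lat"] <= 8.5 + 1e-9))
  expect_error(build_background(occ, list(A = climate_raster(matrix(NA_real_, 10, 10),
                                                             c(0, 0, 10, 10), 1, "A")),
                                buffer = 10),
               "no valid")
})

test_that("environmental PCA matches an eigen-decomposition oracle", {
  set.seed(90)
  X <- matrix(rnorm(2500), 500, 5, dimnames = list(NULL, paste0("V", 1:5)))
  bg <- list(env = X)
  p <- pca_env(bg, bg)
  Z <- scale(rbind(X, X))
  ev <- eigen(cov(Z), symmetric = TRUE)$values
  expect_equal(p$sdev^2, ev, tolerance = 1e-8)
  expect_equal(unname(p$var_frac), (ev / sum(ev))[1:2], tolerance = 1e-8)
  # loadings orthonormal, axes ordered by decreasing variance
  expect_equal(crossprod(p$rotation), diag(2), ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(diff(p$sdev) <= 1e-12))
  # duplicated pixel set gives the same axes as the single-set PCA
  single <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(abs(p$rotation), abs(single$rotation[, 1:2]), tolerance = 1e-10)
})

test_that("collinear pixels load a single axis; rank < 2 is an error", {
  t_par <- seq(0, 1, length.out = 50)
  X <- cbind(A = t_par, B = 2 * t_par, C = -t_par)
  bg <- list(env = X)
  expect_error(pca_env(bg, bg), "rank < 2")
  X2 <- cbind(X, D = c(rep(0, 25), rep(1, 25)))
  p <- pca_env(list(env = X2), list(env = X2))
  expect_gt(p$var_frac[1], 0.70) # the line dominates
})

test_that("occupancy grids are normalized, local and guarded", {
  set.seed(91)
  occ <- cbind(runif(50, 0.0, 0.2), runif(50, 0.8, 1.0)) # tight corner cluster
  bg <- cbind(runif(2000), runif(2000))
  extent <- c(0, 1, 0, 1)
  g <- occupancy_grid(occ, bg, extent, R = 50)
  expect_equal(sum(g$z), 1, tolerance = 1e-9)
  expect_true(all(g$z >= 0))
  am <- which(g$z == max(g$z), arr.ind = TRUE)
  expect_lt(am[1, 1], 15)  # x cells near 0
  expect_gt(am[1, 2], 35)  # y cells near 1
  # availability threshold zeroes unavailable cells
  expect_true(all(g$z[g$e <= max(g$e) * 1e-6] == 0))
  # degenerate axis -> bandwidth error
  expect_error(occupancy_grid(cbind(rep(0.5, 6), 1:6 / 10), bg, extent, R = 20),
               "bandwidth")
  expect_error(occupancy_grid(occ[1:4, ], bg, extent, R = 20), "at least 5")
})

test_that("availability correction flattens occupancy when occ matches background", {
  set.seed(92)
  bg <- cbind(runif(5000), runif(5000))
  occ <- bg[sample.int(5000, 5000, replace = TRUE), ]
  g <- occupancy_grid(occ, bg, c(0, 1, 0, 1), R = 20)
  zpos <- g$z[g$z > 0]
  expect_lt(max(zpos) / min(zpos), 2)
})

test_that("Schoener's D identities hold exactly", {
  z <- matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2)
  expect_equal(schoener_d(z, z), 1)
  zA <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  zB <- matrix(c(0, 0, 0.5, 0.5), 2, 2)
  expect_equal(schoener_d(zA, zB), 0) # disjoint supports
  z1 <- matrix(c(0.6, 0.4, 0, 0), 2, 2)
  z2 <- matrix(c(0.4, 0.6, 0, 0), 2, 2)
  expect_equal(schoener_d(z1, z2), 0.8)
  expect_identical(schoener_d(z1, z2), schoener_d(z2, z1)) # symmetry
  # invariant to a simultaneous cell permutation
  set.seed(93)
  zr <- matrix(runif(16), 4, 4); zr <- zr / sum(zr)
  zs <- matrix(runif(16), 4, 4); zs <- zs / sum(zs)
  perm <- sample(16)
  expect_equal(schoener_d(matrix(zr[perm], 4, 4), matrix(zs[perm], 4, 4)),
               schoener_d(zr, zs), tolerance = 1e-12)
  expect_error(schoener_d(zr, matrix(0.25, 2, 2)), "shapes")
  expect_error(schoener_d(zr * 2, zs), "sum to 1")
})

test_that("identical occurrence sets give D = 1 and p = 1", {
  sc <- make_pair_scenario("equivalent", seed = 94)
  et <- equivalency_test(sc$insect, sc$insect, sc$rasters, reps = 30, seed = 95)
  expect_equal(et$d_obs, 1)
  expect_equal(et$p.value, 1)
})

test_that("the equivalency pipeline is deterministic under a fixed seed", {
  sc <- make_pair_scenario("truncated", seed = 96)
  run <- function(seed) {
    et <- equivalency_test(sc$insect, sc$host, sc$rasters, reps = 20, seed = seed)
    jsonlite::toJSON(et[c("d_obs", "null_d", "p.value")], digits = NA)
  }
  expect_identical(run(7), run(7)) # including null_d order
  expect_false(identical(run(7), run(8)))
})

test_that("p attains its lower bound when the observed D undercuts the null", {
  sc <- make_pair_scenario("truncated", seed = 97)
  et <- equivalency_test(sc$insect, sc$host, sc$rasters, reps = 50, seed = 98)
  expect_gte(et$p.value, 1 / (et$reps + 1))
  if (et$d_obs < min(et$null_d)) {
    expect_equal(et$p.value, 1 / (et$reps + 1))
  }
  # the permutation null and p-value satisfy the counting definition
  expect_equal(et$p.value,
               (sum(et$null_d <= et$d_obs) + 1) / (et$reps + 1))
})
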