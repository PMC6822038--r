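#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward pure-birth simulation: starting from the root's two daughter
#' lineages, waiting times between speciation events are exponential with
#' rate `birth_rate` times the current lineage count, and the lineage that
#' splits is chosen uniformly. After the n-th lineage appears the present
#' is placed one further exponential waiting time (rate `n * birth_rate`)
#' later, so the expected number of lineages grows exponentially at the
#' birth rate. Tips are labelled `t1..tn`; branch lengths are in the same
#' time units as `1 / birth_rate`.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate per lineage per time unit.
#' @param seed optional integer; the generator is a pure function of
#'   (parameters, seed).
#' @return Ultrametric [ape::phylo] with attribute `"ultrametric" = TRUE`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 3, birth_rate > 0)
  with_seed(seed, {
    nodes <- list(list(start = 0, children = NULL, split = NA_real_),
                  list(start = 0, children = NULL, split = NA_real_))
    active <- c(1L, 2L)
    t <- 0
    k <- 2L
    while (k < n_tips) {
      t <- t + stats::rexp(1L, rate = birth_rate * k)
      i <- active[sample.int(k, 1L)]
      nodes[[i]]$split <- t
      id1 <- length(nodes) + 1L
      id2 <- length(nodes) + 2L
      nodes[[id1]] <- list(start = t, children = NULL, split = NA_real_)
      nodes[[id2]] <- list(start = t, children = NULL, split = NA_real_)
      nodes[[i]]$children <- c(id1, id2)
      active <- c(active[active != i], id1, id2)
      k <- k + 1L
    }
    present <- t + stats::rexp(1L, rate = birth_rate * n_tips)
    counter <- new.env()
    counter$tip <- 0L
    build <- function(i) {
      nd <- nodes[[i]]
      if (is.null(nd$children)) {
        counter$tip <- counter$tip + 1L
        sprintf("t%d:%.12f", counter$tip, present - nd$start)
      } else {
        sprintf("(%s,%s):%.12f", build(nd$children[1L]), build(nd$children[2L]),
                nd$split - nd$start)
      }
    }
    txt <- sprintf("(%s,%s);", build(1L), build(2L))
    tree <- ape::read.tree(text = txt)
    attr(tree, "ultrametric") <- TRUE
    tree
  })
}

#' Simulate traits under lambda-transformed Brownian motion
#'
#' Draws one tip trait matrix from the Gaussian model whose tip covariance
#' is the lambda-transformed phylogenetic covariance (Kronecker) the rate
#' matrix `Sigma`, with mean `root` per variable. `lambda = 1` is pure
#' Brownian motion; `lambda = 0` makes tips independent.
#'
#' @param tree dated tree.
#' @param lambda value in \[0, 1\].
#' @param Sigma rate (co)variance matrix of the variables (must be nonzero).
#' @param root root state, recycled over variables.
#' @param seed optional integer seed.
#' @return Tips x variables matrix with attribute `"standardized" = FALSE`.
#' @export
simulate_lambda_bm <- function(tree, lambda, Sigma, root = 0, seed = NULL) {
  Sigma <- as.matrix(Sigma)
  if (all(Sigma == 0)) stop("Sigma must not be identically zero")
  C <- lambda_transform(tree_vcv(tree), lambda)
  LC <- mat_sqrt(C)
  LS <- mat_sqrt(Sigma)
  n <- nrow(C)
  p <- nrow(Sigma)
  root <- rep_len(root, p)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    X <- t(LC) %*% Z %*% LS
    X <- sweep(X, 2L, root, "+")
    dimnames(X) <- list(rownames(C), colnames(Sigma))
    attr(X, "standardized") <- FALSE
    X
  })
}

#' Default gradient parameters for the five bioclimatic variables
#'
#' Linear latitude/longitude gradients with magnitudes chosen to resemble
#' Northern-Hemisphere continental climatologies (temperatures in degrees
#' Celsius declining poleward, driest-quarter precipitation in millimetres
#' varying along longitude), plus independent Gaussian cell noise.
#'
#' @return Named list of per-variable parameter lists
#'   (`base`, `lat_slope`, `lon_slope`, `noise_sd`).
#' @export
default_raster_params <- function() {
  list(
    BIO5  = list(base = 45, lat_slope = 0.5, lon_slope = 0,   noise_sd = 0.5),
    BIO6  = list(base = 25, lat_slope = 0.9, lon_slope = 0,   noise_sd = 0.5),
    BIO10 = list(base = 40, lat_slope = 0.5, lon_slope = 0,   noise_sd = 0.5),
    BIO11 = list(base = 30, lat_slope = 0.8, lon_slope = 0,   noise_sd = 0.5),
    BIO17 = list(base = 10, lat_slope = 0,   lon_slope = 0.8, noise_sd = 2)
  )
}

#' Generate synthetic gradient climate rasters
#'
#' Each variable is a deterministic gradient over the grid,
#' `base - lat_slope * |lat| + lon_slope * (lon - lon_min)`, plus Gaussian
#' cell noise that may be correlated across variables. An optional nodata
#' border masks the outermost cells.
#'
#' @param extent `c(lon_min, lat_min, lon_max, lat_max)` degrees; the
#'   default desk-scale grid spans 60 degrees of longitude and 30 of
#'   latitude.
#' @param resolution cell size in degrees.
#' @param params per-variable gradient specification (see
#'   [default_raster_params()]).
#' @param noise_cor optional correlation matrix of the cell noise across
#'   variables (identity by default).
#' @param nodata_border width, in cells, of an `NA` border (0 = none).
#' @param seed optional integer seed.
#' @return Named list of [climate_raster] objects.
#' @export
make_synthetic_rasters <- function(extent = c(-30, 20, 30, 50), resolution = 0.5,
                                   params = default_raster_params(),
                                   noise_cor = NULL, nodata_border = 0,
                                   seed = NULL) {
  ncols <- round((extent[3] - extent[1]) / resolution)
  nrows <- round((extent[4] - extent[2]) / resolution)
  lon <- extent[1] + (seq_len(ncols) - 0.5) * resolution
  lat <- extent[4] - (seq_len(nrows) - 0.5) * resolution
  lon_m <- matrix(lon, nrows, ncols, byrow = TRUE)
  lat_m <- matrix(lat, nrows, ncols)
  p <- length(params)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(nrows * ncols * p), nrows * ncols, p)
    if (!is.null(noise_cor)) Z <- Z %*% mat_sqrt(noise_cor)
    out <- vector("list", p)
    names(out) <- names(params)
    for (k in seq_len(p)) {
      pk <- params[[k]]
      vals <- pk$base - pk$lat_slope * abs(lat_m) +
        pk$lon_slope * (lon_m - extent[1]) +
        pk$noise_sd * matrix(Z[, k], nrows, ncols)
      if (nodata_border > 0) {
        b <- seq_len(nodata_border)
        vals[b, ] <- NA; vals[nrow(vals) + 1 - b, ] <- NA
        vals[, b] <- NA; vals[, ncol(vals) + 1 - b] <- NA
      }
      out[[k]] <- climate_raster(vals, extent, resolution, names(params)[k])
    }
    out
  })
}

#' Specify a Gaussian climatic niche
#'
#' @param center named per-variable optimum, in the rasters' units.
#' @param breadth named per-variable Gaussian s.d. (> 0).
#' @param truncation optional named list of one-sided hard cuts per
#'   variable, each `c(max = q)` or `c(min = q)`: suitability is zero
#'   beyond the cut (e.g. "no cells warmer than q").
#' @return Object of class `niche_spec`.
#' @export
niche_spec <- function(center, breadth, truncation = NULL) {
  stopifnot(length(center) == length(breadth), all(breadth > 0))
  if (is.null(names(center))) stop("center must be named by variable")
  structure(list(center = center, breadth = breadth, truncation = truncation),
            class = "niche_spec")
}

#' Sample occurrences from climatic suitability
#'
#' Cell suitability is the unnormalized Gaussian
#' `exp(-sum_v (value_v - center_v)^2 / (2 * breadth_v^2))`, with any
#' truncation applied as a hard zero; cells are sampled with probability
#' proportional to suitability (with replacement) and each point is placed
#' uniformly within its cell. Geography couples to climate only through
#' the rasters.
#'
#' @param rasters list of [climate_raster].
#' @param niche [niche_spec()].
#' @param n number of points.
#' @param species species label for the output table.
#' @param seed optional integer seed.
#' @return Occurrence table (`species`, `lon`, `lat`).
#' @export
sample_occurrences <- function(rasters, niche, n, species = "sp1", seed = NULL) {
  cells <- raster_cell_table(rasters)
  vars <- names(niche$center)
  miss <- setdiff(vars, names(cells))
  if (length(miss)) stop("niche variables missing from rasters: ", paste(miss, collapse = ", "))
  ll <- 0
  for (v in vars) {
    ll <- ll - (cells[[v]] - niche$center[[v]])^2 / (2 * niche$breadth[[v]]^2)
  }
  suit <- exp(ll - max(ll))
  if (!is.null(niche$truncation)) {
    for (v in names(niche$truncation)) {
      cut <- niche$truncation[[v]]
      if ("max" %in% names(cut)) suit[cells[[v]] > cut[["max"]]] <- 0
      if ("min" %in% names(cut)) suit[cells[[v]] < cut[["min"]]] <- 0
    }
  }
  if (all(suit == 0)) stop("all-zero suitability: no cell satisfies the niche")
  res <- rasters[[1L]]$resolution
  with_seed(seed, {
    idx <- sample.int(nrow(cells), size = n, replace = TRUE, prob = suit)
    lon <- cells$lon[idx] + stats::runif(n, -res / 2, res / 2)
    lat <- cells$lat[idx] + stats::runif(n, -res / 2, res / 2)
    data.frame(species = species, lon = lon, lat = lat)
  })
}

#' Generate an insect/host occurrence pair with known ground truth
#'
#' The host is sampled from a broad Gaussian niche centred on mid-latitude
#' climate. The insect is sampled either from the identical niche
#' (`kind = "equivalent"`) or from the same niche hard-truncated at its
#' own optimum of the warmest-month maximum temperature
#' (`kind = "truncated"`), i.e. restricted to the colder half of the host's
#' climatic range — the pattern shown by host-specialized insects whose
#' climatic tolerance is narrower than their hosts'.
#'
#' @param kind `"equivalent"` or `"truncated"`.
#' @param params optional overrides: `rasters`, `host_niche`,
#'   `n_insect` (default 50), `n_host` (default 50).
#' @param seed optional integer seed; the scenario is a pure function of
#'   (params, seed).
#' @return list with `insect` and `host` occurrence tables, `rasters`, and
#'   a `truth` record of the generating parameters.
#' @export
make_pair_scenario <- function(kind = c("equivalent", "truncated"),
                               params = list(), seed = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, {
    rasters <- params$rasters %||% make_synthetic_rasters()
    host_niche <- params$host_niche %||% niche_spec(
      center = c(BIO5 = 27.5, BIO6 = -6.5, BIO10 = 22.5, BIO11 = 2, BIO17 = 34),
      breadth = c(BIO5 = 4, BIO6 = 4, BIO10 = 4, BIO11 = 4, BIO17 = 12)
    )
    n_insect <- params$n_insect %||% 50
    n_host <- params$n_host %||% 50
    insect_niche <- if (kind == "equivalent") host_niche else {
      niche_spec(host_niche$center, host_niche$breadth,
                 truncation = list(BIO5 = c(max = unname(host_niche$center["BIO5"]))))
    }
    host <- sample_occurrences(rasters, host_niche, n_host, species = "host_pool")
    insect <- sample_occurrences(rasters, insect_niche, n_insect, species = "insect")
    list(
      insect = insect, host = host, rasters = rasters,
      truth = list(kind = kind, host_niche = host_niche,
                   insect_niche = insect_niche,
                   n_insect = n_insect, n_host = n_host, seed = seed)
    )
  })
}
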