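#' Pool the occurrences of all hosts of an insect
#'
#' The host-side niche of a host-specialized insect is represented by the
#' combination of the occurrences of all its host plants. When the insect
#' entity is a species group, the hosts of every member species are pooled.
#' Records sharing exact coordinates across hosts are kept once; the pooled
#' table carries a single pseudo-species label `<insect>_hosts` (the source
#' host of each record is preserved in a `host` column).
#'
#' @param insect insect species or group identifier.
#' @param assoc association list from [read_host_associations()].
#' @param host_occ occurrence table of host plants.
#' @param groups optional species-group mapping (list with `mapping`), used
#'   to resolve group membership.
#' @return Pooled occurrence table.
#' @export
host_union <- function(insect, assoc, host_occ, groups = NULL) {
  members <- insect
  if (!is.null(groups) && length(groups$mapping)) {
    members <- unique(c(members, names(groups$mapping)[groups$mapping == insect]))
  }
  members <- intersect(members, names(assoc))
  if (length(members) == 0L) stop("no host association found for ", insect)
  hosts <- unique(unlist(assoc[members], use.names = FALSE))
  present <- hosts %in% host_occ$species
  if (any(!present)) {
    pn_log("host_union(%s): %d host(s) without occurrences: %s", insect,
           sum(!present), paste(hosts[!present], collapse = ", "))
  }
  if (!any(present)) stop("none of the hosts of ", insect, " has occurrence records")
  sub <- host_occ[host_occ$species %in% hosts, , drop = FALSE]
  sub$host <- sub$species
  sub$species <- paste0(insect, "_hosts")
  sub <- sub[!duplicated(sub[, c("lon", "lat")]), , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "hosts") <- hosts
  attr(sub, "n_hosts") <- length(hosts)
  sub
}

#' Environmental background of a species
#'
#' The background (available environment) of a species is the rectangle
#' spanned by the minimum and maximum longitude and latitude of its
#' occurrences, broadened by `buffer` degrees in all directions (10 by
#' default, a conservative widening intended to encompass the reachable
#' environment), then clipped to the raster extent and to valid latitudes.
#' Every raster cell whose centre lies in the rectangle and that has valid
#' values in all variables contributes one row of climate values.
#'
#' @param occ occurrence table of one entity.
#' @param rasters list of [climate_raster] sharing a grid.
#' @param buffer widening of the bounding rectangle, degrees.
#' @return Object of class `env_background`: `rectangle`
#'   (`c(lon_min, lat_min, lon_max, lat_max)`), `env` (cells x variables
#'   matrix), `lonlat` (cell centres).
#' @export
build_background <- function(occ, rasters, buffer = 10) {
  if (nrow(occ) < 1L) stop("no occurrences to build a background from")
  r1 <- check_raster_stack(rasters)
  rect <- c(min(occ$lon) - buffer, min(occ$lat) - buffer,
            max(occ$lon) + buffer, max(occ$lat) + buffer)
  rect[1] <- max(rect[1], r1$extent[1])
  rect[2] <- max(rect[2], r1$extent[2], -90)
  rect[3] <- min(rect[3], r1$extent[3])
  rect[4] <- min(rect[4], r1$extent[4], 90)
  cells <- raster_cell_table(rasters, rect = rect)
  if (nrow(cells) == 0L) stop("background rectangle contains no valid raster cells")
  structure(
    list(rectangle = rect,
         env = as.matrix(cells[, setdiff(names(cells), c("lon", "lat")), drop = FALSE]),
         lonlat = as.matrix(cells[, c("lon", "lat")])),
    class = "env_background"
  )
}

#' Environmental-space PCA over two pooled backgrounds
#'
#' Calibrates a principal component analysis on the pooled background
#' pixels of the two entities being compared (variables centred and scaled
#' to unit variance) and retains the first two axes. All occurrence and
#' background climate rows are later projected into this common plane.
#'
#' @param bgA,bgB [build_background()] results.
#' @return Object of class `pca_env`: `center`, `scale`, `rotation`
#'   (variables x 2), `sdev`, `var_frac` (explained-variance fractions of
#'   the retained axes).
#' @export
pca_env <- function(bgA, bgB) {
  X <- rbind(bgA$env, bgB$env)
  if (nrow(X) < 3L) stop("need at least 3 pooled background pixels")
  sds <- apply(X, 2L, stats::sd)
  if (sum(sds > 0) < 2L) stop("need at least 2 variables with nonzero variance")
  X <- X[, sds > 0, drop = FALSE]
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (length(p$sdev) < 2L || p$sdev[2L] <= 1e-12 * p$sdev[1L]) {
    stop("pooled background has rank < 2 in environmental space")
  }
  structure(
    list(center = p$center, scale = p$scale,
         rotation = p$rotation[, 1:2, drop = FALSE],
         sdev = p$sdev,
         var_frac = (p$sdev^2 / sum(p$sdev^2))[1:2]),
    class = "pca_env"
  )
}

#' Project climate rows onto the first two environmental PCA axes
#'
#' @param pca [pca_env()] result.
#' @param X matrix or data frame of climate values (columns matching the
#'   PCA's variables).
#' @return Two-column score matrix.
#' @export
project_pca <- function(pca, X) {
  X <- as.matrix(X[, names(pca$center), drop = FALSE])
  scale(X, center = pca$center, scale = pca$scale) %*% pca$rotation
}

# Product Gaussian kernel density of `pts` (2-col matrix) evaluated at the
# R x R cell centres of `extent` = c(xmin, xmax, ymin, ymax); bandwidths
# per axis. Implemented as an outer product of axis kernels.
kernel_density_grid <- function(pts, extent, R, h) {
  if (any(h <= 0) || any(!is.finite(h))) {
    stop("zero or non-finite kernel bandwidth (all points identical on an axis?)")
  }
  dx <- (extent[2] - extent[1]) / R
  dy <- (extent[4] - extent[3]) / R
  gx <- extent[1] + (seq_len(R) - 0.5) * dx
  gy <- extent[3] + (seq_len(R) - 0.5) * dy
  Kx <- stats::dnorm(outer(gx, pts[, 1L], "-") / h[1]) / h[1]
  Ky <- stats::dnorm(outer(gy, pts[, 2L], "-") / h[2]) / h[2]
  (Kx %*% t(Ky)) / nrow(pts)
}

#' Corrected occupancy grid in environmental space
#'
#' Grids the environmental plane (first two PCA axes) into `R` x `R` cells
#' over `extent` and estimates at each cell centre the occurrence density
#' `o` (Gaussian product kernel over the entity's occurrence scores,
#' per-axis normal-reference (Silverman) bandwidths) and the availability
#' density `e` (same estimator over the entity's background scores). The
#' occupancy `z` divides occurrence density by availability so that overlap
#' measures preference rather than background climate frequency, sets cells
#' with negligible availability (`e <= 1e-6 * max(e)`) to zero to avoid
#' division blow-ups, and normalizes to sum 1.
#'
#' @param occ_scores two-column matrix of occurrence scores (>= 5 rows).
#' @param bg_scores two-column matrix of background scores.
#' @param extent `c(xmin, xmax, ymin, ymax)` in score space; must cover all
#'   scores.
#' @param R grid resolution per axis (default 100).
#' @param e_grid optional precomputed availability density (matrix from a
#'   previous call), so permutation replicates can reuse it.
#' @return Object of class `occupancy_grid`: `R`, `extent`, `o`, `e`, `z`,
#'   `h_occ`, `h_bg`.
#' @export
occupancy_grid <- function(occ_scores, bg_scores, extent, R = 100, e_grid = NULL) {
  occ_scores <- rbind(occ_scores)
  if (nrow(occ_scores) < 5L) stop("need at least 5 occurrence score rows")
  eps <- 1e-9 * max(abs(extent), 1)
  if (min(occ_scores[, 1]) < extent[1] - eps || max(occ_scores[, 1]) > extent[2] + eps ||
      min(occ_scores[, 2]) < extent[3] - eps || max(occ_scores[, 2]) > extent[4] + eps) {
    stop("extent does not cover all occurrence scores")
  }
  if (any(apply(occ_scores, 2L, stats::sd) == 0)) {
    stop("zero kernel bandwidth: all occurrence scores identical on an axis")
  }
  h_occ <- c(stats::bw.nrd0(occ_scores[, 1L]), stats::bw.nrd0(occ_scores[, 2L]))
  o <- kernel_density_grid(occ_scores, extent, R, h_occ)
  if (is.null(e_grid)) {
    h_bg <- c(stats::bw.nrd0(bg_scores[, 1L]), stats::bw.nrd0(bg_scores[, 2L]))
    e <- kernel_density_grid(bg_scores, extent, R, h_bg)
  } else {
    e <- e_grid$e
    h_bg <- e_grid$h_bg
  }
  avail <- e > max(e) * 1e-6
  raw <- matrix(0, R, R)
  raw[avail] <- o[avail] / e[avail]
  z <- raw / sum(raw)
  structure(list(R = R, extent = extent, o = o, e = e, z = z,
                 h_occ = h_occ, h_bg = h_bg),
            class = "occupancy_grid")
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|zA - zB|)` over the cells of two corrected occupancy
#' grids of identical shape, each summing to 1. D is 0 for disjoint niches
#' and 1 for identical ones.
#'
#' @param zA,zB [occupancy_grid()] objects or plain occupancy matrices.
#' @return Overlap value in \[0, 1\].
#' @export
schoener_d <- function(zA, zB) {
  if (inherits(zA, "occupancy_grid")) zA <- zA$z
  if (inherits(zB, "occupancy_grid")) zB <- zB$z
  if (!all(dim(zA) == dim(zB))) stop("occupancy grids have different shapes")
  for (z in list(zA, zB)) {
    if (abs(sum(z) - 1) > 1e-6) stop("occupancy grid does not sum to 1")
  }
  min(1, max(0, 1 - 0.5 * sum(abs(zA - zB))))
}

#' Niche equivalency test between two sets of occurrences
#'
#' Implements the pooled-split permutation test of niche equivalency in
#' environmental space. The fixed pipeline is: extract climate at both
#' entities' occurrence points; build each entity's buffered-rectangle
#' background; calibrate one PCA on the two pooled backgrounds; project
#' occurrences and backgrounds; grid the plane over the range of the pooled
#' background scores; build both corrected occupancy grids; compute the
#' observed Schoener's D. The null distribution then pools the two
#' entities' occurrence scores and, `reps` times, randomly splits them into
#' two sets of the original sizes and recomputes D with backgrounds, PCA,
#' grid extent and availability densities frozen (only the occurrence
#' kernel bandwidths are recomputed, since subset sizes differ).
#'
#' The default alternative is one-sided: niches are declared non-equivalent
#' when the observed D is low relative to the null, with
#' `p = (#\{D_null <= D_obs\} + 1) / (reps + 1)`.
#'
#' @param occA,occB occurrence tables of the two entities (e.g. an insect
#'   and the pooled range of its hosts); each needs >= 5 records with valid
#'   climate.
#' @param rasters list of [climate_raster] sharing a grid.
#' @param reps number of pooled-split permutations (default 100).
#' @param seed optional integer seed; fixed seed gives byte-identical
#'   results.
#' @param buffer background rectangle widening, degrees (default 10).
#' @param R occupancy grid resolution (default 100).
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return Object of class `equivalency_test`: `d_obs`, `null_d`,
#'   `p.value`, `n_A`, `n_B`, `reps`, `seed`, `alternative`, plus the
#'   fitted `pca` and both grids.
#' @export
equivalency_test <- function(occA, occB, rasters, reps = 100, seed = NULL,
                             buffer = 10, R = 100,
                             alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (reps < 1) stop("reps must be >= 1")
  valA <- extract_at_points(rasters, occA)
  valB <- extract_at_points(rasters, occB)
  if (nrow(valA) < 5L || nrow(valB) < 5L) {
    stop(sprintf("need >= 5 records with valid climate on each side (have %d and %d)",
                 nrow(valA), nrow(valB)))
  }
  vars <- setdiff(names(valA), c("species", "lon", "lat"))
  bgA <- build_background(valA, rasters, buffer = buffer)
  bgB <- build_background(valB, rasters, buffer = buffer)
  pca <- pca_env(bgA, bgB)
  sA <- project_pca(pca, valA[, vars, drop = FALSE])
  sB <- project_pca(pca, valB[, vars, drop = FALSE])
  bsA <- project_pca(pca, bgA$env)
  bsB <- project_pca(pca, bgB$env)
  pooled_bg <- rbind(bsA, bsB)
  extent <- c(range(pooled_bg[, 1L]), range(pooled_bg[, 2L]))
  gA <- occupancy_grid(sA, bsA, extent, R = R)
  gB <- occupancy_grid(sB, bsB, extent, R = R)
  d_obs <- schoener_d(gA, gB)
  pooled <- rbind(sA, sB)
  nA <- nrow(sA); nB <- nrow(sB); n <- nA + nB
  null_d <- with_seed(seed, vapply(seq_len(reps), function(r) {
    perm <- sample.int(n)
    pA <- pooled[perm[seq_len(nA)], , drop = FALSE]
    pB <- pooled[perm[nA + seq_len(nB)], , drop = FALSE]
    schoener_d(
      occupancy_grid(pA, NULL, extent, R = R, e_grid = gA),
      occupancy_grid(pB, NULL, extent, R = R, e_grid = gB)
    )
  }, numeric(1)))
  p_low <- (sum(null_d <= d_obs) + 1) / (reps + 1)
  p <- if (alternative == "less") p_low else {
    p_high <- (sum(null_d >= d_obs) + 1) / (reps + 1)
    min(1, 2 * min(p_low, p_high))
  }
  structure(
    list(d_obs = d_obs, null_d = null_d, p.value = p,
         n_A = nA, n_B = nB, reps = reps, seed = seed,
         alternative = alternative, buffer = buffer, R = R,
         pca = pca, grid_A = gA, grid_B = gB),
    class = "equivalency_test"
  )
}

#' @export
print.equivalency_test <- function(x, ...) {
  cat("Niche equivalency test (pooled-split permutation)\n")
  cat(sprintf("  Schoener's D observed = %.3f  (n = %d vs %d, %d permutations)\n",
              x$d_obs, x$n_A, x$n_B, x$reps))
  cat(sprintf("  null D: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$null_d), min(x$null_d), max(x$null_d)))
  cat(sprintf("  p = %.4g (%s)%s\n", x$p.value,
              if (x$alternative == "less") "one-sided, low D = non-equivalent"
              else "two-sided",
              if (x$p.value <= 0.05) "  -> niche equivalency rejected" else ""))
  invisible(x)
}
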