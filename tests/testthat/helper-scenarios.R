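# End-to-end scenario: species' thermal optima evolve along the tree under
# lambda-transformed Brownian motion; each species' occurrences are sampled
# around the climate found at its optimal latitude, so per-variable medians
# inherit the phylogenetic signal of the latitude optimum.
make_signal_scenario <- function(n_tips = 30, lambda = 1, n_occ = 10, seed = 1) {
  set.seed(seed)
  rasters <- make_synthetic_rasters()
  tree <- simulate_yule_tree(n_tips, 1)
  x <- simulate_lambda_bm(tree, lambda, matrix(1))[, 1]
  lat_opt <- pmin(48, pmax(22, 35 + 5 * x / sd(x)))
  occ <- do.call(rbind, lapply(seq_along(lat_opt), function(i) {
    lat <- lat_opt[i]
    ctr <- c(BIO5 = 45 - 0.5 * lat, BIO6 = 25 - 0.9 * lat,
             BIO10 = 40 - 0.5 * lat, BIO11 = 30 - 0.8 * lat, BIO17 = 34)
    sample_occurrences(rasters,
                       niche_spec(ctr, c(BIO5 = 1, BIO6 = 1, BIO10 = 1,
                                         BIO11 = 1, BIO17 = 8)),
                       n_occ, species = tree$tip.label[i])
  }))
  list(tree = tree, occ = occ, rasters = rasters, lat_opt = lat_opt)
}

# Three-entity equivalency batch: two equivalent insect/host pairs and one
# cold-truncated pair on a shared raster stack, with per-entity host species
# relabelled so the association table is realistic.
make_batch_scenario <- function(seed = 1, n = 50) {
  set.seed(seed)
  rasters <- make_synthetic_rasters()
  kinds <- c(ins_eq1 = "equivalent", ins_eq2 = "equivalent", ins_tr = "truncated")
  insects <- list(); hosts <- list(); assoc <- list()
  for (i in seq_along(kinds)) {
    ent <- names(kinds)[i]
    sc <- make_pair_scenario(kinds[[i]], params = list(rasters = rasters,
                                                       n_insect = n, n_host = n))
    sc$insect$species <- ent
    host_name <- paste0("Pinus_", i)
    sc$host$species <- host_name
    insects[[ent]] <- sc$insect
    hosts[[ent]] <- sc$host
    assoc[[ent]] <- host_name
  }
  list(rasters = rasters,
       insect_occ = do.call(rbind, insects),
       host_occ = do.call(rbind, hosts),
       assoc = assoc)
}
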