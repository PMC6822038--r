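#' Assemble a pipeline run configuration
#'
#' Bundles input locations (or in-memory objects) and analysis parameters.
#' All parameter defaults are the conventional values of the method:
#' minimum 5 records per species, a 10-degree background buffer, occupancy
#' grids at R = 100, 100 equivalency permutations, 1000 Brownian
#' simulations, median summaries and the mean Euclidean disparity metric.
#'
#' Inputs may be file paths (read with the package readers) or the
#' corresponding in-memory objects (a `phylo` tree, occurrence data
#' frames, a named list of `climate_raster`s, an association list), which
#' makes the orchestration functions directly scriptable.
#'
#' @param tree path to a Newick file or an [ape::phylo].
#' @param occurrences path or occurrence table for the focal (insect)
#'   species.
#' @param rasters named character vector of raster paths or a named list
#'   of [climate_raster].
#' @param host_occurrences path or occurrence table of host plants
#'   (equivalency only).
#' @param association path or association list (equivalency only).
#' @param groups path or species-group list, optional.
#' @param min_n,buffer,R,reps,n_sim,summary,metric,seed analysis
#'   parameters; see Details.
#' @param outdir optional output directory for CSV/JSON reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(tree = NULL, occurrences = NULL, rasters = NULL,
                       host_occurrences = NULL, association = NULL,
                       groups = NULL, min_n = 5, buffer = 10, R = 100,
                       reps = 100, n_sim = 1000,
                       summary = c("median", "min", "max"),
                       metric = c("euclidean", "squared"),
                       seed = NULL, outdir = NULL) {
  structure(
    list(tree = tree, occurrences = occurrences, rasters = rasters,
         host_occurrences = host_occurrences, association = association,
         groups = groups, min_n = min_n, buffer = buffer, R = R,
         reps = reps, n_sim = n_sim, summary = match.arg(summary),
         metric = match.arg(metric), seed = seed, outdir = outdir),
    class = "run_config"
  )
}

# Resolve a config entry that may be a path or an object.
resolve_input <- function(x, reader, what) {
  if (is.null(x)) stop("config is missing the ", what, " input", call. = FALSE)
  if (is.character(x) && length(x) == 1L && !dir.exists(x)) {
    if (!file.exists(x)) stop(what, " path does not exist: ", x, call. = FALSE)
    return(reader(x))
  }
  x
}

resolve_rasters <- function(x) {
  if (is.null(x)) stop("config is missing the rasters input", call. = FALSE)
  if (is.character(x)) {
    paths <- x
    if (length(paths) == 1L && dir.exists(paths)) {
      paths <- list.files(paths, pattern = "\\.(asc|txt)$", full.names = TRUE)
      if (length(paths) == 0L) stop("no .asc rasters found in directory")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("raster path(s) do not exist: ", paste(missing, collapse = ", "))
    out <- lapply(paths, read_raster)
    names(out) <- vapply(out, function(r) r$variable_id, character(1))
    return(out)
  }
  x
}

resolve_config_inputs <- function(cfg, need = character()) {
  out <- list()
  if ("tree" %in% need) {
    out$tree <- if (is.character(cfg$tree)) resolve_input(cfg$tree, read_time_tree, "tree")
    else resolve_input(cfg$tree, identity, "tree")
  }
  if ("occurrences" %in% need) {
    out$occ <- if (is.character(cfg$occurrences))
      resolve_input(cfg$occurrences, read_occurrences, "occurrences")
    else resolve_input(cfg$occurrences, identity, "occurrences")
  }
  if ("rasters" %in% need) out$rasters <- resolve_rasters(cfg$rasters)
  if ("host_occurrences" %in% need) {
    out$host_occ <- if (is.character(cfg$host_occurrences))
      resolve_input(cfg$host_occurrences, read_occurrences, "host occurrences")
    else resolve_input(cfg$host_occurrences, identity, "host occurrences")
  }
  if ("association" %in% need) {
    out$assoc <- if (is.character(cfg$association))
      resolve_input(cfg$association, read_host_associations, "association")
    else resolve_input(cfg$association, identity, "association")
  }
  if (!is.null(cfg$groups)) {
    out$groups <- if (is.character(cfg$groups))
      resolve_input(cfg$groups, read_species_groups, "species groups")
    else cfg$groups
  }
  out
}

# Shared front half of the trait pipeline: group, filter, extract, summarize.
prepare_traits <- function(cfg, need_tree = TRUE) {
  inp <- resolve_config_inputs(cfg, c(if (need_tree) "tree", "occurrences", "rasters"))
  occ <- apply_species_groups(inp$occ, inp$groups)
  if (need_tree) {
    flt <- filter_min_occurrences(occ, inp$tree, min_n = cfg$min_n)
    occ <- flt$occ
    inp$tree <- flt$tree
  }
  values <- extract_at_points(inp$rasters, occ)
  summ <- summarize_species(values)
  pn_log("pipeline: %d species summarized over %d variables",
         length(unique(summ$species)), length(unique(summ$variable)))
  list(tree = inp$tree, occ = occ, rasters = inp$rasters,
       values = values, summary = summ, groups = inp$groups,
       assoc = NULL)
}

# Prune tree/traits to their common species (species can drop below the
# occurrence floor after nodata filtering).
align_tree_traits <- function(tree, tm) {
  common <- intersect(tree$tip.label, rownames(tm))
  if (length(common) < 3L) stop("fewer than 3 species shared by tree and traits")
  tree <- prune_tree(tree, common)
  list(tree = tree, tm = tm[tree$tip.label, , drop = FALSE])
}

#' Run the phylogenetic-signal analysis end to end
#'
#' Reads all inputs, applies grouping and the minimum-occurrence filter,
#' extracts climate, summarizes species and fits maximum-likelihood
#' Pagel's lambda (with the lambda = 0 likelihood-ratio test) for every
#' bioclimatic variable, for each of the median, minimum and maximum
#' per-species summaries.
#'
#' @param cfg a [run_config()].
#' @return list: `results` (data frame: one row per variable per summary
#'   statistic), `traits` (list of the three trait matrices), `tree`,
#'   `config`. Written to `signal.csv` / `signal.json` under
#'   `cfg$outdir` when set.
#' @export
run_signal <- function(cfg) {
  prep <- prepare_traits(cfg, need_tree = TRUE)
  stats_used <- c("median", "min", "max")
  traits <- lapply(stats_used, function(s) trait_matrix(prep$summary, stat = s))
  names(traits) <- stats_used
  results <- do.call(rbind, lapply(stats_used, function(s) {
    al <- align_tree_traits(prep$tree, traits[[s]])
    fit_lambda_table(al$tree, al$tm, summary_used = s)
  }))
  rownames(results) <- NULL
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(cfg$outdir, "signal.csv"), row.names = FALSE)
    jsonlite::write_json(results, file.path(cfg$outdir, "signal.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(list(results = results, traits = traits, tree = prep$tree, config = cfg))
}

#' Run the disparity-through-time analysis end to end
#'
#' Median per-species climate summaries are standardized and fed to
#' [dtt_envelope()] with `cfg$n_sim` Brownian simulations.
#'
#' @param cfg a [run_config()].
#' @return list: `dtt` (the [dtt_envelope()] object), `tree`, `config`.
#'   Written to `dtt.json` under `cfg$outdir` when set.
#' @export
run_dtt <- function(cfg) {
  prep <- prepare_traits(cfg, need_tree = TRUE)
  tm <- trait_matrix(prep$summary, stat = cfg$summary)
  al <- align_tree_traits(prep$tree, tm)
  res <- dtt_envelope(al$tree, standardize_traits(al$tm),
                      n_sim = cfg$n_sim, seed = cfg$seed, metric = cfg$metric)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res[c("times", "observed", "median", "q025", "q975",
                               "n_sim", "total_disparity")],
                         file.path(cfg$outdir, "dtt.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(dtt = res, tree = al$tree, config = cfg))
}

#' Run niche equivalency tests for every insect entity in the association
#'
#' For each insect species or group in the association table, pools the
#' occurrences of its hosts, and runs the pooled-split permutation test of
#' niche equivalency. Entities with fewer than `cfg$min_n` valid insect
#' occurrences are reported as NA rows rather than errors, as are
#' entity-level failures (the reason is recorded and the batch continues).
#'
#' @param cfg a [run_config()] with `occurrences`, `host_occurrences`,
#'   `association` and `rasters` set.
#' @return Data frame with one row per insect entity: `insect`, `d_obs`,
#'   `p.value`, `n_occurrences`, `n_hosts`, `note`. Written to
#'   `equivalency.csv` under `cfg$outdir` when set.
#' @export
run_equivalency_batch <- function(cfg) {
  inp <- resolve_config_inputs(cfg, c("occurrences", "rasters",
                                      "host_occurrences", "association"))
  if (length(inp$assoc) == 0L) stop("empty association table")
  occ <- apply_species_groups(inp$occ, inp$groups)
  entities <- if (!is.null(inp$groups) && length(inp$groups$mapping)) {
    unique(c(setdiff(names(inp$assoc), names(inp$groups$mapping)),
             unname(inp$groups$mapping[intersect(names(inp$assoc),
                                                 names(inp$groups$mapping))])))
  } else {
    names(inp$assoc)
  }
  rows <- lapply(sort(entities), function(ent) {
    occA <- occ[occ$species == ent, , drop = FALSE]
    na_row <- function(note, n_hosts = NA_integer_) {
      data.frame(insect = ent, d_obs = NA_real_, p.value = NA_real_,
                 n_occurrences = nrow(occA), n_hosts = n_hosts,
                 note = note, row.names = NULL)
    }
    if (nrow(occA) < cfg$min_n) {
      pn_log("equivalency[%s]: %d occurrence(s) < %d, reported as NA",
             ent, nrow(occA), cfg$min_n)
      return(na_row(sprintf("fewer than %d occurrences", cfg$min_n)))
    }
    tryCatch({
      occB <- host_union(ent, inp$assoc, inp$host_occ, groups = inp$groups)
      et <- equivalency_test(occA, occB, inp$rasters, reps = cfg$reps,
                             seed = cfg$seed, buffer = cfg$buffer, R = cfg$R)
      data.frame(insect = ent, d_obs = et$d_obs, p.value = et$p.value,
                 n_occurrences = et$n_A, n_hosts = attr(occB, "n_hosts"),
                 note = "", row.names = NULL)
    }, error = function(e) na_row(conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$outdir, "equivalency.csv"), row.names = FALSE)
  }
  out
}
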