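#' Read georeferenced occurrence records
#'
#' Reads a CSV with header columns `species`, `lon`, `lat` (extra columns
#' are preserved as source metadata). Rows with unparseable or out-of-bounds
#' coordinates (latitude outside \[-90, 90\]) are rejected with a logged
#' count; longitudes are normalized to \[-180, 180\]; exact duplicate
#' `(species, lon, lat)` rows are removed, as is conventional when cleaning
#' museum and database records. No grid-based thinning or datum
#' transformation is performed (coordinates are assumed WGS84 decimal
#' degrees).
#'
#' @param path CSV file path.
#' @return A deduplicated occurrence data frame with attributes
#'   `n_duplicates` and `n_rejected`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence CSV missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty occurrence file: ", path)
    return(structure(df, n_duplicates = 0L, n_rejected = 0L))
  }
  occurrence_table(df)
}

#' Validate and deduplicate an in-memory occurrence table
#'
#' @param df data frame with columns `species`, `lon`, `lat` (extras kept).
#' @return The cleaned table; see [read_occurrences()] for the rules.
#' @export
occurrence_table <- function(df) {
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  bad_parse <- is.na(df$lon) | is.na(df$lat)
  # normalize longitude to [-180, 180] (antimeridian wrap not handled)
  df$lon <- ifelse(bad_parse, df$lon, ((df$lon + 180) %% 360) - 180)
  bad_bounds <- !bad_parse & (df$lat < -90 | df$lat > 90)
  rejected <- bad_parse | bad_bounds
  if (any(rejected)) {
    pn_log("occurrences: rejected %d row(s) (%d unparseable, %d out of bounds)",
           sum(rejected), sum(bad_parse), sum(bad_bounds))
  }
  df <- df[!rejected, , drop = FALSE]
  dup <- duplicated(df[, c("species", "lon", "lat")])
  if (any(dup)) pn_log("occurrences: removed %d duplicate row(s)", sum(dup))
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_duplicates") <- sum(dup)
  attr(df, "n_rejected") <- sum(rejected)
  df
}

#' Read a species-group mapping
#'
#' CSV with columns `species`, `group`. A row whose `group` is empty or `NA`
#' places the species on the drop list (removed entirely from analyses,
#' mirroring the treatment of taxa whose records cannot be attributed to a
#' single lineage).
#'
#' @param path CSV file path.
#' @return A list with `mapping` (named character: species -> group) and
#'   `drop` (character vector of species to remove).
#' @export
read_species_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "group"), names(df))
  if (length(miss)) stop("species-group CSV missing column(s): ", paste(miss, collapse = ", "))
  dropped <- is.na(df$group) | !nzchar(trimws(df$group))
  mapping <- stats::setNames(df$group[!dropped], df$species[!dropped])
  if (anyDuplicated(names(mapping))) stop("species mapped to more than one group")
  list(mapping = mapping, drop = unique(df$species[dropped]))
}

#' Relabel occurrences by species group
#'
#' Replaces species identifiers by their group identifier where mapped
#' (unmapped identifiers pass through unchanged), removes drop-listed
#' species, and re-deduplicates (two grouped species may share a record).
#' Idempotent.
#'
#' @param occ occurrence table.
#' @param groups list as returned by [read_species_groups()]; `NULL` or an
#'   empty mapping is the identity.
#' @return Relabeled occurrence table.
#' @export
apply_species_groups <- function(occ, groups = NULL) {
  if (is.null(groups) || (length(groups$mapping) == 0L && length(groups$drop %||% character()) == 0L)) {
    return(occ)
  }
  drop <- groups$drop %||% character()
  if (length(drop)) {
    n0 <- nrow(occ)
    occ <- occ[!(occ$species %in% drop), , drop = FALSE]
    if (nrow(occ) < n0) pn_log("groups: dropped %d row(s) for %d drop-listed species",
                               n0 - nrow(occ), length(drop))
  }
  mapped <- occ$species %in% names(groups$mapping)
  occ$species[mapped] <- unname(groups$mapping[occ$species[mapped]])
  occurrence_table(occ)
}

#' Read an insect-to-host association table
#'
#' CSV with columns `insect`, `host`; one row per association.
#'
#' @param path CSV file path.
#' @return Named list: insect entity -> character vector of host species.
#' @export
read_host_associations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("insect", "host"), names(df))
  if (length(miss)) stop("association CSV missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty association table")
  assoc <- split(df$host, df$insect)
  lapply(assoc, unique)
}

#' Apply the minimum-occurrence filter to table and tree together
#'
#' Species represented by fewer than `min_n` records are removed from the
#' occurrence table and pruned from the tree (dropping a tip suppresses the
#' resulting degree-2 node and sums its branch lengths, so remaining
#' root-to-tip depths are unchanged). The default threshold of 5 records is
#' the conventional floor below which a climatic niche summary is not
#' considered meaningful.
#'
#' @param occ occurrence table.
#' @param tree dated tree ([ape::phylo]).
#' @param min_n minimum record count per species (>= 1).
#' @return list with elements `occ` and `tree`.
#' @export
filter_min_occurrences <- function(occ, tree, min_n = 5) {
  stopifnot(min_n >= 1)
  counts <- table(occ$species)
  keep_sp <- names(counts)[counts >= min_n]
  occ2 <- occ[occ$species %in% keep_sp, , drop = FALSE]
  rownames(occ2) <- NULL
  keep_tips <- intersect(tree$tip.label, keep_sp)
  if (length(keep_tips) < 3L) {
    stop(sprintf("pruning would leave %d tip(s); need at least 3", length(keep_tips)))
  }
  tree2 <- prune_tree(tree, keep_tips)
  pn_log("filter: %d -> %d records, %d -> %d tips (min_n = %d)",
         nrow(occ), nrow(occ2), length(tree$tip.label), length(tree2$tip.label), min_n)
  list(occ = occ2, tree = tree2)
}
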