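#' Per-species climatic niche summaries
#'
#' Collapses the per-record climate extraction to a per-species summary:
#' median, minimum and maximum of each bioclimatic variable, plus the count
#' of records with valid climate values. The median uses the midpoint of
#' the two central order statistics for even sample sizes.
#'
#' @param values per-record value table from [extract_at_points()]
#'   (`species` column plus one numeric column per variable).
#' @return Long data frame: `species`, `variable`, `median`, `min`, `max`,
#'   `n_used`.
#' @export
summarize_species <- function(values) {
  vars <- setdiff(names(values), c("species", "lon", "lat"))
  if (length(vars) == 0L) stop("no variable columns in value table")
  sp <- unique(values$species)
  out <- do.call(rbind, lapply(sp, function(s) {
    sub <- values[values$species == s, vars, drop = FALSE]
    data.frame(
      species = s,
      variable = vars,
      median = vapply(sub, stats::median, numeric(1)),
      min = vapply(sub, min, numeric(1)),
      max = vapply(sub, max, numeric(1)),
      n_used = nrow(sub),
      row.names = NULL
    )
  }))
  out
}

#' Build a species-by-variable trait matrix
#'
#' @param summary long summary from [summarize_species()].
#' @param stat which summary statistic becomes the trait:
#'   `"median"` (default), `"min"` or `"max"`.
#' @return Numeric matrix, rows = species, columns = variables, with a
#'   logical attribute `"standardized"` (FALSE).
#' @export
trait_matrix <- function(summary, stat = c("median", "min", "max")) {
  stat <- match.arg(stat)
  sp <- unique(summary$species)
  vars <- unique(summary$variable)
  tm <- matrix(NA_real_, length(sp), length(vars), dimnames = list(sp, vars))
  tm[cbind(match(summary$species, sp), match(summary$variable, vars))] <- summary[[stat]]
  attr(tm, "standardized") <- FALSE
  tm
}

#' Column-standardize a trait matrix
#'
#' Converts each variable to z-scores (sample standard deviation, n - 1
#' denominator) so every variable carries the same weight in multivariate
#' disparity. Idempotent up to floating point.
#'
#' @param tm trait matrix (species x variables).
#' @return Matrix with columns of mean 0 and sd 1, attribute
#'   `"standardized"` set to `TRUE`.
#' @export
standardize_traits <- function(tm) {
  sds <- apply(tm, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(colnames(tm)[sds == 0], collapse = ", "))
  }
  out <- scale(tm, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}
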