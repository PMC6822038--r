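#' Read a time-calibrated tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants a
#' dated tree must satisfy before any comparative analysis: unique tip
#' labels, non-negative branch lengths, and ultrametricity (all root-to-tip
#' path lengths equal within a relative tolerance of 1e-6). A
#' non-ultrametric tree is accepted with a warning and flagged through the
#' `"ultrametric"` attribute, since real dated trees often carry rounding
#' noise. Node support annotations are ignored.
#'
#' @param path path to a Newick file with branch lengths.
#' @param tol relative tolerance on the spread of root-to-tip depths.
#' @return An [ape::phylo] object with a logical attribute `"ultrametric"`.
#' @export
read_time_tree <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("malformed Newick in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) {
    # ape::read.tree returns NULL (with a warning) on some malformed input;
    # locate the first structural problem for the error message.
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    bad <- regexpr("[^(),:;[:alnum:]_. '\\-\\[\\]#&=]", txt)
    stop(sprintf("malformed Newick in %s (near character offset %d)",
                 path, if (bad > 0) bad else nchar(txt)))
  }
  validate_time_tree(tree, tol = tol, where = path)
}

# Shared validation for trees read from disk or built in memory.
validate_time_tree <- function(tree, tol = 1e-6, where = "tree") {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in ", where, ": ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop(where, " has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in ", where)
  d <- tip_depths(tree)
  spread <- (max(d) - min(d)) / max(max(d), .Machine$double.eps)
  ultra <- spread <= tol
  if (!ultra) {
    warning(sprintf("%s is not ultrametric (relative depth spread %.3g); flagged",
                    where, spread))
    pn_log("tree: non-ultrametric input accepted (relative spread %.3g)", spread)
  }
  attr(tree, "ultrametric") <- ultra
  tree
}

# Root-to-tip path lengths, named by tip label.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Prune a dated tree to a tip subset, preserving shared history
#'
#' Drops the other tips, suppresses the resulting degree-2 nodes (their
#' branch lengths are summed), and records the path length between the
#' original root and the retained tips' common ancestor as the pruned
#' tree's root edge. Keeping that stem means the phylogenetic covariance
#' of the pruned tree equals the corresponding submatrix of the full
#' tree's covariance.
#'
#' @param tree [ape::phylo].
#' @param keep tip labels to retain (>= 2).
#' @return Pruned tree; `$root.edge` carries the shared stem length.
#' @export
prune_tree <- function(tree, keep) {
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  ultra <- attr(tree, "ultrametric")
  if (length(keep) == length(tree$tip.label)) return(tree)
  stem0 <- tree$root.edge %||% 0
  mrca_depth <- if (length(keep) == 1L) 0 else {
    m <- ape::getMRCA(tree, keep)
    ape::node.depth.edgelength(tree)[m]
  }
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- stem0 + mrca_depth
  attr(out, "ultrametric") <- ultra
  out
}
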