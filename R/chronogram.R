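#' Read and validate a time-calibrated phylogeny
#'
#' Reads a rooted ultrametric chronogram from a Newick file (a NEXUS trees
#' block is accepted read-only) and validates it: branch lengths present and
#' non-negative, tip labels unique and non-empty, tree rooted, and all
#' root-to-tip path lengths equal within a relative tolerance.  Branch
#' lengths are interpreted as absolute time in millions of years (Ma); no
#' unit inference is attempted.  Integer internal node labels, when present,
#' are preserved so that reconstructions can be reported against a published
#' node numbering.
#'
#' @param path Path to a Newick (or NEXUS) tree file.
#' @param tol Relative ultrametricity tolerance: the maximum allowed
#'   deviation of any root-to-tip path from the tree height, as a fraction
#'   of the height.  Default `1e-6`.
#' @return An object of class `phylo` (see \pkg{ape}) that has passed
#'   chronogram validation.  Polytomies are accepted at this stage; the
#'   likelihood engine requires a fully bifurcating tree and says so.
#' @seealso [validate_chronogram()], [node_age()], [extract_subtree()]
#' @export
read_chronogram <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  tree <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
    ape::read.nexus(path)
  } else {
    tryCatch(ape::read.tree(path),
             error = function(e) stop("Newick parse failure in '", path,
                                      "': ", conditionMessage(e)))
  }
  if (is.null(tree)) stop("Newick parse failure in '", path, "'")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_chronogram(tree, tol = tol)
  tree
}

#' Validate a chronogram
#'
#' Checks the invariants a chronogram must satisfy before biogeographic
#' inference: rooted, branch lengths present and non-negative, unique
#' non-empty tip labels, and ultrametricity within a relative tolerance.
#'
#' @param tree A `phylo` object.
#' @inheritParams read_chronogram
#' @return The tree, invisibly.  Errors name the offending tip where
#'   ultrametricity fails.
#' @export
validate_chronogram <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  nt <- ape::Ntip(tree)
  if (nt < 2L) stop("tree must have at least 2 tips")
  if (any(!nzchar(tree$tip.label))) stop("tree has empty tip labels")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(tree)
  h <- stats::median(depth[seq_len(nt)])  # robust reference height
  if (h <= 0) stop("tree height is zero")
  off <- abs(depth[seq_len(nt)] - h)
  bad <- which(off > tol * h)
  if (length(bad)) {
    worst <- bad[which.max(off[bad])]
    stop("tree is not ultrametric within tolerance: tip '",
         tree$tip.label[worst], "' has root-to-tip length ",
         format(depth[worst], digits = 10), " but tree height is ",
         format(h, digits = 10))
  }
  invisible(tree)
}

#' Tree height (root age) in Ma
#'
#' @param tree A chronogram (`phylo`).
#' @return The maximum root-to-tip path length.
#' @export
tree_height <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))])
}

# Resolve a node given as an ape index, a tip label, or an internal node
# label (e.g. a published node number stored in tree$node.label).
resolve_node <- function(tree, node) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (length(node) != 1L || is.na(node) || node < 1L || node > nt + nn)
      stop("unknown node id: ", node)
    return(node)
  }
  if (is.character(node) && length(node) == 1L) {
    i <- match(node, tree$tip.label)
    if (!is.na(i)) return(i)
    if (!is.null(tree$node.label)) {
      i <- match(node, tree$node.label)
      if (!is.na(i)) return(nt + i)
    }
    stop("unknown node label: '", node, "'")
  }
  stop("'node' must be a single node index or label")
}

#' Age of a node in Ma
#'
#' The age of a node is the tree height minus its root-to-node path length,
#' so extant tips have age 0 and the root has age equal to the tree height.
#'
#' @param tree A chronogram.
#' @param node A node: an ape node index, a tip label, or an internal node
#'   label (published node numbers are matched against `tree$node.label`).
#' @param tol Relative tolerance below which an age is snapped to 0.
#' @return Age in Ma.
#' @export
node_age <- function(tree, node, tol = 1e-6) {
  i <- resolve_node(tree, node)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ape::Ntip(tree))])
  a <- h - depth[i]
  if (abs(a) < tol * h) a <- 0
  a
}

#' Tabulate node ages
#'
#' @param tree A chronogram.
#' @return A data frame with columns `node` (ape index), `label` (tip or
#'   internal node label, `NA` when absent) and `age` (Ma), one row per
#'   node.  Suitable for writing as a CSV node-age report.
#' @export
node_age_table <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(nt)])
  lab <- c(tree$tip.label,
           if (is.null(tree$node.label)) rep(NA_character_, nn)
           else ifelse(nzchar(tree$node.label), tree$node.label,
                       NA_character_))
  age <- h - depth
  age[abs(age) < 1e-6 * h] <- 0
  data.frame(node = seq_len(nt + nn), label = lab, age = age,
             stringsAsFactors = FALSE)
}

#' Extract the induced subtree for a set of tips
#'
#' Returns the subtree induced by a tip subset, rooted at their most recent
#' common ancestor, with degree-2 nodes suppressed and branch lengths
#' summed.  The result of extracting from an ultrametric tree is itself
#' ultrametric, and retained nodes keep their original ages.
#'
#' @param tree A chronogram.
#' @param tips Character vector of tip labels to keep (at least 2).
#' @return A `phylo` chronogram.
#' @export
extract_subtree <- function(tree, tips) {
  if (length(tips) < 2L) stop("need at least 2 tips to extract a subtree")
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("unknown tip label(s): ", paste(missing, collapse = ", "))
  sub <- ape::keep.tip(tree, tips)
  validate_chronogram(sub)
  sub
}
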