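#' Cophenetic (patristic) distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' distance basis for MPD and MNTD.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return A symmetric numeric matrix over tip labels with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  check_tree(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, i]` is the root-to-tip distance of tip i and `C[i, j]` the shared
#' path length (root to MRCA) of tips i and j: the covariance structure of a
#' unit-rate Brownian trait on the tree.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return A symmetric positive semi-definite matrix over tip labels.
#' @export
vcv_matrix <- function(tree) {
  check_tree(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node the standardized
#' difference of daughter values, with branch-length augmentation as values
#' are averaged up the tree. Under Brownian motion the n-1 contrasts are iid
#' normal with variance equal to the rate, which is what the permutation
#' test of phylogenetic signal exploits. Zero-length branches are augmented
#' by `1e-8 *` tree depth; polytomies are resolved to bifurcations with
#' zero-length internal branches first.
#'
#' @param tree A rooted `phylo` object.
#' @param trait Named numeric vector, or a tibble with columns `otu_id` and
#'   `value`, covering every tip.
#' @return Numeric vector of the n-1 standardized contrasts.
#' @export
independent_contrasts <- function(tree, trait) {
  check_tree(tree)
  x <- as_trait_vector(trait, tree$tip.label)
  tree <- regularize_tree(tree)
  as.vector(ape::pic(x[tree$tip.label], tree))
}

# Resolve polytomies and lift zero-length branches so pruning is defined.
regularize_tree <- function(tree) {
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-8 * max(depth, 1)
  if (any(tree$edge.length <= 0)) {
    tree$edge.length[tree$edge.length <= 0] <- eps
  }
  tree
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label) > 0) {
    stop("duplicate tip labels", call. = FALSE)
  }
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree must have finite branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  invisible(tree)
}

# Accepts a named vector or a (otu_id, value[, se]) tibble; returns a named
# vector aligned to `tips`, erroring on gaps.
as_trait_vector <- function(trait, tips, column = "value") {
  if (is.data.frame(trait)) {
    v <- trait[[column]]
    names(v) <- trait$otu_id
    trait <- v
  }
  if (is.null(names(trait))) {
    stop("trait must be named by otu_id", call. = FALSE)
  }
  missing <- setdiff(tips, names(trait))
  if (length(missing) > 0) {
    stop("trait missing for tip(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  trait[tips]
}
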