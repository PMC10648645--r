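#' Simulate a carrier genealogy with known TMRCA
#'
#' Generates the true genealogy of a set of variant carriers descending from
#' a single founder: a rooted ultrametric tree with branch lengths in
#' generations, where the root is the most recent common ancestor (MRCA) of
#' all sampled carrier chromosomes. Under the founder-mutation model every
#' present-day carrier chromosome sits at depth `tmrca` below the root.
#'
#' @param n_carriers Number of sampled carriers (leaves), `>= 2`.
#' @param tmrca Time to the MRCA in generations, `> 0`.
#' @param shape `"star"` (all lineages split at the root, the usual
#'   worst-case/independence model), `"coalescent"` (a random coalescent
#'   topology rescaled so the root sits exactly at `tmrca`), or `"tree"`
#'   (an explicit tree supplied via `tree`).
#' @param tree For `shape = "tree"`: an [ape::read.tree()] `phylo` object or
#'   a Newick string with branch lengths in generations; must be ultrametric
#'   and have `n_carriers` leaves.
#' @param ids Leaf labels; default `C01..Cnn`.
#' @param seed Optional integer seed (used for the coalescent shape).
#' @return An object of class `genealogy`: list with elements `tree`
#'   (`phylo`), `tmrca_generations`, `n`, `ids`.
#' @examples
#' g <- simulate_genealogy(4, tmrca = 100, shape = "star")
#' pairwise_generations(g)[1, 2]  # 100
#' @export
simulate_genealogy <- function(n_carriers, tmrca,
                               shape = c("star", "coalescent", "tree"),
                               tree = NULL, ids = NULL, seed = NULL) {
  shape <- match.arg(shape)
  if (shape != "tree") {
    if (n_carriers < 2) stop("need at least 2 carriers", call. = FALSE)
    # tmrca = 0 (all leaves identical to the founder) is a valid degenerate
    # case for exercising downstream stages
    if (tmrca < 0) stop("tmrca must be >= 0", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("C%02d", seq_len(n_carriers))
  if (!is.null(seed)) set.seed(seed)
  if (shape == "star") {
    phy <- ape::stree(n_carriers, type = "star", tip.label = ids)
    phy$edge.length <- rep(tmrca, nrow(phy$edge))
  } else if (shape == "coalescent") {
    phy <- ape::rcoal(n_carriers, tip.label = ids)
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length / depth * tmrca
  } else {
    if (is.null(tree)) stop("shape = 'tree' requires `tree`", call. = FALSE)
    phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
    if (is.null(phy) || is.null(phy$edge.length))
      stop("explicit tree must carry branch lengths", call. = FALSE)
    if (length(phy$tip.label) != n_carriers)
      stop("explicit tree leaf count != n_carriers", call. = FALSE)
    depths <- ape::node.depth.edgelength(phy)[seq_len(n_carriers)]
    if (diff(range(depths)) > 1e-6 * max(depths))
      stop("explicit tree must be ultrametric (all leaves equally deep)",
           call. = FALSE)
    tmrca <- max(depths)
    ids <- phy$tip.label
  }
  structure(list(tree = phy, tmrca_generations = tmrca,
                 n = n_carriers, ids = ids),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Carrier genealogy: %d leaves, TMRCA %.4g generations\n",
              x$n, x$tmrca_generations))
  invisible(x)
}

#' Pairwise generations to each pair's MRCA
#'
#' Half the patristic (path) distance between two leaves of an ultrametric
#' genealogy is the number of generations back to that pair's common
#' ancestor; the matrix maximum equals the overall TMRCA.
#'
#' @param genealogy A [simulate_genealogy()] object.
#' @return Symmetric numeric matrix (generations), zero diagonal.
#' @export
pairwise_generations <- function(genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  d <- ape::cophenetic.phylo(genealogy$tree) / 2
  d[genealogy$ids, genealogy$ids, drop = FALSE]
}
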