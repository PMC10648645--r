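#' UPGMA clustering of a pairwise distance matrix
#'
#' Classical (size-weighted, arithmetic-mean) UPGMA. The input is the
#' meioses/path matrix between carriers (twice the generations to each
#' pair's MRCA), so merge heights — half the cluster distance at each merge
#' — read directly in generations and the root height estimates the TMRCA
#' of the whole sample. Among equal-minimum pairs the lexicographically
#' smallest pair of cluster labels (each cluster labelled by its smallest
#' member id) is merged first, a deterministic tie-break.
#'
#' @param d Symmetric numeric matrix, zero diagonal, non-negative
#'   off-diagonal (path distances, i.e. meioses).
#' @param ids Leaf labels (default `rownames(d)`).
#' @return An object of class `upgma_tree`: list with `merge`, `height`
#'   (node heights in generations, hclust-style ordering), `labels`,
#'   `order`, `root_height`, `secondary_height` (height of the root's
#'   deeper child cluster), `n`.
#' @examples
#' d <- matrix(c(0, 10, 300, 10, 0, 300, 300, 300, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(d)
#' tmrca(tr)  # 150
#' @export
upgma <- function(d, ids = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("L%02d", seq_len(n))
  if (any(abs(d - t(d)) > 1e-8)) stop("asymmetric distances", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal", call. = FALSE)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)

  D <- d
  size <- rep(1L, n)
  node <- -seq_len(n)            # hclust convention: negative = leaf
  label <- ids                   # smallest member id per active cluster
  height_node <- rep(0, n)       # per active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    act <- which(active)
    dm <- Inf; best <- NULL
    for (ii in seq_along(act)[-length(act)]) for (jj in (ii + 1L):length(act)) {
      p <- act[ii]; q <- act[jj]
      dpq <- D[p, q]
      if (dpq < dm - 1e-12) {
        dm <- dpq; best <- c(p, q)
      } else if (abs(dpq - dm) <= 1e-12) {
        lab_new <- sort(c(label[p], label[q]))
        lab_old <- sort(c(label[best[1]], label[best[2]]))
        if (lab_new[1] < lab_old[1] ||
            (lab_new[1] == lab_old[1] && lab_new[2] < lab_old[2])) {
          dm <- dpq; best <- c(p, q)
        }
      }
    }
    p <- best[1]; q <- best[2]
    merge[s, ] <- sort(c(node[p], node[q]))
    height[s] <- dm / 2
    # arithmetic-mean (size-weighted) update into slot p
    for (r in act) if (r != p && r != q)
      D[p, r] <- D[r, p] <-
        (size[p] * D[p, r] + size[q] * D[q, r]) / (size[p] + size[q])
    size[p] <- size[p] + size[q]
    node[p] <- s
    label[p] <- min(label[p], label[q])
    height_node[p] <- height[s]
    active[q] <- FALSE
  }
  secondary <- if (n == 2L) 0 else {
    kids <- merge[n - 1L, ]
    max(vapply(kids, function(k) if (k < 0) 0 else height[k], numeric(1)))
  }
  structure(list(merge = merge, height = height, labels = ids,
                 order = merge_order(merge, n),
                 root_height = height[n - 1L],
                 secondary_height = secondary, n = n),
            class = "upgma_tree")
}

# leaf ordering for plotting (left-to-right traversal of the merge tree)
merge_order <- function(merge, n) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(n - 1L)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf(
    "UPGMA genealogy: %d carriers, root (TMRCA) %.1f generations, deeper root child at %.1f\n",
    x$n, x$root_height, x$secondary_height))
  invisible(x)
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "upgma (heights in generations)",
                 call = match.call(), dist.method = "meioses"),
            class = "hclust")
}

#' @export
plot.upgma_tree <- function(x, ylab = "generations", ...) {
  plot(stats::as.hclust(x), ylab = ylab, ...)
  invisible(x)
}

#' Time to the most recent common ancestor of the clustered carriers
#'
#' The UPGMA root height in generations. The attribute `secondary_height`
#' carries the height of the root's deeper child subtree — the common
#' ancestor of all carriers but the most divergent cluster, often the
#' better-supported, more recent ancestor of the bulk of the sample.
#'
#' @param tree An [upgma()] tree.
#' @return Root height (generations), with attribute `secondary_height`.
#' @export
tmrca <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  structure(tree$root_height, secondary_height = tree$secondary_height)
}

#' Cophenetic matrix of an UPGMA tree, in generations
#'
#' Entry (i, j) is the height of the smallest cluster containing both
#' leaves, i.e. the estimated generations to that pair's MRCA on the tree.
#'
#' @param tree An [upgma()] tree.
#' @return Symmetric numeric matrix.
#' @export
cophenetic_generations <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- tree$n
  members <- vector("list", n - 1L)
  C <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (k in seq_len(n - 1L)) {
    grab <- function(x) if (x < 0) -x else members[[x]]
    a <- grab(tree$merge[k, 1]); b <- grab(tree$merge[k, 2])
    C[a, b] <- tree$height[k]
    C[b, a] <- tree$height[k]
    members[[k]] <- c(a, b)
  }
  C
}

#' Convert generations to calendar years
#'
#' @param g Generations, `> 0`.
#' @param years_per_generation A value or range in `[10, 40]` (default the
#'   conventional 20-25 years).
#' @return `g * years_per_generation` (a value or range).
#' @examples
#' generations_to_years(155)        # 3100 3875
#' generations_to_years(97, 25)     # 2425
#' @export
generations_to_years <- function(g, years_per_generation = c(20, 25)) {
  if (any(g <= 0)) stop("g must be > 0", call. = FALSE)
  if (any(years_per_generation < 10 | years_per_generation > 40))
    stop("years_per_generation outside plausible range [10, 40]",
         call. = FALSE)
  g * years_per_generation
}

#' Newick serialization of an UPGMA tree
#'
#' Branch lengths are in generations; leaf depth equals the root height.
#'
#' @param tree An [upgma()] tree.
#' @param file Optional path; when given the text is also written there.
#' @return Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  phy <- as_phylo_upgma(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# phylo with edge lengths equal to node-height differences (generations)
as_phylo_upgma <- function(tree) {
  n <- tree$n
  nnode <- n - 1L
  # internal node numbering: phylo root = n+1; our merge k -> phylo node
  # (n + (nnode - k + 1)) so the last merge (root) gets n+1
  node_id <- function(k) if (k < 0) -k else n + (nnode - k + 1L)
  hts <- function(k) if (k < 0) 0 else tree$height[k]
  edge <- matrix(0L, 2L * nnode, 2L)
  elen <- numeric(2L * nnode)
  r <- 0L
  for (k in seq_len(nnode)) {
    for (child in tree$merge[k, ]) {
      r <- r + 1L
      edge[r, ] <- c(node_id(k), node_id(child))
      elen[r] <- tree$height[k] - hts(child)
    }
  }
  structure(list(edge = edge, edge.length = elen, tip.label = tree$labels,
                 Nnode = nnode), class = "phylo", order = "cladewise")
}
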