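# Genealogy container: a rooted, binary, ultrametric gene tree with
# absolute node ages in 4N0 generations.
#
# Nodes are indexed 1..(2n-1): tips are 1..n in label order, internal
# nodes n+1..(2n-1) in strictly non-decreasing age order, so every child
# has a smaller index than its parent and the root is node 2n-1. This
# makes clade (descendant) computations a single forward pass.

new_genealogy <- function(ages, children, parent, tip_label,
                          tip_population, t_join = NA_real_) {
  n <- length(tip_label)
  structure(
    list(n_tips = n, ages = ages, children = children, parent = parent,
         tip_label = tip_label, tip_population = tip_population,
         root = 2L * n - 1L, t_join = t_join),
    class = "genealogy")
}

is_genealogy <- function(x) inherits(x, "genealogy")

as_genealogy_checked <- function(x) {
  if (!is_genealogy(x)) stop("expected a 'genealogy' object")
  x
}

validate_genealogy <- function(tree) {
  n <- tree$n_tips
  m <- 2L * n - 1L
  stopifnot(length(tree$ages) == m, nrow(tree$children) == m,
            length(tree$parent) == m, anyDuplicated(tree$tip_label) == 0L)
  if (any(tree$ages[seq_len(n)] != 0))
    stop("invalid genealogy: leaf ages must be 0")
  if (n >= 2L) {
    for (v in (n + 1L):m) {
      ch <- tree$children[v, ]
      if (anyNA(ch) || any(ch >= v))
        stop("invalid genealogy: children must precede parents")
      if (any(tree$ages[ch] >= tree$ages[v]))
        stop("invalid genealogy: internal nodes must be strictly older than their children")
    }
  }
  invisible(tree)
}

# Logical (2n-1) x n matrix; row v marks the tips descending from node v.
clade_matrix <- function(tree) {
  n <- tree$n_tips
  m <- 2L * n - 1L
  M <- matrix(FALSE, m, n)
  M[cbind(seq_len(n), seq_len(n))] <- TRUE
  if (n >= 2L) {
    for (v in (n + 1L):m) {
      ch <- tree$children[v, ]
      M[v, ] <- M[ch[1L], ] | M[ch[2L], ]
    }
  }
  M
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Coalescent genealogy with ", x$n_tips, " tips",
      if (!is.na(x$t_join)) paste0(" (t_join = ", x$t_join, " x 4N0)"),
      "\n  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' @param x A `genealogy` object.
#' @param ... Unused.
#' @return An object of class `phylo` with branch lengths in 4N0
#'   generations.
#' @importFrom ape as.phylo
#' @method as.phylo genealogy
#' @export
as.phylo.genealogy <- function(x, ...) {
  n <- x$n_tips
  m <- 2L * n - 1L
  # phylo numbering: tips 1..n, root n+1, other internals n+2..2n-1
  map <- integer(m)
  map[seq_len(n)] <- seq_len(n)
  map[x$root] <- n + 1L
  others <- setdiff((n + 1L):m, x$root)
  if (length(others)) map[others] <- n + 1L + seq_along(others)
  nonroot <- setdiff(seq_len(m), x$root)
  edge <- cbind(map[x$parent[nonroot]], map[nonroot])
  edge.length <- x$ages[x$parent[nonroot]] - x$ages[nonroot]
  phy <- structure(list(edge = edge, edge.length = edge.length,
                        tip.label = x$tip_label, Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# Rebuild the internal representation from an ape phylo object. Requires
# a rooted binary tree with branch lengths; node ages are recovered from
# root-to-tip path lengths and the tree must be ultrametric within `tol`.
phylo_to_genealogy <- function(phy, tol = 1e-6, t_join = NA_real_) {
  n <- length(phy$tip.label)
  if (n < 2L) stop("genealogy must have at least 2 tips")
  if (is.null(phy$edge.length)) stop("branch lengths are required")
  if (phy$Nnode != n - 1L)
    stop("tree must be rooted and strictly binary (expected ", n - 1L,
         " internal nodes, found ", phy$Nnode, ")")
  depths <- ape::node.depth.edgelength(phy)
  height <- max(depths[seq_len(n)])
  ages <- height - depths
  if (max(abs(ages[seq_len(n)])) > tol * max(1, height))
    stop("tree is not ultrametric within tolerance ", tol,
         "; leaf age spread = ", signif(max(abs(ages[seq_len(n)])), 3))
  ages[seq_len(n)] <- 0
  internal_phy <- (n + 1L):(2L * n - 1L)
  ord <- internal_phy[order(ages[internal_phy])]  # ascending age
  map <- integer(2L * n - 1L)
  map[seq_len(n)] <- seq_len(n)
  map[ord] <- n + seq_along(ord)
  ages2 <- numeric(2L * n - 1L)
  ages2[map] <- ages
  children <- matrix(NA_integer_, 2L * n - 1L, 2L)
  parent <- integer(2L * n - 1L)
  for (e in seq_len(nrow(phy$edge))) {
    p <- map[phy$edge[e, 1L]]
    c0 <- map[phy$edge[e, 2L]]
    parent[c0] <- p
    slot <- if (is.na(children[p, 1L])) 1L else 2L
    children[p, slot] <- c0
  }
  tree <- new_genealogy(ages2, children, parent, phy$tip.label,
                        tip_population = infer_populations(phy$tip.label),
                        t_join = t_join)
  validate_genealogy(tree)
  tree
}

# X* tips are population 2 (ingroup), Y* tips population 1 (outgroup);
# anything else is left unassigned.
infer_populations <- function(labels) {
  pop <- rep(NA_integer_, length(labels))
  pop[startsWith(labels, "X")] <- 2L
  pop[startsWith(labels, "Y")] <- 1L
  pop
}
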