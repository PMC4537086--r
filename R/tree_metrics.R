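#' Time to most recent common ancestor of a set of leaves
#'
#' Age of the lowest node whose descendant leaf set contains every queried
#' label. A singleton query returns 0 (a leaf is its own ancestor);
#' querying all leaves returns the root height.
#'
#' @param tree A `genealogy` object.
#' @param query Character vector of leaf labels (non-empty, all present in
#'   the tree).
#' @return TMRCA in 4N0 generations.
#' @seealso [root_height()], [basal_node_age()], [classify_sorting()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tmrca(tr, c("A", "B"))  # 1
#' tmrca(tr, c("A", "C"))  # 2
tmrca <- function(tree, query) {
  tree <- as_genealogy_checked(tree)
  if (length(query) < 1L) stop("query must contain at least one leaf label")
  idx <- match(query, tree$tip_label)
  if (anyNA(idx))
    stop("unknown taxon label(s): ",
         paste(query[is.na(idx)], collapse = ", "))
  idx <- unique(idx)
  if (length(idx) == 1L) return(0)
  tree$ages[mrca_node(tree, idx)]
}

# Internal: index of the MRCA node of tip indices `idx`.
mrca_node <- function(tree, idx, M = clade_matrix(tree)) {
  covers <- which(rowSums(M[, idx, drop = FALSE]) == length(idx))
  covers[which.min(tree$ages[covers])]
}

#' Root height (global TMRCA) of a genealogy
#'
#' @param tree A `genealogy` object.
#' @return Age of the root in 4N0 generations; equals
#'   `tmrca(tree, all leaves)` and bounds every subset TMRCA from above.
#' @export
root_height <- function(tree) {
  tree <- as_genealogy_checked(tree)
  tree$ages[tree$root]
}

#' Age of the most basal non-root node
#'
#' The "most basal node" statistic sometimes reported in place of the
#' TMRCA: here formalized as the oldest internal node other than the root
#' (the older child of the root, when that child is internal). On a
#' binary tree this is always strictly younger than the root height, which
#' is why reading a basal-node age as the TMRCA underestimates it.
#'
#' @param tree A `genealogy` object with at least 3 leaves.
#' @return Age in 4N0 generations, strictly less than [root_height()].
#' @export
#' @examples
#' basal_node_age(parse_newick("(((A:1,B:1):1,C:2):1,D:3);"))  # 2
basal_node_age <- function(tree) {
  tree <- as_genealogy_checked(tree)
  n <- tree$n_tips
  if (n < 3L)
    stop("basal node age is undefined for a tree with fewer than 3 leaves")
  max(tree$ages[(n + 1L):(2L * n - 2L)])
}

#' Classify the lineage-sorting status of an ingroup
#'
#' Determines whether the queried ingroup is monophyletic: whether the
#' descendant set of its MRCA is exactly the ingroup. With a single
#' non-ingroup leaf this is equivalent to reciprocal monophyly. A
#' singleton ingroup is vacuously monophyletic.
#'
#' @param tree A `genealogy` object.
#' @param ingroup Character vector of leaf labels; a non-empty proper
#'   subset of the tree's leaves.
#' @return An object of class `sorting_status`: list with `status`
#'   (`"MONOPHYLETIC"` or `"NON_MONOPHYLETIC"`), `n_query`, and
#'   `n_intruders` (non-ingroup leaves under the ingroup's MRCA).
#' @export
#' @examples
#' classify_sorting(parse_newick("((X1:1,Y1:1):1,X2:2);"), c("X1", "X2"))
classify_sorting <- function(tree, ingroup) {
  tree <- as_genealogy_checked(tree)
  if (length(ingroup) < 1L) stop("ingroup must be non-empty")
  idx <- match(ingroup, tree$tip_label)
  if (anyNA(idx))
    stop("unknown taxon label(s): ",
         paste(ingroup[is.na(idx)], collapse = ", "))
  idx <- unique(idx)
  if (length(idx) == tree$n_tips)
    stop("invalid query: ingroup must be a proper subset of the leaves")
  M <- clade_matrix(tree)
  node <- if (length(idx) == 1L) idx else mrca_node(tree, idx, M)
  n_desc <- sum(M[node, ])
  intruders <- n_desc - length(idx)
  structure(
    list(status = if (intruders == 0L) "MONOPHYLETIC" else "NON_MONOPHYLETIC",
         n_query = length(idx), n_intruders = as.integer(intruders)),
    class = "sorting_status")
}

#' @export
print.sorting_status <- function(x, ...) {
  cat(x$status, " (", x$n_query, " query leaves, ", x$n_intruders,
      " intruders)\n", sep = "")
  invisible(x)
}

#' @rdname classify_sorting
#' @export
is_monophyletic <- function(tree, ingroup) {
  classify_sorting(tree, ingroup)$status == "MONOPHYLETIC"
}

#' Write a genealogy as a Newick string
#'
#' @param tree A `genealogy` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (rooted, branch lengths on all non-root
#'   nodes, no internal labels), terminated with ";".
#' @export
write_newick <- function(tree, digits = 10) {
  tree <- as_genealogy_checked(tree)
  ape::write.tree(as.phylo.genealogy(tree), digits = digits)
}

#' Parse a rooted binary ultrametric Newick string
#'
#' Reads a Newick tree (branch lengths required) and recovers absolute
#' node ages from root-to-tip path lengths. Input must be rooted, strictly
#' binary and ultrametric within `tol` (relative to tree height);
#' otherwise an error is raised. Internal labels are ignored.
#'
#' @param text A single Newick string.
#' @param tol Ultrametricity tolerance on leaf depths.
#' @return A `genealogy` object.
#' @export
#' @examples
#' root_height(parse_newick("((A:1,B:1):1,C:2);"))  # 2
parse_newick <- function(text, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character ",
         length(chars))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("Newick parse error: input could not be read as a tree")
  phylo_to_genealogy(phy, tol = tol)
}

#' Tabulate per-tree summary metrics
#'
#' Computes, for each genealogy, the ingroup TMRCA, root height,
#' basal-node age, sorting status and (optionally) segregating-site count.
#'
#' @param trees List of `genealogy` objects (each with >= 3 leaves).
#' @param ingroup Character vector of ingroup leaf labels.
#' @param haplotypes Optional list of `haplotype_matrix` objects matched
#'   to `trees`; adds a `segsites` column.
#' @return A data frame with one row per tree; ages in 4N0 generations.
#' @export
tree_metrics_table <- function(trees, ingroup, haplotypes = NULL) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  if (!is.null(haplotypes)) stopifnot(length(haplotypes) == length(trees))
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    st <- classify_sorting(tr, ingroup)
    data.frame(
      replicate = i,
      tmrca_ingroup_4N0 = tmrca(tr, ingroup),
      root_height_4N0 = root_height(tr),
      basal_node_age_4N0 = basal_node_age(tr),
      monophyletic = st$status == "MONOPHYLETIC",
      n_intruders = st$n_intruders,
      segsites = if (is.null(haplotypes)) NA_integer_ else
        ncol(haplotypes[[i]]$matrix))
  })
  do.call(rbind, rows)
}
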