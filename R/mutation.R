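#' Total branch length of a genealogy
#'
#' Sum over all non-root nodes of (parent age - node age), in 4N0
#' generations. Under the panmictic coalescent of n samples its
#' expectation is the harmonic sum H(n-1) (see
#' [expected_total_length()]).
#'
#' @param tree A `genealogy` object.
#' @return Non-negative total length in 4N0 generations.
#' @export
#' @examples
#' total_branch_length(parse_newick("((A:1,B:1):1,C:2);"))  # 5
total_branch_length <- function(tree) {
  tree <- as_genealogy_checked(tree)
  v <- seq_len(2L * tree$n_tips - 1L)[-tree$root]
  sum(tree$ages[tree$parent[v]] - tree$ages[v])
}

new_haplotype_matrix <- function(labels, positions, matrix, branch_nodes = integer(0)) {
  structure(list(labels = labels, positions = positions, matrix = matrix,
                 branch_nodes = branch_nodes),
            class = "haplotype_matrix")
}

#' Overlay infinite-sites mutations on a genealogy
#'
#' Implements the `-t theta` part of the ms command: the total mutation
#' count is Poisson with mean `theta * total_branch_length(tree)`; each
#' mutation lands on a branch with probability proportional to branch
#' length, receives a fresh uniform(0,1) position mark, and sets the
#' derived allele (1) in exactly the leaves descending from that branch.
#' Every mutation hits a new site (no back-mutation); the ancestral state
#' is 0. Columns are ordered by ascending position.
#'
#' @param tree A `genealogy` object.
#' @param theta Non-negative population-scaled mutation rate per locus.
#' @param seed Integer seed for the mutation substream (kept separate from
#'   the genealogy stream; see [simulate_ms()]).
#' @return An object of class `haplotype_matrix`: `labels` (leaf order),
#'   `positions` (strictly increasing in (0,1)), `matrix` (leaves x sites,
#'   0/1), and `branch_nodes` (the node below each mutated branch, for
#'   auditing the infinite-sites construction). Sites are never invariant.
#' @export
#' @examples
#' tr <- simulate_genealogy(sim_config(c(1, 10), theta = 2, t_join = 10), 0)
#' hap <- drop_mutations(tr, 2, seed = 99)
#' dim(hap$matrix)
drop_mutations <- function(tree, theta, seed = 1L) {
  tree <- as_genealogy_checked(tree)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("invalid parameter: theta must be a non-negative number")
  n <- tree$n_tips
  empty <- function() new_haplotype_matrix(
    tree$tip_label, numeric(0),
    matrix(0L, n, 0L, dimnames = list(tree$tip_label, NULL)))
  if (theta == 0) return(empty())
  with_seed(seed, {
    v <- seq_len(2L * n - 1L)[-tree$root]
    len <- tree$ages[tree$parent[v]] - tree$ages[v]
    S <- stats::rpois(1L, theta * sum(len))
    if (S == 0L) return(empty())
    br <- v[sample.int(length(v), S, replace = TRUE, prob = len)]
    pos <- stats::runif(S)
    o <- order(pos)
    br <- br[o]
    pos <- pos[o]
    M <- clade_matrix(tree)
    mat <- matrix(0L, n, S, dimnames = list(tree$tip_label, NULL))
    for (s in seq_len(S)) mat[M[br[s], ], s] <- 1L
    new_haplotype_matrix(tree$tip_label, pos, mat, br)
  })
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("Infinite-sites haplotype matrix: ", length(x$labels), " samples x ",
      ncol(x$matrix), " segregating sites\n", sep = "")
  invisible(x)
}
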