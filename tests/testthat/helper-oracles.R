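# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately share no code with the package
# internals they check.

# Exact probability that j ingroup lineages plus one outgroup lineage end
# up with the ingroup monophyletic, by exhaustive enumeration of all
# uniformly chosen pair-merge histories. State: a list of lineage
# "contents"; the outgroup is the element containing 0.
enumerate_monophyly <- function(j) {
  recurse <- function(lineages) {
    m <- length(lineages)
    if (m == 1L) {
      return(0)  # never saw a pure-ingroup ancestor of everything
    }
    npairs <- m * (m - 1) / 2
    total <- 0
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        merged <- c(lineages[[a]], lineages[[b]])
        rest <- lineages[-c(a, b)]
        if (!(0L %in% merged) && length(merged) == j) {
          p <- 1  # ingroup just became a single lineage: monophyletic
        } else {
          p <- recurse(c(rest, list(merged)))
        }
        total <- total + p / npairs
      }
    }
    total
  }
  if (j == 1L) return(1)
  recurse(c(list(0L), as.list(seq_len(j))))
}

# Brute-force MRCA age of a label set on an ape phylo tree: enumerate
# every node, collect its descendant tips by walking edges, and take the
# youngest node covering the query.
brute_force_tmrca <- function(phy, labels) {
  n <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  ages <- max(depths[seq_len(n)]) - depths
  want <- match(labels, phy$tip.label)
  desc_tips <- function(node) {
    if (node <= n) return(node)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  if (length(want) == 1L) return(0)
  best <- Inf
  for (node in seq_len(n + phy$Nnode)) {
    if (all(want %in% desc_tips(node))) best <- min(best, ages[node])
  }
  best
}

# Brute-force monophyly of a label set on a phylo tree via descendant
# enumeration (no reliance on the package's clade machinery).
brute_force_monophyletic <- function(phy, labels) {
  n <- length(phy$tip.label)
  want <- sort(match(labels, phy$tip.label))
  desc_tips <- function(node) {
    if (node <= n) return(node)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  for (node in (n + 1L):(n + phy$Nnode)) {
    if (identical(sort(desc_tips(node)), want)) return(TRUE)
  }
  length(want) == 1L
}

# Monte-Carlo standard error helpers.
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
se_binom <- function(p, n) sqrt(p * (1 - p) / n)
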