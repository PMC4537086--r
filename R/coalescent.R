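#' Simulate one genealogy under the two-population isolation model
#'
#' Runs the coalescent backward in time for the sample described by
#' `config`. While a population holds k >= 2 lineages the waiting time to
#' its next coalescence is exponential with rate k(k-1) (time in 4N0
#' generations, so a pair coalesces after mean 0.5 units); the coalescing
#' pair is drawn uniformly from the k(k-1)/2 pairs in label-sorted order.
#' The two populations evolve independently until `t_join`, when all
#' lineages of the source population move into the destination; the
#' simulation ends when a single lineage remains. There is no migration
#' and both populations have the same constant size N0.
#'
#' The result is deterministic given `(config$seed, replicate_index)`:
#' each replicate has its own counter-based substream (see [mix_seed()]).
#'
#' @param config A [sim_config()] object.
#' @param replicate_index Non-negative replicate counter (0-based).
#' @return A `genealogy` object: rooted, binary, ultrametric, with node
#'   ages in 4N0 generations and population-labelled tips (`Y*` =
#'   population 1, `X*` = population 2).
#' @export
#' @examples
#' cfg <- sim_config(pop_sizes = c(1, 10), theta = 2, t_join = 10)
#' tr <- simulate_genealogy(cfg, 0)
#' root_height(tr) > 10
simulate_genealogy <- function(config, replicate_index = 0L) {
  config <- as_sim_config(config)
  replicate_index <- as.integer(replicate_index)
  if (is.na(replicate_index) || replicate_index < 0L)
    stop("replicate_index must be a non-negative integer")
  with_seed(mix_seed(config$seed, replicate_index, 0L), sim_one(config))
}

sim_one <- function(config) {
  pops <- config$pop_sizes
  n <- sum(pops)
  npop <- length(pops)
  m <- 2L * n - 1L
  ages <- numeric(m)
  children <- matrix(NA_integer_, m, 2L)
  parent <- integer(m)
  tip_population <- rep.int(seq_len(npop), pops)
  labels <- tip_labels_for(pops)

  active <- vector("list", npop)
  off <- 0L
  for (p in seq_len(npop)) {
    active[[p]] <- off + seq_len(pops[p])
    off <- off + pops[p]
  }
  t <- 0
  joined <- npop < 2L
  if (!joined && config$t_join == 0) {
    active <- join_pops(active, config)
    joined <- TRUE
  }
  nxt <- n + 1L
  total <- n
  while (total > 1L) {
    k <- lengths(active)
    rate <- k * (k - 1)
    R <- sum(rate)
    if (R == 0) {
      # each population down to <= 1 lineage before the join: jump to it
      t <- config$t_join
      active <- join_pops(active, config)
      joined <- TRUE
      next
    }
    dt <- stats::rexp(1L, R)
    if (!joined && t + dt >= config$t_join) {
      t <- config$t_join
      active <- join_pops(active, config)
      joined <- TRUE
      next
    }
    t <- t + dt
    live <- which(rate > 0)
    p <- if (length(live) == 1L) live else
      live[sample.int(length(live), 1L, prob = rate[live])]
    a <- active[[p]]
    kk <- length(a)
    npairs <- (kk * (kk - 1L)) %/% 2L
    pr <- if (npairs == 1L) 1L else sample.int(npairs, 1L)
    ij <- pair_from_index(kk, pr)
    c1 <- a[ij[1L]]
    c2 <- a[ij[2L]]
    ages[nxt] <- t
    children[nxt, 1L] <- c1
    children[nxt, 2L] <- c2
    parent[c1] <- nxt
    parent[c2] <- nxt
    active[[p]] <- c(a[-ij], nxt)  # nxt exceeds all live indices: stays sorted
    total <- total - 1L
    nxt <- nxt + 1L
  }
  new_genealogy(ages, children, parent, labels, tip_population,
                t_join = if (npop == 2L) config$t_join else NA_real_)
}

join_pops <- function(active, config) {
  s <- config$source_pop
  d <- config$dest_pop
  active[[d]] <- sort(c(active[[d]], active[[s]]))
  active[[s]] <- integer(0)
  active
}

# idx-th pair (i, j), i < j, of k items in lexicographic order.
pair_from_index <- function(k, idx) {
  i <- 1L
  row <- k - 1L
  while (idx > row) {
    idx <- idx - row
    i <- i + 1L
    row <- row - 1L
  }
  c(i, i + idx)
}

#' Simulate a set of replicate genealogies
#'
#' Draws `config$n_reps` independent genealogies. Replicate `i` uses the
#' substream `mix_seed(config$seed, i - 1, 0)`, so rerunning with the same
#' seed reproduces identical trees and replicate `i` does not depend on
#' how many replicates are requested.
#'
#' @param config A [sim_config()] object.
#' @return A list of `genealogy` objects of length `config$n_reps`;
#'   element `i` equals `simulate_genealogy(config, i - 1)`.
#' @export
#' @examples
#' cfg <- sim_config(pop_sizes = c(1, 10), theta = 2, t_join = 10,
#'                   n_reps = 10, seed = 7)
#' trees <- simulate_replicates(cfg)
#' length(trees)
simulate_replicates <- function(config) {
  config <- as_sim_config(config)
  lapply(seq_len(config$n_reps) - 1L,
         function(i) simulate_genealogy(config, i))
}

#' Simulate genealogies together with infinite-sites haplotypes
#'
#' Convenience pipeline: simulates `config$n_reps` genealogies and
#' overlays mutations at rate `config$theta` on each. The mutation stream
#' is separate from the genealogy stream, so the trees are identical to
#' those from [simulate_replicates()] whatever the value of theta.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `trees` (list of `genealogy`) and
#'   `haplotypes` (list of `haplotype_matrix`).
#' @export
simulate_ms <- function(config) {
  config <- as_sim_config(config)
  trees <- simulate_replicates(config)
  haps <- lapply(seq_along(trees), function(i)
    drop_mutations(trees[[i]], config$theta,
                   seed = mix_seed(config$seed, i - 1L, 1L)))
  list(trees = trees, haplotypes = haps)
}
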