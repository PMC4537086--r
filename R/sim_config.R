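#' Simulation configuration for the two-population isolation model
#'
#' Bundles the parameters of the isolation model behind an ms command of
#' the form `ms nsam nreps -t theta -I 2 n1 n2 -ej t_join 1 2 -T`:
#' per-population sample counts, the population-scaled mutation rate
#' theta = 4N0mu per locus, the join (divergence) time, and replication
#' and seeding controls. Times are in units of 4N0 generations, the ms
#' convention, so the deep-divergence command's `-ej 10` is 40 N0
#' generations (see [convert_time()]).
#'
#' @param pop_sizes Integer vector of non-negative sample counts per
#'   population, in ms `-I` order. One or two populations are supported;
#'   total sample size must be at least 2.
#' @param theta Non-negative population-scaled mutation rate per locus
#'   (ms `-t`).
#' @param t_join Non-negative time, in 4N0 generations, at which (looking
#'   backward) the source population's lineages move into the destination
#'   population (ms `-ej`). Ignored when only one population is given.
#' @param source_pop,dest_pop Indices of the populations merged at
#'   `t_join` (ms `-ej t i j` moves population `i` into `j`).
#' @param n_reps Positive number of replicates.
#' @param seed Integer master seed; replicate substreams are derived with
#'   [mix_seed()].
#' @param emit_trees Logical; whether ms-dialect output should include the
#'   Newick tree line (ms `-T`).
#' @return An object of class `sim_config`.
#' @seealso [simulate_genealogy()], [parse_ms_command()]
#' @export
#' @examples
#' sim_config(pop_sizes = c(1, 10), theta = 2, t_join = 10)
sim_config <- function(pop_sizes, theta = 0, t_join = 0,
                       source_pop = 1L, dest_pop = 2L,
                       n_reps = 1L, seed = 1L, emit_trees = FALSE) {
  pop_sizes <- as.integer(pop_sizes)
  if (length(pop_sizes) < 1L || length(pop_sizes) > 2L)
    stop("invalid config: one or two populations are supported, got ",
         length(pop_sizes))
  if (any(pop_sizes < 0L))
    stop("invalid config: population sample counts must be non-negative")
  if (sum(pop_sizes) < 2L)
    stop("invalid config: at least 2 samples are required in total")
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("invalid config: theta must be a non-negative number")
  if (!is.numeric(t_join) || length(t_join) != 1L || is.na(t_join) || t_join < 0)
    stop("invalid config: t_join must be a non-negative number")
  source_pop <- as.integer(source_pop)
  dest_pop <- as.integer(dest_pop)
  if (length(pop_sizes) == 2L) {
    if (is.na(source_pop) || is.na(dest_pop) ||
        source_pop < 1L || source_pop > 2L || dest_pop < 1L || dest_pop > 2L)
      stop("invalid config: join population indices out of range")
    if (source_pop == dest_pop)
      stop("invalid config: source and destination populations must differ")
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    stop("invalid config: n_reps must be a positive integer")
  structure(
    list(pop_sizes = pop_sizes, theta = as.numeric(theta),
         t_join = as.numeric(t_join), source_pop = source_pop,
         dest_pop = dest_pop, n_reps = n_reps, seed = as.integer(seed),
         emit_trees = isTRUE(emit_trees)),
    class = "sim_config")
}

as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  stop("expected a 'sim_config' object; see sim_config() or parse_ms_command()")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-population isolation-model configuration\n")
  cat("  ms equivalent: ", render_ms_command(x), "\n", sep = "")
  cat("  samples:", paste(x$pop_sizes, collapse = " + "),
      " theta:", x$theta, " t_join (4N0):", x$t_join,
      " reps:", x$n_reps, " seed:", x$seed, "\n")
  invisible(x)
}

# Tip labels per ms -I ordering: population 1 first. With two populations
# the single-representative outgroup convention of the study design is
# used: population 1 leaves are "Y1..", population 2 leaves "X1.."; a
# lone panmictic population is labelled "X1..Xn".
tip_labels_for <- function(pop_sizes) {
  if (length(pop_sizes) == 1L) return(paste0("X", seq_len(pop_sizes)))
  c(if (pop_sizes[1L] > 0L) paste0("Y", seq_len(pop_sizes[1L])),
    if (pop_sizes[2L] > 0L) paste0("X", seq_len(pop_sizes[2L])))
}

#' Leaf labels of the ingroup (population 2) for a configuration
#'
#' @param config A [sim_config()] object.
#' @return Character vector of population-2 leaf labels (`"X1"`, ...).
#' @export
ingroup_labels <- function(config) {
  config <- as_sim_config(config)
  if (length(config$pop_sizes) == 1L) return(paste0("X", seq_len(config$pop_sizes)))
  paste0("X", seq_len(config$pop_sizes[2L]))
}
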