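# Scenario experiments: the deep- and recent-divergence contrasts and the
# lineage-sorting sweep.

#' Configuration of a named divergence scenario
#'
#' `"deep"` binds the command `ms 11 1 -t 2.0 -I 2 1 10 -ej 10 1 2 -T`
#' (divergence 40 N0 generations in the past); `"recent"` the `-ej 0.01`
#' variant (0.04 N0 generations). Both sample 10 ingroup lineages (X) and
#' a single outgroup (Y).
#'
#' @param scenario `"deep"` or `"recent"`.
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @return A [sim_config()] object.
#' @export
scenario_config <- function(scenario, n_reps = 5000L, seed = 1L) {
  t_join <- switch(scenario,
                   deep = 10,
                   recent = 0.01,
                   stop("unknown scenario '", scenario,
                        "'; valid names: deep, recent"))
  sim_config(pop_sizes = c(1L, 10L), theta = 2, t_join = t_join,
             n_reps = n_reps, seed = seed, emit_trees = TRUE)
}

#' Run a divergence scenario and summarize TMRCA versus divergence date
#'
#' Simulates `n_reps` genealogies with mutations, records per replicate
#' the ingroup TMRCA, root height (the MRCA of X and Y — the per-replicate
#' divergence-date proxy), basal-node age, sorting status and
#' segregating-site count, and summarizes the TMRCA and root-height
#' distributions (means, quantiles, Freedman-Diaconis histograms). The
#' true divergence parameter `t_join` is carried alongside for reference.
#' Deterministic given the seed.
#'
#' @param scenario `"deep"`, `"recent"`, or `NULL` when `config` is given.
#' @param n_reps Number of replicates (ignored when `config` is given).
#' @param seed Master seed (ignored when `config` is given).
#' @param config Optional custom [sim_config()] with two sampled
#'   populations; overrides the named scenario.
#' @param keep_trees Logical; retain the simulated genealogies in the
#'   result (memory scales with `n_reps`).
#' @return An object of class `scenario_result`: list with `scenario`,
#'   `config`, `replicates` (data frame, one row per replicate),
#'   `summary` (list described above) and, if requested, `trees`.
#' @export
#' @examples
#' res <- run_scenario("deep", n_reps = 50, seed = 1)
#' res$summary$monophyly_fraction
run_scenario <- function(scenario = c("deep", "recent"), n_reps = 5000L,
                         seed = 1L, config = NULL, keep_trees = FALSE) {
  if (is.null(config)) {
    scenario <- match.arg(scenario)
    config <- scenario_config(scenario, n_reps = n_reps, seed = seed)
  } else {
    config <- as_sim_config(config)
    if (length(config$pop_sizes) != 2L || any(config$pop_sizes < 1L))
      stop("custom scenario configs need samples in both populations")
    scenario <- "custom"
  }
  ingroup <- ingroup_labels(config)
  sim <- simulate_ms(config)
  reps <- tree_metrics_table(sim$trees, ingroup, sim$haplotypes)
  stopifnot(all(reps$tmrca_ingroup_4N0 <= reps$root_height_4N0),
            all(reps$basal_node_age_4N0 < reps$root_height_4N0),
            all(reps$root_height_4N0 > config$t_join))
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  hist_of <- function(x) {
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  summary <- list(
    command = render_ms_command(config),
    t_join_4N0 = config$t_join,
    n_reps = config$n_reps,
    monophyly_fraction = mean(reps$monophyletic),
    tmrca_ingroup = list(mean = mean(reps$tmrca_ingroup_4N0),
                         quantiles = stats::quantile(reps$tmrca_ingroup_4N0, qs),
                         histogram = hist_of(reps$tmrca_ingroup_4N0)),
    root_height = list(mean = mean(reps$root_height_4N0),
                       quantiles = stats::quantile(reps$root_height_4N0, qs),
                       histogram = hist_of(reps$root_height_4N0)))
  structure(
    list(scenario = scenario, config = config, replicates = reps,
         summary = summary,
         trees = if (keep_trees) sim$trees else NULL),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat("Scenario '", x$scenario, "': ", s$command, "\n", sep = "")
  cat(sprintf("  %d replicates; monophyly fraction %.4f\n",
              s$n_reps, s$monophyly_fraction))
  cat(sprintf("  ingroup TMRCA  mean %.3f (4N0); divergence (root height) mean %.3f; t_join %.3g\n",
              s$tmrca_ingroup$mean, s$root_height$mean, s$t_join_4N0))
  invisible(x)
}

#' Write scenario outputs to a directory
#'
#' Writes `replicates.tsv` (per-replicate table, unit-annotated columns)
#' and `summary.json` (config echo, monophyly fraction, quantiles and
#' histogram arrays).
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "replicates.tsv")
  json <- file.path(dir, "summary.json")
  utils::write.table(result$replicates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- result$summary
  s$tmrca_ingroup$quantiles <- as.list(s$tmrca_ingroup$quantiles)
  s$root_height$quantiles <- as.list(s$root_height$quantiles)
  jsonlite::write_json(s, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' Sweep divergence time to locate completion of lineage sorting
#'
#' For each divergence time on the grid (given in Ne generations, the
#' units in which lineage sorting is conventionally said to complete
#' after 4-7 Ne), simulates fresh genealogies of 10 ingroup plus 1
#' outgroup lineage and records the fraction in which the ingroup is
#' monophyletic. Times are converted internally to 4N0 units (t/4).
#'
#' @param t_values Ascending, non-empty divergence times in Ne
#'   generations.
#' @param n_reps Replicates per grid point.
#' @param seed Master seed; each grid point gets its own substream.
#' @param threshold Monophyly fraction in `[0, 1)` defining "complete"
#'   sorting; the smallest grid time meeting it is reported.
#' @param n_in,n_out Ingroup/outgroup sample sizes (the single-outgroup
#'   study design is the default; `n_out` must be 1 for the analytic
#'   oracle to apply).
#' @return A data frame of class `sorting_sweep` with columns `t_Ne`,
#'   `t_4N0`, `n_reps`, `monophyly_fraction`, `se` (binomial standard
#'   error) and `p_oracle` (exact [monophyly_probability()], when
#'   `n_out == 1`). Attribute `t_complete` holds the smallest qualifying
#'   `t_Ne`, or `NA` when the threshold is not reached; attribute
#'   `threshold` echoes the input.
#' @export
#' @examples
#' sw <- lineage_sorting_sweep(c(2, 4, 6), n_reps = 200, seed = 1)
#' attr(sw, "t_complete")
lineage_sorting_sweep <- function(t_values, n_reps = 5000L, seed = 1L,
                                  threshold = 0.9, n_in = 10L, n_out = 1L) {
  if (length(t_values) < 1L) stop("t_values must be non-empty")
  if (is.unsorted(t_values, strictly = TRUE))
    stop("t_values must be strictly ascending")
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  ingroup <- paste0("X", seq_len(n_in))
  rows <- lapply(seq_along(t_values), function(g) {
    t4 <- convert_time(t_values[g], "Ne", "4N0")
    cfg <- sim_config(pop_sizes = c(n_out, n_in), theta = 0, t_join = t4,
                      n_reps = n_reps, seed = mix_seed(seed, g, 2L))
    frac <- mean(vapply(simulate_replicates(cfg),
                        function(tr) is_monophyletic(tr, ingroup),
                        logical(1)))
    data.frame(t_Ne = t_values[g], t_4N0 = t4, n_reps = n_reps,
               monophyly_fraction = frac,
               se = sqrt(frac * (1 - frac) / n_reps),
               p_oracle = if (n_out == 1L)
                 monophyly_probability(n_in, t4) else NA_real_)
  })
  out <- do.call(rbind, rows)
  hit <- which(out$monophyly_fraction >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "t_complete") <- if (length(hit)) out$t_Ne[min(hit)] else NA_real_
  class(out) <- c("sorting_sweep", "data.frame")
  out
}

#' @export
print.sorting_sweep <- function(x, ...) {
  cat("Lineage-sorting sweep (times in Ne generations)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  tc <- attr(x, "t_complete")
  cat(sprintf("smallest t with monophyly fraction >= %.2f: %s\n",
              attr(x, "threshold"),
              if (is.na(tc)) "not reached" else format(tc)))
  invisible(x)
}

#' Fraction of trees whose basal-node age is below the root height
#'
#' Executable form of the strict ordering between the age of the most
#' basal non-root node and the TMRCA (root height): the returned fraction
#' is 1.0 on any valid input set of binary trees.
#'
#' @param trees List of `genealogy` objects with at least 3 leaves each.
#' @return Fraction in `[0, 1]`.
#' @export
compare_node_age_vs_tmrca <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  mean(vapply(trees,
              function(tr) basal_node_age(tr) < root_height(tr),
              logical(1)))
}
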