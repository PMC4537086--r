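# Two-population isolation-model simulator.

test_that("the deep-divergence command yields 11 population-labelled leaves", {
  cfg <- parse_ms_command("ms 11 1 -t 2.0 -I 2 1 10 -ej 10 1 2 -T")
  tr <- simulate_genealogy(cfg, 0)
  expect_s3_class(tr, "genealogy")
  expect_equal(tr$n_tips, 11L)
  expect_equal(sum(tr$tip_population == 1L), 1L)
  expect_equal(sum(tr$tip_population == 2L), 10L)
  expect_setequal(tr$tip_label, c("Y1", paste0("X", 1:10)))
})

test_that("simulated genealogies are ultrametric with strictly ordered node ages", {
  cfg <- sim_config(pop_sizes = c(2, 5), theta = 0, t_join = 0.7,
                    n_reps = 200, seed = 11)
  for (tr in simulate_replicates(cfg)) {
    n <- tr$n_tips
    expect_true(all(tr$ages[seq_len(n)] == 0))
    for (v in (n + 1L):(2L * n - 1L)) {
      expect_true(all(tr$ages[tr$children[v, ]] < tr$ages[v]))
    }
    expect_equal(root_height(tr), max(tr$ages))
  }
})

test_that("root age exceeds t_join whenever both populations are sampled", {
  cfg <- sim_config(pop_sizes = c(1, 10), theta = 0, t_join = 0.5,
                    n_reps = 500, seed = 5)
  heights <- vapply(simulate_replicates(cfg), root_height, numeric(1))
  expect_true(all(heights > 0.5))
})

test_that("two-sample root age is Exp(rate 2): sample mean 0.5 within 3 SE", {
  cfg <- sim_config(pop_sizes = c(1, 1), theta = 0, t_join = 0,
                    n_reps = 10000, seed = 42)
  heights <- vapply(simulate_replicates(cfg), root_height, numeric(1))
  expect_lt(abs(mean(heights) - 0.5), 3 * se_mean(heights))
})

test_that("t_join = 0 reduces to the panmictic coalescent of the pooled sample", {
  cfg <- sim_config(pop_sizes = c(2, 2), theta = 0, t_join = 0,
                    n_reps = 5000, seed = 8)
  heights <- vapply(simulate_replicates(cfg), root_height, numeric(1))
  expect_lt(abs(mean(heights) - expected_tmrca(4)), 3 * se_mean(heights))
})

test_that("replicates are reproducible and invariant to n_reps", {
  cfg5 <- sim_config(pop_sizes = c(1, 10), theta = 2, t_join = 10,
                     n_reps = 5, seed = 99, emit_trees = TRUE)
  trees_a <- simulate_replicates(cfg5)
  trees_b <- simulate_replicates(cfg5)
  expect_identical(lapply(trees_a, write_newick),
                   lapply(trees_b, write_newick))
  cfg2 <- cfg5; cfg2$n_reps <- 2L
  trees_c <- simulate_replicates(cfg2)
  expect_identical(write_newick(trees_c[[2]]), write_newick(trees_a[[2]]))
  expect_identical(write_newick(trees_a[[1]]),
                   write_newick(simulate_genealogy(cfg5, 0)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(pop_sizes = 1), "at least 2 samples")
  expect_error(sim_config(pop_sizes = c(1, 1), t_join = -1), "t_join")
  expect_error(sim_config(pop_sizes = c(1, 1), theta = -1), "theta")
  expect_error(sim_config(pop_sizes = c(1, 1), source_pop = 1, dest_pop = 1),
               "must differ")
  expect_error(sim_config(pop_sizes = c(1, 1), source_pop = 3), "out of range")
  expect_error(sim_config(pop_sizes = c(1, 1), n_reps = 0), "n_reps")
  expect_error(simulate_genealogy(sim_config(c(1, 1)), -1), "non-negative")
})

test_that("root-age distribution matches an independent coalescent simulator (msprime)", {
  # Cross-validation against msprime under the identical two-population
  # isolation model (10 + 1 samples, split at t_join): two-sample
  # Kolmogorov-Smirnov at alpha = 0.01.
  t_join <- 0.25
  n <- 3000
  script <- sprintf('
import msprime, sys
dem = msprime.Demography()
dem.add_population(name="X", initial_size=2)
dem.add_population(name="Y", initial_size=2)
dem.add_population(name="anc", initial_size=2)
dem.add_population_split(time=%f, derived=["X", "Y"], ancestral="anc")
reps = msprime.sim_ancestry({"X": 10, "Y": 1}, demography=dem,
                            ploidy=1, num_replicates=%d, random_seed=123)
for ts in reps:
    print(ts.max_root_time / 4.0)
', 4 * t_join, n)
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", py, stdout = TRUE)
  ref <- as.numeric(out)
  expect_equal(length(ref), n)
  cfg <- sim_config(pop_sizes = c(1, 10), theta = 0, t_join = t_join,
                    n_reps = n, seed = 77)
  mine <- vapply(simulate_replicates(cfg), root_height, numeric(1))
  ks <- suppressWarnings(stats::ks.test(mine, ref))
  expect_gt(ks$p.value, 0.01)
})
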