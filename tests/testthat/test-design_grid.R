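grid_params <- function(...) {
  analysis_params(replicate_grid = c(2, 3), depth_grid = c(1e4, 2e4),
                  n_repetitions = 3, master_seed = 5, ...)
}

test_that("the grid enumerates cells and is deterministic from the master seed", {
  pilot <- small_pilot(n_genes = 200, reps = 8, lib = 4e4, seed = 201)
  params <- grid_params()
  cells <- run_grid(pilot$counts, pilot$design, params)
  expect_length(cells, 2 * 2 * 3)

  again <- run_grid(pilot$counts, pilot$design, params)
  expect_identical(lapply(cells, `[[`, "de_set"),
                   lapply(again, `[[`, "de_set"))

  # infeasible grids fail before any computation
  bad_r <- grid_params()
  bad_r$replicate_grid <- c(2L, 9L)
  expect_error(run_grid(pilot$counts, pilot$design, bad_r), "exceeds available")
  bad_d <- grid_params()
  bad_d$depth_grid <- 1e9
  expect_error(run_grid(pilot$counts, pilot$design, bad_d), "depth_grid")
})

test_that("the dispersion-mode rule and full-data rule are applied per cell", {
  pilot <- small_pilot(n_genes = 150, reps = 5, lib = 2e4, seed = 202)
  params <- analysis_params(replicate_grid = c(4, 5), depth_grid = 1e4,
                            n_repetitions = 2, master_seed = 1)
  cells <- run_grid(pilot$counts, pilot$design, params)
  modes <- vapply(cells, `[[`, character(1), "dispersion_mode")
  rs <- vapply(cells, `[[`, numeric(1), "r")
  expect_true(all(modes[rs == 4] == "common"))
  expect_true(all(modes[rs == 5] == "tagwise"))
  # r = 5 of 5 available: single possible draw, run once
  expect_identical(sum(rs == 5), 1L)
  expect_identical(sum(rs == 4), 2L)
})

test_that("indicator aggregation matches hand-computed medians and stability", {
  mk <- function(r, d, rep_i, set) list(r = r, depth = d, repetition = rep_i,
                                        seed = 0, dispersion_mode = "common",
                                        de_set = set)
  cells <- list(mk(2, 1e4, 1, c("A", "B", "C")),
                mk(2, 1e4, 2, c("B", "C", "D")),
                mk(2, 1e4, 3, c("B", "E")))
  ref <- c("B", "D")
  summary <- aggregate_indicators(cells, ref)
  expect_equal(summary$median_nde, 3)
  expect_equal(summary$stability_nde, 1)          # intersection {B}
  expect_equal(summary$median_power, 0.5)         # per-rep powers .5, 1, .5
  expect_equal(summary$stability_power, 0.5)      # {B} vs {B, D}

  counts_only <- aggregate_indicators(list(mk(2, 1, 1, letters[1:10]),
                                           mk(2, 1, 2, letters[1:20]),
                                           mk(2, 1, 3, letters[1:30])),
                                      letters[1:5])
  expect_equal(counts_only$median_nde, 20)
  # identical sets per repetition: stability equals the median count
  same <- aggregate_indicators(rep(list(mk(3, 1, 1, c("x", "y"))), 1), c("x"))
  expect_equal(same$stability_nde, same$median_nde)

  expect_error(aggregate_indicators(list(mk(2, 1, 1, "a"), mk(2, 1, 3, "b")),
                                    "a"),
               "missing repetition")
})

test_that("stratum-restricted indicators intersect sets with the stratum", {
  mk <- function(rep_i, set) list(r = 2, depth = 1, repetition = rep_i,
                                  seed = 0, dispersion_mode = "common",
                                  de_set = set)
  strata <- factor(stats::setNames(c("low", "low", "high", "high", "medium"),
                                   c("A", "B", "C", "D", "E")),
                   levels = c("low", "medium", "high"))
  cells <- list(mk(1, c("A", "C", "E")), mk(2, c("A", "B", "C")))
  summary <- aggregate_indicators(cells, reference = c("A", "C"), strata = strata)
  expect_equal(summary$median_nde_low, 1.5)   # sizes 1 and 2
  expect_equal(summary$stability_nde_low, 1)  # {A}
  expect_equal(summary$median_power_low, 1)   # low reference = {A}
  expect_equal(summary$stability_nde_high, 1) # {C}
  expect_equal(summary$median_power_high, 1)
})

test_that("stability power never exceeds median power on real grids", {
  pilot <- small_pilot(n_genes = 300, reps = 6, lib = 3e4, seed = 203)
  params <- analysis_params(replicate_grid = c(2, 4), depth_grid = c(1e4, 2.5e4),
                            n_repetitions = 4, master_seed = 11)
  full <- run_de(pilot$counts, pilot$design)
  ref <- reference_de_set(full, 1e-4)
  cells <- run_grid(pilot$counts, pilot$design, params)
  summary <- aggregate_indicators(cells, ref)
  expect_true(all(summary$stability_power <= summary$median_power + 1e-12))
  expect_true(all(summary$stability_nde <=
                    vapply(split(cells, vapply(cells, function(cell)
                      paste(cell$r, cell$depth), character(1))),
                      function(block) max(lengths(lapply(block, `[[`, "de_set"))),
                      numeric(1))[paste(summary$r, summary$depth)]))
})

test_that("median power increases from the weakest to the strongest design", {
  pilot <- small_pilot(n_genes = 400, reps = 7, lib = 4e4, seed = 204)
  params <- analysis_params(replicate_grid = c(2, 7), depth_grid = c(1e4, 3.5e4),
                            n_repetitions = 3, master_seed = 21)
  full <- run_de(pilot$counts, pilot$design)
  ref <- reference_de_set(full, 1e-4)
  summary <- aggregate_indicators(run_grid(pilot$counts, pilot$design, params),
                                  ref)
  weakest <- summary[summary$r == 2 & summary$depth == 1e4, ]
  strongest <- summary[summary$r == 7 & summary$depth == 3.5e4, ]
  expect_gt(strongest$median_power, weakest$median_power)
  expect_gte(strongest$median_nde, weakest$median_nde)
})

test_that("equal-budget views select, order and classify combinations", {
  summary <- data.frame(r = c(2, 4, 8, 3),
                        depth = c(2e7, 1e7, 5e6, 1e7),
                        median_power = c(0.5, 0.7, 0.9, 0.55))
  view <- equal_budget_view(summary, 4e7)
  expect_identical(view$r, c(2, 4, 8))  # the 3e7 combination is excluded
  expect_identical(attr(view, "dominance"), "replicates")

  rev_view <- equal_budget_view(
    data.frame(r = c(2, 4, 8), depth = c(2e7, 1e7, 5e6),
               median_power = c(0.9, 0.7, 0.5)), 4e7)
  expect_identical(attr(rev_view, "dominance"), "depth")

  # budget off by < 15% still qualifies
  near <- equal_budget_view(summary, 3.9e7)
  expect_identical(nrow(near), 3L)
  expect_error(equal_budget_view(summary, 1e9), "fewer than two")
})
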