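# Parameter space partitioning: grid mechanics, determinism, aggregation.

test_that("grid sizes are computed, never materialized", {
  expect_equal(n_param_sets(psp_grid("orl", points = 60)), 777600000)
  expect_equal(n_param_sets(psp_grid("vse", points = 8)), 32768)
  expect_equal(n_param_sets(psp_grid("ev", points = 60)), 216000)
  g1 <- psp_grid("orl", points = 1)
  expect_equal(n_param_sets(g1), 1)
  expect_equal(grid_points(g1, "A_rew"), 0.5)
  expect_equal(grid_points(g1, "beta_F"), 0)
  g <- psp_grid("vse", points = 5)
  expect_equal(grid_points(g, "beta"), seq(0, 5, length.out = 5))
})

test_that("invalid grids are rejected", {
  expect_error(psp_grid("orl", points = 0), "points")
  expect_error(psp_grid("nonsense"))
  expect_error(psp_grid("orl", bounds = tibble::tibble(
    parameter = c("A_rew", "A_pun", "K_prime", "beta_F", "beta_P"),
    min = c(0, 0, 0, -Inf, -5), max = c(1, 1, 5, Inf, 5))), "truncation")
})

test_that("a single-set grid yields a unit mass on one label", {
  r <- run_psp(psp_grid("orl", points = 1), seed = 4)
  broad <- r$proportions[r$proportions$definition == "broad", ]
  expect_equal(sum(broad$proportion == 1), 1)
  expect_equal(sum(broad$proportion), 1)
})

test_that("PSP results are deterministic and chunking-invariant", {
  g <- psp_grid("vse", points = 4) # 1024 sets
  r1 <- run_psp(g, seed = 6, chunk_size = 1024)
  r2 <- run_psp(g, seed = 6, chunk_size = 97)
  expect_equal(r1$proportions, r2$proportions)
  r3 <- run_psp(g, seed = 6, chunk_size = 1024)
  expect_identical(r1$proportions, r3$proportions)
  r4 <- run_psp(g, seed = 7)
  expect_false(identical(r1$proportions, r4$proportions))
})

test_that("broad proportions sum to one and renormalized restricted too", {
  r <- run_psp(psp_grid("orl", points = 4), seed = 2, definition = "both")
  pr <- r$proportions
  expect_equal(sum(pr$proportion[pr$definition == "broad"]), 1,
               tolerance = 1e-9)
  ren <- pr$proportion[pr$definition == "restricted_renorm"]
  if (length(ren)) expect_equal(sum(ren), 1, tolerance = 1e-9)
  raw <- pr[pr$definition == "restricted_raw", ]
  expect_equal(sum(raw$proportion), 1, tolerance = 1e-9) # includes "none"
})

test_that("disjoint half-grids agree within Monte-Carlo error", {
  g <- psp_grid("vse", points = 6) # 7776 sets
  r <- run_psp(g, seed = 9, keep_labels = TRUE, definition = "broad")
  lab <- r$labels
  even <- lab[seq(1, length(lab), 2)]
  odd <- lab[seq(2, length(lab), 2)]
  for (l in c("GOB", "BOG", "IOF", "FOI")) {
    p1 <- mean(even == l)
    p2 <- mean(odd == l)
    se <- sqrt(0.25 * 2 / length(even))
    expect_lt(abs(p1 - p2), 5 * se + 0.01)
  }
})

test_that("ORL's space is dominated by GOB and FOI, with small BOG and IOF", {
  r <- run_psp(psp_grid("orl", points = 6), seed = 1, definition = "broad")
  p <- r$proportions$proportion
  names(p) <- r$proportions$label
  expect_gt(p[["GOB"]] + p[["FOI"]], 0.7)
  expect_lt(p[["BOG"]], 0.15)
  expect_lt(p[["IOF"]], 0.15)
})

test_that("restricted runs demand 100-trial sessions", {
  expect_error(run_psp(psp_grid("orl", points = 2), n_trials = 40,
                       definition = "both"), "100-trial")
  expect_silent(r <- run_psp(psp_grid("orl", points = 2), n_trials = 40,
                             definition = "broad"))
})

test_that("comparison tables assemble and validate", {
  r1 <- run_psp(psp_grid("orl", points = 3), seed = 5)
  r2 <- run_psp(psp_grid("vse", points = 3), seed = 5)
  tab <- compare_parameter_spaces(list(r1, r2))
  expect_equal(names(tab), c("label", "orl", "vse"))
  expect_equal(nrow(tab), 5)
  one <- compare_parameter_spaces(r1)
  expect_equal(ncol(one), 2)
  expect_error(compare_parameter_spaces(list()), "no PSP")
  rb <- run_psp(psp_grid("vse", points = 3), seed = 5, definition = "broad")
  expect_error(compare_parameter_spaces(list(r1, rb),
                                        definition = "restricted_raw"),
               "lacks")
})

test_that("replicates add independent runs per parameter set", {
  g <- psp_grid("vse", points = 3)
  r <- run_psp(g, seed = 2, replicates = 3)
  expect_equal(r$n_runs, 3 * n_param_sets(g))
  expect_equal(sum(r$proportions$n[r$proportions$definition == "broad"]),
               r$n_runs)
})
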