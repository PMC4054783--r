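test_that("analytic expectations match the published concordance layout", {
  # E column for all nine catalogue pairs (universe 4,096), 1 d.p.
  e <- function(n1, n2) round(expected_pairwise_overlap(n1, n2, 4096), 1)
  expect_equal(e(238, 238), 13.8)
  expect_equal(e(238, 285), 16.6)
  expect_equal(e(238, 400), 23.2)
  expect_equal(e(285, 400), 27.8)
  expect_equal(e(238, 1182), 68.7)
  expect_equal(e(285, 1182), 82.2)
  expect_equal(expected_pairwise_overlap(0, 100, 4096), 0)
  expect_error(expected_pairwise_overlap(10, 10, 0), "positive")
  # multi-way: one sample intersects itself
  expect_equal(expected_multiway_overlap(57, 4096), 57)
  expect_equal(round(expected_multiway_overlap(c(238, 238, 285), 400)), 101)
  expect_true(expected_multiway_overlap(c(238, 238, 285), 1182) > 11 &&
                expected_multiway_overlap(c(238, 238, 285), 1182) < 12)
  expect_error(expected_multiway_overlap(c(500, 100), 400), "<= N")
})

test_that("simulated overlap null matches hypergeometric closed forms", {
  sim <- simulate_overlap(c(238, 238), universe = 4096, reps = 4000,
                          seed = 101)
  m <- expected_pairwise_overlap(238, 238, 4096)
  v <- pairwise_overlap_variance(238, 238, 4096)
  mc_se_mean <- sqrt(v / sim$reps)
  expect_lt(abs(sim$expected_mean - m), 3 * mc_se_mean)
  mc_se_sd <- sqrt(v) / sqrt(2 * (sim$reps - 1))
  expect_lt(abs(sim$expected_sd - sqrt(v)), 3 * mc_se_sd)
  # observed at the simulated mean gives Z ~ 0
  simz <- simulate_overlap(c(50, 60), observed = round(
    expected_pairwise_overlap(50, 60, 4096)), universe = 4096,
    reps = 2000, seed = 5)
  expect_lt(abs(simz$z), 1)
  expect_error(simulate_overlap(c(500, 10), universe = 400, seed = 1),
               "exceeds")
})

test_that("overlap significance is invariant to catalogue labelling order", {
  a <- simulate_overlap(c(120, 300), observed = 30, universe = 4096,
                        reps = 3000, seed = 7)
  b <- simulate_overlap(c(300, 120), observed = 30, universe = 4096,
                        reps = 3000, seed = 8)
  se <- sqrt(pairwise_overlap_variance(120, 300, 4096) / 3000)
  expect_lt(abs(a$expected_mean - b$expected_mean), 6 * se)
  expect_lt(abs(a$z - b$z), 1)
  expect_lt(abs(a$fold - b$fold), 0.5)
})

test_that("overlap_table reports O/E/F/Z/P for every pair", {
  sets <- list(A = fix_pool(60, 1), B = fix_pool(80, 2), C = fix_pool(40, 3))
  tab <- overlap_table(sets, reps = 500, seed = 9)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("n1", "n2", "O", "E", "F", "Z", "P") %in% names(tab)))
  expect_equal(tab$E, with(tab, n1 * n2 / 4096))
  expect_true(all(tab$P >= 0 & tab$P <= 1))
})

test_that("pool-size estimation inverts the sampling model", {
  # analytic inversion recovers a known pool exactly for two catalogues
  n <- 800
  target <- expected_pairwise_overlap(200, 240, n)
  expect_equal(estimate_pool_size(c(200, 240), target, method = "analytic",
                                  round_to = 1), n)
  # monotone: a larger target intersection implies a smaller pool
  est_hi <- estimate_pool_size(c(238, 238, 285, 400), 20,
                               method = "analytic", round_to = 1)
  est_lo <- estimate_pool_size(c(238, 238, 285, 400), 10,
                               method = "analytic", round_to = 1)
  expect_lt(est_hi, est_lo)
  expect_error(estimate_pool_size(c(100, 200), 150, method = "analytic"),
               "impossible")
  # simulation-based search recovers a generated pool
  cat600 <- gen_hexamer_catalogues(600, c(238, 238, 285, 400), seed = 33)
  obs <- length(intersect_at_least(cat600$sets, 4))
  est <- estimate_pool_size(c(238, 238, 285, 400), obs, reps = 3000,
                            seed = 34)
  expect_lt(abs(est - 600), 0.15 * 600)
})

test_that("per-catalogue contribution Z scores behave at the extremes", {
  s <- fix_pool(40, 5)
  four <- list(a = s, b = s, c = s, d = s)
  cz <- contribution_zscores(four, k = 3, reps = 400, seed = 6)
  expect_true(all(cz$observed == 40))
  expect_true(all(cz$Z > 5))
  # disjoint sets: nothing reaches a 3-way intersection
  disj <- list(a = hexamer_set(all_hexamers()[1:30]),
               b = hexamer_set(all_hexamers()[31:60]),
               c = hexamer_set(all_hexamers()[61:90]))
  expect_warning(
    cz2 <- contribution_zscores(disj, k = 3, reps = 300, seed = 7),
    "degenerate")
  expect_true(all(cz2$observed == 0))
  # catalogues genuinely drawn from the universe calibrate near zero
  rnd <- lapply(1:4, function(i) fix_pool(120, 50 + i))
  cz3 <- contribution_zscores(rnd, k = 3, reps = 400, seed = 8)
  expect_true(all(abs(cz3$Z) < 4, na.rm = TRUE))
})
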