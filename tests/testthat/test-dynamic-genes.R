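test_that("mouse GAD reproduces every piecewise branch", {
  # hand-derived: old(10)=1 (middle branch), gain(8)=1, young(2)=1, ratio cap
  res <- gad_mouse(x_young_pct = 2, x_old_pct = 10, r = 5)
  expect_equal(unlist(res[, c("old", "gain", "young", "ratio")]),
    c(old = 1, gain = 1, young = 1, ratio = 2.5)
  )
  expect_equal(res$gad, 5.5)

  # logistic branch at small positivity
  expect_equal(gad_mouse(0.5, 2, 1)$old, 1 / (1 + exp(-4)))
  # declining branch: old(24) = -24/4 + 6 = 0
  expect_equal(gad_mouse(1, 24, 2)$old, 0)
  # gain branches: gain(2)=0.4, gain(20)=0, gain(10)=1
  expect_equal(gad_mouse(1, 3, 1)$gain, 0.4)
  expect_equal(gad_mouse(1, 21, 1)$gain, 0)
  expect_equal(gad_mouse(1, 11, 1)$gain, 1)
  # young branches: young(6) = -3 + 3.5 = 0.5
  expect_equal(gad_mouse(6, 10, 1)$young, 0.5)
  # ratio cap is exact
  expect_identical(gad_mouse(1, 10, 3.0)$ratio, 2.5)
  expect_identical(gad_mouse(1, 10, 2.49)$ratio, 2.49)
  # gad equals the sum of its components
  for (args in list(c(2, 10, 5), c(0.3, 2.2, 1.3), c(7, 30, 0.4))) {
    r <- gad_mouse(args[1], args[2], args[3])
    expect_equal(r$gad, r$old + r$gain + r$young + r$ratio, tolerance = 1e-12)
  }
  expect_error(gad_mouse(1, 10, 0), class = "senesig_data_error")
})

test_that("the old-proportion reward is non-decreasing up to 20% and flat on (3, 20]", {
  xs <- seq(0.1, 20, length.out = 100)
  olds <- gad_mouse(rep(2, 100), xs, rep(1.5, 100))$old
  expect_true(all(diff(olds) >= -1e-12))
  expect_true(all(gad_mouse(2, seq(3.01, 20, 0.5), 1.5)$old == 1))
})

test_that("human GAD reproduces its printed branches", {
  res <- gad_human(2, 10, slope_pct_per_year = 0.1, age_of_peak = 68, age_max = 68)
  expect_equal(
    unlist(res[, c("old", "gain", "young", "dMax", "aMax", "slope_term")]),
    c(old = 1, gain = 1, young = 1, dMax = 1, aMax = 1, slope_term = 0.5)
  )
  expect_equal(res$gad, 5.5)
  # aMax penalty below 38 years: aMax(28) = -10
  expect_equal(gad_human(2, 10, 0.1, 28, 28)$aMax, -10)
  # corrected dMax penalizes peaks far before the oldest bin
  expect_equal(gad_human(2, 10, 0.1, 18, 88)$dMax, -(70 - 50))
  # literal printed direction makes the penalty branch unreachable
  expect_equal(gad_human(2, 10, 0.1, 18, 88, dmax_literal = TRUE)$dMax, 1)
  # slope gate: non-positive slope is never a candidate
  expect_false(gad_human(2, 10, 0, 68, 68)$candidate)
  expect_false(gad_human(2, 10, -0.2, 68, 68)$candidate)
  expect_true(gad_human(2, 10, 0.01, 68, 68)$candidate)
})

test_that("positivity computes proportions with young-baseline imputation", {
  m <- matrix(0, 2, 200)
  m[1, 1:3] <- 5 # gene 1 in 3 of 200 cells
  ac <- counts_from_dense(m, ages = rep(3, 200))
  p <- positivity(ac)
  expect_equal(p$p, c(3 / 200, 0))
  pi <- positivity(ac, impute_zero = TRUE)
  expect_equal(pi$p[2], 1 / 200)
  expect_true(pi$imputed[2])
  expect_false(pi$imputed[1])
  # imputed proportions never exceed any non-imputed positive proportion
  expect_true(pi$p[2] <= min(pi$p[!pi$imputed & pi$n_pos > 0]))
  # all-positive gene
  m2 <- matrix(1, 1, 10)
  expect_equal(positivity(counts_from_dense(m2, rep(3, 10)))$p, 1)
  expect_error(positivity(ac, cells = integer(0)), class = "senesig_data_error")
})

test_that("mouse stratification follows the 200-cell baseline rules", {
  mk <- function(n3, n1, n30, n24, n18 = 0) {
    ages <- c(rep(3, n3), rep(1, n1), rep(30, n30), rep(24, n24), rep(18, n18))
    counts_from_dense(matrix(1, 2, length(ages)), ages)
  }
  # enough 3m and 30m cells: single-age baselines
  s <- stratify_mouse(mk(250, 100, 300, 50))
  expect_equal(s$n_young, 250)
  expect_equal(s$n_old, 300)
  # young fallback aggregates 1m with 3m
  s <- suppressMessages(stratify_mouse(mk(150, 100, 300, 0)))
  expect_equal(s$n_young, 250)
  # old fallback to 24m when 30m is short
  s <- stratify_mouse(mk(250, 0, 150, 220))
  expect_equal(s$n_old, 220)
  # no old baseline -> population skipped
  expect_equal(nrow(suppressMessages(stratify_mouse(mk(250, 0, 0, 0, n18 = 300)))), 0)
})

test_that("human stratification implements both eligibility paths", {
  mk <- function(bins) {
    ages <- unlist(mapply(rep, as.numeric(names(bins)), bins, SIMPLIFY = FALSE))
    counts_from_dense(matrix(1, 2, length(ages)), ages, age_unit = "years")
  }
  # three bins >= 100 with one >= 48
  expect_equal(nrow(stratify_human(mk(c("20" = 120, "50" = 150, "70" = 200)))), 1)
  # young<=28 + old>=58 path (58 bin also satisfies >=48)
  expect_equal(nrow(stratify_human(mk(c("30" = 150, "60" = 150)))), 1)
  # neither path
  expect_equal(nrow(suppressMessages(stratify_human(mk(c("40" = 500, "50" = 500))))), 0)
  # three bins but none >= 48 -> ineligible
  expect_equal(nrow(suppressMessages(stratify_human(mk(c("10" = 200, "20" = 200, "30" = 200))))), 0)
  # bins below 100 cells do not count
  expect_equal(nrow(suppressMessages(stratify_human(mk(c("20" = 99, "60" = 150))))), 0)
})

test_that("age binning maps years to decade bins indexed from 8", {
  expect_equal(human_age_bin(c(8, 17, 18, 27, 48, 92)), c(8, 8, 18, 18, 48, 88))
})

test_that("p18 extrapolation matches the closed two-point form and floors", {
  # points on the line p = 0.001 * age -> p18 = 0.018
  expect_equal(extrapolate_p18(c(28, 48, 68), 0.001 * c(28, 48, 68), 100), 0.018)
  # negative extrapolation floored at 1/n of the youngest bin
  expect_equal(extrapolate_p18(c(48, 68), c(0.02, 0.04), 150), 1 / 150)
  expect_error(extrapolate_p18(c(48, 48), c(0.1, 0.2), 100),
    class = "senesig_data_error"
  )
})

test_that("permutation null preserves per-gene positive counts and is seeded", {
  k_pos <- c(5L, 40L, 120L)
  sizes <- c(200L, 300L)
  # the group-count shuffle preserves each gene's total positives
  set.seed(99)
  for (i in 1:25) {
    k <- senesig:::split_positives(k_pos, sizes)
    expect_equal(rowSums(k), k_pos)
    expect_true(all(k >= 0))
    expect_true(all(t(k) <= sizes))
  }
  n1 <- permutation_null(k_pos, sizes, "mouse", n_perm = 50, seed = 4)
  n2 <- permutation_null(k_pos, sizes, "mouse", n_perm = 50, seed = 4)
  expect_identical(n1$values, n2$values)
  expect_length(n1$values, 50 * 3)
  expect_error(permutation_null(k_pos, sizes, "mouse", n_perm = 0),
    class = "senesig_data_error"
  )
})

test_that("empirical p-values and dynamic calls behave at the extremes", {
  obs <- tibble::tibble(gene = c("hi", "mid"), gad = c(10, 0))
  null_vals <- c(rnorm(10000), 0) # median ~ 0, max << 10
  called <- call_dynamic(obs, null_vals, alpha = 0.01)
  expect_equal(called$empirical_p[1], 1 / (length(null_vals) + 1))
  expect_true(called$dynamic[1])
  expect_gt(called$empirical_p[2], 0.4)
  expect_false(called$dynamic[2])
  # monotonicity of the called set in alpha
  d01 <- call_dynamic(obs, null_vals, alpha = 0.01)$dynamic
  d05 <- call_dynamic(obs, null_vals, alpha = 0.05)$dynamic
  expect_true(all(!d01 | d05))
})

test_that("a planted rising gene is called dynamic against static background", {
  # positivity 1% young -> 10% old against static genes, several seeds
  hits <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_counts(sim_spec(
      n_genes = 800L, n_cells_per_age = 400L, seed = 100L + s,
      programs = list(list(
        n_genes = 1L, co_positive_rate = 0.9, background_positivity = 0.01
      ))
    ))
    dyn <- suppressMessages(
      find_dynamic_genes(sim$data, "mouse", n_perm = 200, seed = s)
    )
    planted <- sim$program_genes$program1
    hits <- hits + (planted %in% dyn$gene[dyn$dynamic])
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("human dynamic-gene calling requires a positive slope", {
  sim <- simulate_counts(sim_spec(
    n_genes = 600L, n_cells_per_age = 500L, age_groups = c(25, 50, 70),
    age_unit = "years",
    senescent_fraction = c("25" = 0.01, "50" = 0.05, "70" = 0.10), seed = 21
  ))
  dyn <- suppressMessages(find_dynamic_genes(sim$data, "human", n_perm = 100, seed = 2))
  expect_true(all(dyn$ratio_or_slope[dyn$dynamic] > 0))
  planted <- sim$program_genes$program1
  expect_gte(sum(planted %in% dyn$gene[dyn$dynamic]), 12)
})
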