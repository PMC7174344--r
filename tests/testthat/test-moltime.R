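# Independent oracle: forward-simulate per-copy Poisson mutation accrual
# by enumerating every copy lineage's (rate multiplier, duration,
# final multiplicity) intervals explicitly, then count by multiplicity.
forward_sim_counts <- function(scenario, t1, T, t2 = NA, mu = 5) {
  iv <- switch(scenario,
    gain_2_1 = list(c(1, t1, 2), c(2, T - t1, 1), c(1, T, 1)),
    cnloh_2_0 = list(c(1, t1, 2), c(2, T - t1, 1)),
    tetra_2_2_sync = list(c(2, t1, 2), c(4, T - t1, 1)),
    tetra_3_1_seq = list(c(1, t1, 3), c(1, t2 - t1, 2), c(1, t2 - t1, 1),
                         c(3, T - t2, 1), c(1, T, 1)),
    tetra_4_0_seq = list(c(1, t1, 4), c(2, t2 - t1, 2), c(4, T - t2, 1)))
  counts <- c(n1 = 0, n2 = 0, n3 = 0, n4 = 0)
  for (x in iv) {
    m <- paste0("n", x[3])
    counts[m] <- counts[m] + stats::rpois(1, mu * x[1] * x[2])
  }
  counts
}

test_that("expected_vaf reproduces the corrected-VAF constants", {
  expect_equal(expected_vaf(2, 1, 3), 2 / 3, tolerance = 1e-12)  # 66%
  expect_equal(expected_vaf(1, 1, 3), 1 / 3, tolerance = 1e-12)  # 33%
  expect_equal(expected_vaf(1, 0.5, 2), 0.25)
  expect_equal(expected_vaf(2, 1, 4), 0.5)  # intermediate stage, 2 of 4
  expect_error(expected_vaf(4, 1, 3), "multiplicity")
  expect_error(expected_vaf(1, 0, 2), "purity")
  # strictly increasing in m and purity
  expect_true(all(diff(expected_vaf(1:3, 0.8, 3)) > 0))
  rho <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(expected_vaf(1, rho, 3)) > 0))
})

test_that("assign_multiplicity recovers planted multiplicities", {
  set.seed(41)
  truth_m <- rep(c(2L, 1L), c(200, 300))
  depth <- 40; rho <- 0.8
  tot <- stats::rpois(500, depth); tot[tot == 0] <- 1L
  altr <- stats::rbinom(500, tot, expected_vaf(truth_m, rho, 3))
  rec <- mutation_records("chr1", seq_len(500) * 100L, "C", "T", "s1",
                          alt_reads = altr, total_reads = tot,
                          context5 = "A", context3 = "A")
  amc <- assign_multiplicity(rec, purity = rho, scenario = "gain_2_1")
  expect_true(amc$estimable)
  expect_equal(unname(amc$counts[["n2"]]), 200, tolerance = 0.05 * 500)
  expect_equal(unname(amc$counts[["n1"]]), 300, tolerance = 0.05 * 500)
  expect_gt(mean(amc$labels == truth_m), 0.9)
})

test_that("assign_multiplicity degenerate and floor cases", {
  set.seed(42)
  tot <- rep(60L, 120)
  altr <- stats::rbinom(120, tot, expected_vaf(1, 0.8, 3))
  rec <- mutation_records("chr1", seq_len(120) * 10L, "C", "T", "s1",
                          alt_reads = altr, total_reads = tot,
                          context5 = "A", context3 = "A")
  amc <- assign_multiplicity(rec, 0.8, "gain_2_1")
  expect_equal(unname(amc$counts[["n2"]]), 0)

  rec49 <- rec[1:49, ]
  amc49 <- assign_multiplicity(rec49, 0.8, "gain_2_1")
  expect_false(amc49$estimable)
  expect_error(molecular_time(amc49, "gain_2_1"), "floor is 50")
  expect_error(assign_multiplicity(rec, NULL, "gain_2_1"), "purity")
  expect_error(assign_multiplicity(rec, 0.8, "gain_9_9"), "scenario")
})

test_that("molecular_time closed forms match hand values", {
  expect_equal(molecular_time(c(n1 = 60, n2 = 0), "gain_2_1")$pi1, 0)
  expect_equal(molecular_time(c(n1 = 60, n2 = 30), "gain_2_1")$pi1, 0.75)
  mt <- molecular_time(c(n1 = 40, n2 = 20, n4 = 10), "tetra_4_0_seq")
  expect_equal(mt$pi1, 40 / 120, tolerance = 1e-12)
  expect_equal(mt$pi2, 80 / 120, tolerance = 1e-12)
  expect_error(molecular_time(c(n1 = 0, n2 = 0), "gain_2_1"), "zero")
  # clipping
  clipped <- molecular_time(c(n1 = 0, n2 = 50), "gain_2_1")
  expect_equal(clipped$pi1, 1)
  expect_true(clipped$clipped)
})

test_that("molecular_time matches the forward-simulation oracle", {
  set.seed(43)
  cases <- list(
    list(scenario = "gain_2_1", t1 = 30, T = 40),
    list(scenario = "cnloh_2_0", t1 = 10, T = 40),
    list(scenario = "tetra_2_2_sync", t1 = 20, T = 40),
    list(scenario = "tetra_3_1_seq", t1 = 12, t2 = 28, T = 40),
    list(scenario = "tetra_4_0_seq", t1 = 16, t2 = 32, T = 40))
  for (cs in cases) {
    errs1 <- errs2 <- numeric(20)
    for (r in 1:20) {
      cn <- forward_sim_counts(cs$scenario, cs$t1, cs$T,
                               t2 = if (is.null(cs$t2)) NA else cs$t2,
                               mu = 8)
      mt <- molecular_time(cn, cs$scenario)
      errs1[r] <- abs(mt$pi1 - cs$t1 / cs$T)
      if (!is.null(cs$t2)) errs2[r] <- abs(mt$pi2 - cs$t2 / cs$T)
    }
    # per-replicate noise at n ~ 700 is ~0.03 SD; the accuracy contract
    # is on the mean absolute error
    expect_lt(mean(errs1), 0.05)
    expect_lt(mean(errs2), 0.05)
  }
})

test_that("bootstrap_moltime is deterministic and narrows with n", {
  c_small <- c(n1 = 60, n2 = 30)
  c_big <- c_small * 100
  b1 <- bootstrap_moltime(c_small, "gain_2_1", n_boot = 300, seed = 5)
  b1b <- bootstrap_moltime(c_small, "gain_2_1", n_boot = 300, seed = 5)
  expect_equal(b1$ci1, b1b$ci1)
  expect_true(b1$ci1[1] <= b1$pi1 && b1$pi1 <= b1$ci1[2])
  b2 <- bootstrap_moltime(c_big, "gain_2_1", n_boot = 300, seed = 5)
  expect_lt(diff(b2$ci1), diff(b1$ci1))
  expect_error(bootstrap_moltime(c_small, "gain_2_1", n_boot = 1), "n_boot")
})

test_that("cluster_time_windows separates and merges correctly", {
  b_early <- bootstrap_moltime(c(n1 = 540, n2 = 20), "gain_2_1",
                               n_boot = 200, seed = 1)
  b_late <- bootstrap_moltime(c(n1 = 120, n2 = 180), "gain_2_1",
                              n_boot = 200, seed = 2)
  w2 <- cluster_time_windows(list(g1 = b_early, g2 = b_late))
  expect_equal(length(unique(w2)), 2)
  expect_lt(w2[["g1"]], w2[["g2"]])  # earliest window numbered first

  b_same <- bootstrap_moltime(c(n1 = 120, n2 = 180), "gain_2_1",
                              n_boot = 200, seed = 3)
  w1 <- cluster_time_windows(list(g1 = b_late, g2 = b_same))
  expect_equal(length(unique(w1)), 1)
  expect_equal(unname(cluster_time_windows(matrix(0.5, 10, 1,
    dimnames = list(NULL, "g")))), 1L)
})

test_that("two true epochs are recovered from six gains (property)", {
  set.seed(44)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    boots <- lapply(1:6, function(g) {
      pi_true <- if (g <= 3) 0.2 else 0.8
      # counts at n = 300 with the gain_2_1 geometry
      n2 <- stats::rpois(1, 300 * pi_true / 3)
      n1 <- 300 - n2
      bootstrap_moltime(c(n1 = n1, n2 = n2), "gain_2_1", n_boot = 100,
                        seed = r * 10 + g)
    })
    w <- cluster_time_windows(boots)
    if (length(unique(w)) == 2 &&
        all(w[1:3] == w[1]) && all(w[4:6] == w[4])) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("intermediary-stage logic distinguishes one vs two windows", {
  set.seed(45)
  mk <- function(n2_planted) {
    m <- rep(c(4L, 2L, 1L), c(100, n2_planted, 200))
    tot <- rep(60L, length(m))
    altr <- stats::rbinom(length(m), tot, expected_vaf(m, 1, 4))
    rec <- mutation_records("chr1", seq_along(m) * 10L, "C", "T", "s1",
                            alt_reads = altr, total_reads = tot,
                            context5 = "A", context3 = "A")
    assign_multiplicity(rec, 1, "tetra_4_0_seq")
  }
  expect_equal(detect_intermediate_stage(mk(50)), "two_windows")
  expect_equal(detect_intermediate_stage(mk(0)), "one_window")
  amc_gain <- mk(50); amc_gain$scenario <- "gain_2_1"
  expect_error(detect_intermediate_stage(amc_gain), "tetrasom")
})

test_that("pi is monotone in the duplicated count (property)", {
  pis <- vapply(seq(0, 200, by = 20), function(n2) {
    molecular_time(c(n1 = 300, n2 = n2), "gain_2_1")$pi1
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
  expect_true(all(pis >= 0 & pis <= 1))
})
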