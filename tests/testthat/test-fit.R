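test_that("fit_exposures recovers pure and mixed synthetic catalogs", {
  y_pure <- mixture_catalog(SIGS, c(SBS5 = 1000))
  x <- fit_exposures(y_pure, SIGS)
  expect_equal(unname(x["SBS5"]), 1000, tolerance = 1e-6)
  expect_lt(sum(x[setdiff(names(x), "SBS5")]), 1e-6 * 1000)
  expect_equal(sum(x), 1000, tolerance = 1e-8)

  # oracle: exhaustive grid search over 2-signature mixtures, 0.1% steps
  y_mix <- mixture_catalog(SIGS, c(SBS2 = 600, SBS13 = 400))
  grid <- seq(0, 1, by = 0.001)
  resid <- vapply(grid, function(w) {
    fit <- 1000 * (w * SIGS[, "SBS2"] + (1 - w) * SIGS[, "SBS13"])
    sum((y_mix - fit)^2)
  }, numeric(1))
  w_star <- grid[which.min(resid)]
  x2 <- fit_exposures(y_mix, SIGS[, c("SBS2", "SBS13")])
  expect_equal(unname(x2["SBS2"]) / 1000, w_star, tolerance = 0.001)
  x_full <- fit_exposures(y_mix, SIGS)
  expect_equal(unname(x_full["SBS2"]), 600, tolerance = 0.01 * 600)
  expect_equal(unname(x_full["SBS13"]), 400, tolerance = 0.01 * 400)

  expect_error(fit_exposures(numeric(96), SIGS), "zero")
  expect_error(fit_exposures(numeric(10), SIGS), "match")
})

test_that("NNLS residual is reported via reconstruction cosine < 1", {
  # a catalog concentrated off every signature's support
  y <- stats::setNames(numeric(96), sbs_classes(96))
  support <- which(apply(SIGS, 1, max) < 1e-3)
  y[support[1:3]] <- c(50, 30, 20)
  fit <- suppressWarnings(censored_fit(y, SIGS))
  expect_lt(fit$cosine, 1)
})

test_that("censored_fit protects clock signatures and censors inactive ones", {
  y <- mixture_catalog(SIGS, c(SBS1 = 5000))
  fit <- censored_fit(y, SIGS)
  expect_true(all(c("SBS1", "SBS5") %in% fit$retained))
  expect_equal(sort(union(fit$retained, fit$censored)),
               sort(colnames(SIGS)))
  expect_setequal(fit$censored, setdiff(colnames(SIGS), c("SBS1", "SBS5")))
  expect_lt(fit$exposures[["SBS5"]], 0.01 * 5000)

  expect_error(censored_fit(y, SIGS, threshold = 0), "threshold")
  expect_warning(censored_fit(mixture_catalog(SIGS, c(SBS1 = 20)), SIGS),
                 "low-confidence")
})

test_that("censored_fit recovers a 70/30 two-signature catalog", {
  y <- sample_catalog(SIGS, c(SBS5 = 0.7, SBS2 = 0.3), 5000, seed = 7)
  fit <- censored_fit(y, SIGS)
  expect_true("SBS2" %in% fit$retained)
  expect_setequal(fit$censored,
                  setdiff(colnames(SIGS), c("SBS1", "SBS2", "SBS5")))
  # oracle: refit on the true signature set
  oracle <- fit_exposures(y, SIGS[, c("SBS1", "SBS2", "SBS5")])
  expect_equal(unname(fit$exposures["SBS2"]), unname(oracle["SBS2"]),
               tolerance = 0.03 * 5000)
  expect_equal(unname(fit$exposures["SBS2"]) / 5000, 0.3,
               tolerance = 0.03)
  expect_equal(unname(fit$exposures["SBS5"]) / 5000, 0.7,
               tolerance = 0.03)
})

test_that("censoring never drops protected signatures (property)", {
  for (s in 1:20) {
    k <- sample(2:5, 1)
    active <- sample(colnames(SIGS), k)
    fr <- stats::setNames(as.numeric(stats::rmultinom(1, 100, rep(1, k))) / 100,
                          active)
    fr <- fr[fr > 0]
    y <- sample_catalog(SIGS, fr, 3000, seed = s)
    fit <- suppressWarnings(censored_fit(y, SIGS))
    expect_true(all(c("SBS1", "SBS5") %in% fit$retained))
    # cosine never drops more than threshold per censored signature
    full <- fit_exposures(y, SIGS)
    cos_full <- cosine_similarity(y, SIGS %*% full)
    expect_gte(fit$cosine,
               cos_full - length(fit$censored) * fit$threshold - 1e-9)
  }
})

test_that("bootstrap_exposures is reproducible and concentrates", {
  y <- sample_catalog(SIGS, c(SBS5 = 0.6, SBS13 = 0.4), 3000, seed = 1)
  ci1 <- bootstrap_exposures(y, SIGS, n_boot = 50, seed = 9)
  ci2 <- bootstrap_exposures(y, SIGS, n_boot = 50, seed = 9)
  expect_equal(ci1$lo, ci2$lo)
  expect_equal(ci1$hi, ci2$hi)
  expect_true(all(ci1$lo <= ci1$point + 1e-9))
  expect_true(all(ci1$hi >= ci1$point - 1e-9))
  expect_equal(attr(ci1, "n_boot"), 50)
  expect_error(bootstrap_exposures(y, SIGS, n_boot = 1), "n_boot")

  # a huge pure catalog has a tight CI (multinomial concentration)
  y_big <- sample_catalog(SIGS, c(SBS5 = 1), 1e6, seed = 2)
  ci_big <- bootstrap_exposures(y_big, SIGS, n_boot = 50, seed = 3)
  w <- ci_big$hi - ci_big$lo
  expect_lt(w[ci_big$signature == "SBS5"], 0.01 * 1e6)
})

test_that("strand bias test matches the exact binomial oracle", {
  counts <- data.frame(group = c("a", "b", "c"),
                       n_transcribed = c(50, 90, 0),
                       n_untranscribed = c(50, 10, 5))
  res <- strand_bias_test(counts)
  expect_equal(res$rate_ratio[1], 1.0)
  expect_equal(res$p_value[1], 1.0)
  # oracle: two-sided exact binomial tail for 90 vs 10
  oracle_p <- 2 * stats::pbinom(10, 100, 0.5)
  expect_equal(res$p_value[2], oracle_p, tolerance = 1e-10)
  expect_lt(res$p_value[2], 1e-15)
  expect_equal(res$rate_ratio[3], 0)
  expect_true(res$boundary[3])
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
  expect_warning(strand_bias_test(
    data.frame(group = "z", n_transcribed = 0, n_untranscribed = 0)),
    "skipped")
})

test_that("assign_to_reference identifies singles, pairs and novelty", {
  a1 <- assign_to_reference(SIGS[, "SBS1"], SIGS)
  expect_equal(a1$chosen, "single")
  expect_equal(a1$single$name, "SBS1")
  expect_equal(a1$single$cosine, 1.0, tolerance = 1e-9)
  expect_gte(a1$pair$cosine, a1$single$cosine - 1e-9)

  mix <- 0.5 * SIGS[, "SBS2"] + 0.5 * SIGS[, "SBS13"]
  a2 <- assign_to_reference(mix, SIGS)
  expect_equal(a2$chosen, "pair")
  expect_setequal(a2$pair$names, c("SBS2", "SBS13"))
  # oracle: grid search over pair weights at 0.5% steps
  grid <- seq(0, 1, by = 0.005)
  cosg <- vapply(grid, function(w) {
    cosine_similarity(mix, w * SIGS[, "SBS2"] + (1 - w) * SIGS[, "SBS13"])
  }, numeric(1))
  w_star <- grid[which.max(cosg)]
  w_sbs2 <- a2$pair$weights[match("SBS2", a2$pair$names)]
  expect_equal(w_sbs2, w_star, tolerance = 0.05)
  expect_equal(w_sbs2, 0.5, tolerance = 0.05)
  expect_equal(sum(a2$pair$weights), 1, tolerance = 1e-9)

  set.seed(5)
  noise <- stats::runif(96)
  # oracle precondition for novelty: nothing in the reference comes close
  expect_lt(max(apply(SIGS, 2, cosine_similarity, u = noise)), 0.9)
  a3 <- assign_to_reference(noise, SIGS)
  expect_equal(a3$chosen, "novel")
})

test_that("binned_fit reproduces the global fit for a single bin", {
  set.seed(21)
  cls <- sample(rownames(SIGS), 400, replace = TRUE,
                prob = as.numeric(SIGS %*% c(0.6, 0, 0.4, 0, 0, 0, 0, 0, 0)))
  rec <- records_from_classes(cls, pos = sample.int(9e5, 400))
  out <- suppressWarnings(binned_fit(rec, SIGS, bin_size = 1e6))
  expect_equal(nrow(out), 1)
  global <- suppressWarnings(censored_fit(build_catalog(rec), SIGS))
  expect_equal(unname(unlist(out[1, colnames(SIGS)])),
               unname(global$exposures))
  expect_error(binned_fit(rec, SIGS, bin_size = 0), "bin_size")

  # under-filled bins are flagged out
  rec2 <- rec
  rec2$pos <- rec2$pos + rep(c(0, 5e6), length.out = 400) *
    (seq_len(400) %% 40 == 0)
  out2 <- suppressWarnings(binned_fit(rec2, SIGS, bin_size = 1e6))
  expect_true(any(!out2$fitted))
  expect_true(all(rowSums(out2[!out2$fitted, colnames(SIGS)]) == 0))
})

test_that("binned_fit correlates exposures with a matched feature track", {
  # plant an SBS5 density gradient across 50 bins
  set.seed(31)
  n_bins <- 50
  lam <- seq(60, 260, length.out = n_bins)
  recs <- list()
  for (b in seq_len(n_bins)) {
    n <- stats::rpois(1, lam[b])
    cls <- sample(rownames(SIGS), n, replace = TRUE, prob = SIGS[, "SBS5"])
    recs[[b]] <- records_from_classes(
      cls, pos = sort(sample.int(1e6, n)) + (b - 1L) * 1e6)
  }
  rec <- do.call(rbind, recs)
  out <- suppressWarnings(binned_fit(rec, SIGS, bin_size = 1e6,
                                     feature = lam[seq_len(n_bins)]))
  r <- attr(out, "feature_cor")[["SBS5"]]
  # oracle: correlation of the true per-bin counts with the track
  truth_cor <- stats::cor(as.numeric(table(floor((rec$pos - 1) / 1e6))), lam)
  expect_gt(r, 0.8)
  expect_gt(truth_cor, 0.8)
})
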