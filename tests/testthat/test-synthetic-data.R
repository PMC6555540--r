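test_that("noiseless GIM cross follows the two-component growth mixture", {
  bt <- small_cross(noise_cv = 0)
  cfg <- attr(bt, "config")
  # oracle: recompute the spore-fraction and abundance chain by hand
  p <- ifelse(bt$chrom == cfg$suppressor_locus$chrom,
              haldane_recomb(abs(bt$pos - cfg$suppressor_locus$pos) / 1000 *
                               attr(cfg$genome, "cm_per_kb")),
              0.5)
  a <- p * 2^(cfg$competition_time / cfg$tau_suppressed) +
    (1 - p) * 2^(cfg$competition_time / cfg$tau_unsuppressed)
  ratio_obs <- bt$intensity_query / bt$intensity_query[1]
  expect_equal(ratio_obs, a / a[1], tolerance = 1e-12)
  # control channel carries no fitness differential
  expect_true(all(bt$intensity_control == bt$intensity_control[1]))
})

test_that("linked barcodes are depleted, unlinked are not", {
  bt <- small_cross(noise_cv = 0)
  cfg <- attr(bt, "config")
  ratio <- bt$intensity_query / bt$intensity_control
  on_chr <- bt$chrom == cfg$suppressor_locus$chrom
  d <- abs(bt$pos - cfg$suppressor_locus$pos)
  nearest <- which(on_chr & d == min(d[on_chr]))[1]
  expect_true(all(ratio[nearest] < ratio[!on_chr]))
  # ratio increases monotonically with genetic distance from the locus
  side <- which(on_chr & bt$pos >= cfg$suppressor_locus$pos)
  expect_true(all(diff(ratio[side]) >= -1e-12))
})

test_that("no selection differential means flat query/control ratio", {
  bt <- small_cross(noise_cv = 0, tau_suppressed = 150,
                    tau_unsuppressed = 150)
  ratio <- bt$intensity_query / bt$intensity_control
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-12)
})

test_that("query-locus marker linkage depletes its own chromosome", {
  bt0 <- small_cross(noise_cv = 0)
  bt1 <- small_cross(noise_cv = 0,
                     query_locus = list(chrom = "chrA", pos = 4e5))
  on_a <- bt1$chrom == "chrA"
  # depletion factor is 2 * r(distance to marker), < 1 near the marker
  r <- bt1$intensity_query[on_a] / bt0$intensity_query[on_a]
  d <- abs(bt1$pos[on_a] - 4e5)
  expect_lt(r[which.min(d)], 0.1)
  expect_true(all(diff(r[order(d)]) >= -1e-12))
})

test_that("generators are reproducible by seed and vary across seeds", {
  b1 <- small_cross(noise_cv = 0.2, seed = 11)
  b2 <- small_cross(noise_cv = 0.2, seed = 11)
  b3 <- small_cross(noise_cv = 0.2, seed = 12)
  expect_identical(b1, b2)
  expect_false(identical(b1$intensity_query, b3$intensity_query))

  g1 <- simulate_growth_curve(135, 0:9 * 60, 0.05, seed = 4)
  g2 <- simulate_growth_curve(135, 0:9 * 60, 0.05, seed = 4)
  expect_identical(g1, g2)

  s1 <- simulate_spread_counts(21, 50, seed = 5)
  s2 <- simulate_spread_counts(21, 50, seed = 5)
  s3 <- simulate_spread_counts(21, 50, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("growth-curve generator is exact without noise", {
  gc <- simulate_growth_curve(102, c(0, 102, 204, 306), noise_cv = 0)
  expect_equal(gc$od / gc$od[1], c(1, 2, 4, 8), tolerance = 1e-12)
  gc2 <- simulate_growth_curve(180, c(0, 90, 180, 270), noise_cv = 0)
  expect_equal(gc2$od[2] / gc2$od[1], 2^0.5, tolerance = 1e-12)
  expect_error(simulate_growth_curve(-10, 0:5), "tau")
  expect_error(simulate_growth_curve(100, c(0, 10, 5, 20)), "increasing")
})

test_that("spread-count generator hits its mean and Poisson limit", {
  sc <- simulate_spread_counts(91, 10000, dispersion = Inf, seed = 8)
  se <- sqrt(91 / 10000)
  expect_lt(abs(mean(sc$counts) - 91), 3 * se)
  sc2 <- simulate_spread_counts(21, 20000, dispersion = Inf, seed = 9)
  expect_equal(var(sc2$counts) / mean(sc2$counts), 1, tolerance = 0.05)
  # overdispersed draws have variance above the mean
  sc3 <- simulate_spread_counts(21, 20000, dispersion = 2, seed = 9)
  expect_gt(var(sc3$counts), 2 * mean(sc3$counts))
  expect_length(simulate_spread_counts(5, 1, seed = 1)$counts, 1)
  expect_true(all(simulate_spread_counts(5, 1, seed = 1)$counts >= 0))
  expect_error(simulate_spread_counts(0, 10), "mean_count")
  expect_error(simulate_spread_counts(5, 10, dispersion = -1), "dispersion")
})

test_that("signal-table generator encodes folds and loading correctly", {
  folds <- expand.grid(strain = c("WT", "M"), probe = c("18S.2", "5S"),
                       stringsAsFactors = FALSE)
  folds$fold <- ifelse(folds$strain == "M" & folds$probe == "18S.2", 3, 1)
  st <- simulate_signal_table(folds, "5S", "WT", n_replicates = 3,
                              noise_cv = 0, loading_cv = 0.5, seed = 2)
  fc <- fold_change(normalize_to_control(st), reference_strain = "WT",
                    n_boot = 50, seed = 2)
  expect_equal(fc$fold[fc$strain == "M" & fc$probe == "18S.2"], 3,
               tolerance = 1e-12)
  expect_equal(fc$fold[fc$strain == "M" & fc$probe == "5S"], 1,
               tolerance = 1e-12)

  # all folds 1 -> all normalized ratios 1
  folds$fold <- 1
  st1 <- simulate_signal_table(folds, "5S", "WT", noise_cv = 0, seed = 3)
  ns1 <- normalize_to_control(st1)
  fc1 <- fold_change(ns1, "WT", n_boot = 50, seed = 3)
  expect_true(all(abs(fc1$fold - 1) < 1e-12))

  # replicate loading multiplier cancels by construction
  st2 <- st1
  one_rep <- st2$strain == "M" & st2$replicate == 2
  st2$signal[one_rep] <- st2$signal[one_rep] * 2.7
  expect_equal(normalize_to_control(st2)$normalized, ns1$normalized,
               tolerance = 1e-12)

  expect_error(simulate_signal_table(folds, "PGK1", "WT"), "control probe")
  folds_bad <- folds
  folds_bad$fold[folds_bad$strain == "WT" & folds_bad$probe == "18S.2"] <- 2
  expect_error(simulate_signal_table(folds_bad, "5S", "WT"), "reference")
})

test_that("fluctuation generator matches its binomial expectations", {
  fl <- simulate_fluctuation(5e-6, 1e8, uv_fold = 10,
                             survival_fraction = 0.5, seed = 10)
  # expected UV colonies 1e8 * 0.5 * 5e-5 = 2500, binomial sd = 50
  expect_lt(abs(fl$uv$suppressor_colonies - 2500), 4 * sqrt(2500))
  expect_lt(abs(fl$spontaneous$suppressor_colonies - 500), 4 * sqrt(500))
  # uv_fold = 1: equal expected frequencies
  f0 <- estimate_frequency(simulate_fluctuation(1e-4, 1e7, uv_fold = 1,
                                                seed = 3)$uv)
  expect_equal(f0$frequency, 1e-4, tolerance = 0.2)
  # degenerate zero frequency
  fz <- simulate_fluctuation(0, 1e4, seed = 1)
  expect_equal(fz$spontaneous$suppressor_colonies, 0)
  expect_equal(fz$uv$suppressor_colonies, 0)
  expect_error(simulate_fluctuation(0.2, 1e6, uv_fold = 10), "uv_fold")
})
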