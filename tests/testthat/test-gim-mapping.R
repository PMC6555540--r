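make_table <- function(q, ctrl) {
  n <- length(q)
  out <- data.frame(barcode_id = paste0("b", seq_len(n)),
                    gene = paste0("g", seq_len(n)),
                    chrom = "c1", pos = seq_len(n) * 1000,
                    intensity_query = q, intensity_control = ctrl,
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_table", "data.frame")
  out
}

test_that("median normalization scales, pseudocounts, and is scale-free", {
  tb <- make_table(c(10, 50, 100, 90), c(50, 50, 50, 50))
  nt <- normalize_arrays(tb)
  expect_equal(median(nt$intensity_query), 1)
  expect_equal(nt$intensity_control, rep(1, 4))

  # global rescaling of a channel leaves the output unchanged
  tb7 <- tb
  tb7$intensity_query <- tb7$intensity_query * 7
  tb7$intensity_control <- tb7$intensity_control * 7
  expect_equal(normalize_arrays(tb7), normalize_arrays(tb))

  # zero replaced by half the smallest positive value before scaling
  tbz <- make_table(c(1, 2, 3, 0), c(1, 1, 1, 1))
  ntz <- normalize_arrays(tbz)
  expected <- c(1, 2, 3, 0.5) / median(c(1, 2, 3, 0.5))
  expect_equal(ntz$intensity_query, expected)

  expect_error(normalize_arrays(make_table(rep(0, 4), rep(1, 4))),
               "all zero")
})

test_that("scores are log2(control/query), high for counter-selection", {
  tb <- make_table(c(1, 5, 7), c(4, 5, 3))
  sc <- compute_scores(tb)
  expect_equal(sc$score, c(2, 0, log2(3 / 7)), tolerance = 1e-12)
  expect_error(compute_scores(make_table(c(0, 1, 1), c(1, 1, 1))),
               "non-positive")
})

test_that("channel swap negates scores and flips maxima to minima", {
  bt <- small_cross(noise_cv = 0.1, seed = 21)
  swapped <- bt
  swapped$intensity_query <- bt$intensity_control
  swapped$intensity_control <- bt$intensity_query
  s1 <- compute_scores(normalize_arrays(bt))
  s2 <- compute_scores(normalize_arrays(swapped))
  expect_equal(s2$score, -s1$score, tolerance = 1e-12)
  p1 <- sliding_window_profile(s1, W = 20)
  p2 <- sliding_window_profile(s2, W = 20)
  expect_equal(which.max(p1$score), which.min(p2$score))
})

test_that("sliding windows match hand-computed cases", {
  sc <- data.frame(barcode_id = paste0("b", 1:4), gene = paste0("g", 1:4),
                   chrom = "c1", pos = c(10, 20, 30, 40),
                   score = c(1, 2, 3, 4))
  pf <- sliding_window_profile(sc, W = 2)
  expect_equal(pf$score, c(1.5, 2.5, 3.5))
  expect_equal(pf$center, c(15, 25, 35))  # even W: mean of middle pair

  # constant scores give constant windows
  sc$score <- rep(7, 4)
  expect_equal(sliding_window_profile(sc, W = 3)$score, c(7, 7))

  # W = n gives one window equal to the chromosome mean
  sc$score <- c(1, 2, 3, 10)
  pf1 <- sliding_window_profile(sc, W = 4)
  expect_equal(nrow(pf1), 1)
  expect_equal(pf1$score, 4)

  # chromosome shorter than W yields no windows plus a warning
  expect_warning(pf0 <- sliding_window_profile(sc, W = 5), "skipped")
  expect_equal(nrow(pf0), 0)
})

test_that("sliding windows agree with a brute-force double loop", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(60:500, 1)
      W <- sample(2:50, 1)
      sc <- random_scored(n)
      got <- suppressWarnings(sliding_window_profile(sc, W = W))
      want <- brute_force_profile(sc, W)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$chrom, want$chrom)
        expect_equal(got$center, want$center)
        expect_equal(got$score, want$score, tolerance = 1e-12)
      }
    }
  })
})

test_that("an injected suppressor peak is called at the right place", {
  bt <- small_cross(n_barcodes = 300, noise_cv = 0,
                    sup = list(chrom = "chrB", pos = 4e5))
  res <- map_suppressor(bt, W = 20, n_perm = 100, seed = 5)
  top <- res$calls[1, ]
  expect_equal(top$chrom, "chrB")
  # within half a window span of the true locus
  spacing <- 8e5 / (sum(bt$chrom == "chrB") + 1)
  expect_lt(abs(top$peak_pos - 4e5), spacing * 20 / 2)
  expect_match(res$calls$candidate_genes[1], ",")
  expect_true(all(res$calls$p_value > 0 & res$calls$p_value <= 1))
})

test_that("flat scores produce no calls and empty profiles are handled", {
  tb <- make_table(rep(2, 50), rep(2, 50))
  res <- map_suppressor(tb, W = 10, n_perm = 100, seed = 1)
  expect_equal(nrow(res$calls), 0)

  pf <- structure(data.frame(chrom = character(0), center = numeric(0),
                             score = numeric(0), start_index = integer(0)),
                  W = 20L, class = c("linkage_profile", "data.frame"))
  sc <- random_scored(10)
  expect_equal(nrow(call_loci(pf, sc, n_perm = 100)), 0)
})

test_that("permutation p-values are invariant to a constant score shift", {
  bt <- small_cross(n_barcodes = 300, noise_cv = 0.2, seed = 31)
  sc <- compute_scores(normalize_arrays(bt))
  pf <- sliding_window_profile(sc, W = 20)
  calls1 <- call_loci(pf, sc, n_perm = 100, seed = 7)
  sc2 <- sc
  sc2$score <- sc2$score + 3.14
  pf2 <- sliding_window_profile(sc2, W = 20)
  calls2 <- call_loci(pf2, sc2, n_perm = 100, seed = 7)
  expect_equal(calls2$p_value, calls1$p_value)
  expect_equal(calls2$chrom, calls1$chrom)
})
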