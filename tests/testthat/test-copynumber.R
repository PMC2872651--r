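test_that("fragment-size filter applies the <= rule, is idempotent and monotone", {
  prof <- make_profile(3, fragment_length = c(300, 600, 601))
  out <- suppressMessages(filter_by_fragment_size(prof, 600))
  expect_equal(nrow(out), 2)
  expect_true(all(out$fragment_length <= 600))

  # max 0 disables the filter entirely
  expect_identical(as.data.frame(suppressMessages(filter_by_fragment_size(prof, 0))),
                   as.data.frame(prof))
  empty <- prof[0, ]
  expect_equal(nrow(suppressMessages(filter_by_fragment_size(empty, 600))), 0)

  # idempotence and monotonicity in the threshold
  set.seed(1)
  prof2 <- make_profile(50, fragment_length = sample(100:1200, 50, TRUE))
  f600 <- suppressMessages(filter_by_fragment_size(prof2, 600))
  expect_identical(as.data.frame(suppressMessages(filter_by_fragment_size(f600, 600))),
                   as.data.frame(f600))
  f900 <- suppressMessages(filter_by_fragment_size(prof2, 900))
  expect_true(all(f600$probe_id %in% f900$probe_id))
  expect_error(filter_by_fragment_size(prof2, -1), ">= 0")
})

test_that("log2 ratios are median-centered over autosomes with raw_cn = 2*2^r", {
  # identical intensities: all zero, copy number 2
  prof <- make_profile(5)
  tr <- compute_log2_ratios(prof)
  expect_equal(tr$log2_ratio, rep(0, 5))
  expect_equal(tr$raw_cn, rep(2, 5))
  expect_true(all(is.na(tr$smoothed_log2)))

  # a global doubling is normalized away
  prof2 <- make_profile(5, tumor_intensity = rep(2000, 5))
  expect_equal(compute_log2_ratios(prof2)$log2_ratio, rep(0, 5))

  # pre-centering ratios {-1, 0, +1}: median 0, so unchanged; cn {1, 2, 4}
  prof3 <- make_profile(3, tumor_intensity = c(500, 1000, 2000))
  tr3 <- compute_log2_ratios(prof3)
  expect_equal(tr3$log2_ratio, c(-1, 0, 1))
  expect_equal(tr3$raw_cn, c(1, 2, 4))
  expect_equal(attr(tr3, "normalization_offset"), 0)

  # sex chromosomes are excluded from the median but still centered
  prof4 <- make_profile(5, chromosome = c("1", "1", "1", "X", "X"),
                        tumor_intensity = c(1000, 1000, 1000, 500, 500))
  tr4 <- compute_log2_ratios(prof4)
  expect_equal(tr4$log2_ratio[tr4$chromosome == "1"], rep(0, 3))
  expect_equal(tr4$log2_ratio[tr4$chromosome == "X"], rep(-1, 2))

  bad <- make_profile(2)
  bad$tumor_intensity[2] <- 0
  expect_error(compute_log2_ratios(bad), "P002")
})

test_that("Gaussian smoothing is an exact weighted mean with no cross-chromosome leakage", {
  # constant track: smoothing is the identity
  tr <- make_track(rep(0.4, 20), position = seq_len(20) * 50000)
  sm <- gaussian_smooth(tr, smoothing_kernel(500000))
  expect_equal(sm$smoothed_log2, rep(0.4, 20))
  expect_equal(sm$smoothed_cn, 2 * 2^0.4 + numeric(20))

  # single-SNP chromosome: smoothed equals raw
  tr1 <- make_track(c(0.9), chromosome = "5", position = 123456)
  expect_equal(gaussian_smooth(tr1)$smoothed_log2, 0.9)

  # 3 SNPs at 1, 100001, 200001 with values {0, 1, 0}, sigma = 125 kb:
  # middle value is the hand-computed normalized weighted sum
  w <- exp(-(1e5)^2 / (2 * 125000^2))
  tr3 <- make_track(c(0, 1, 0), position = c(1, 100001, 200001))
  sm3 <- gaussian_smooth(tr3, smoothing_kernel(500000))
  expect_equal(sm3$smoothed_log2[2], 1 / (1 + 2 * w), tolerance = 1e-12)

  # chromosomes smoothed independently
  tr2 <- make_track(c(1, 1, -1, -1), chromosome = c("1", "1", "2", "2"),
                    position = c(1000, 2000, 1000, 2000))
  sm2 <- gaussian_smooth(tr2, smoothing_kernel(500000))
  expect_equal(sm2$smoothed_log2, c(1, 1, -1, -1))
})

test_that("smoothing is a convex combination and commutes with constant shifts", {
  set.seed(7)
  n <- 200
  tr <- make_track(rnorm(n), position = sort(sample.int(2e7, n)))
  k <- smoothing_kernel(500000)
  sm <- gaussian_smooth(tr, k)$smoothed_log2
  expect_true(all(sm >= min(tr$log2_ratio) - 1e-12))
  expect_true(all(sm <= max(tr$log2_ratio) + 1e-12))

  shifted <- tr
  shifted$log2_ratio <- shifted$log2_ratio + 0.75
  expect_equal(gaussian_smooth(shifted, k)$smoothed_log2, sm + 0.75,
               tolerance = 1e-12)
})

test_that("truncated smoother matches the untruncated O(n^2) oracle when the window covers the span", {
  set.seed(8)
  n <- 300
  pos <- sort(sample.int(1e6, n))
  tr <- make_track(rnorm(n), position = pos)
  sigma <- 5e5  # truncation*sigma = 1.5e6 > chromosome span
  sm <- gaussian_smooth(tr, smoothing_kernel(window = 4 * sigma))$smoothed_log2
  expect_equal(sm, smooth_oracle(pos, tr$log2_ratio, sigma), tolerance = 1e-6)
})
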