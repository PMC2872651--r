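test_that("Viterbi decodes dominant-emission and step sequences correctly", {
  p <- cn_hmm_params()
  # all observations at the neutral mean: all-state-2 path
  path <- viterbi_decode(rep(0, 25), seq_len(25) * 1000, p)
  expect_equal(as.vector(path), rep(2L, 25))

  # clean step from 0 to -1 log2 at small gaps
  p2 <- cn_hmm_params(emission_sd = 0.1)
  obs <- c(0, 0, 0, -1, -1, -1)
  pos <- seq_len(6) * 1000
  path2 <- viterbi_decode(obs, pos, p2)
  expect_equal(as.vector(path2), c(2L, 2L, 2L, 1L, 1L, 1L))
  # and the decoded path attains the exhaustive-enumeration maximum
  le <- matrix(gaussian_emissions(obs, p2$state_means, p2$emission_sd),
               ncol = length(p2$states))
  bf <- brute_force_viterbi(le, pos, p2$stay_prob_at_1bp, p2$decay_length,
                            p2$stay_min)
  expect_equal(attr(path2, "log_prob"), bf$log_prob, tolerance = 1e-9)
  expect_equal(match(as.vector(path2), p2$states), bf$path)

  # single observation: most likely emission state
  expect_equal(as.vector(viterbi_decode(-0.9, 500, p)), 1L)
  expect_equal(as.vector(viterbi_decode(5, 500, p)), 4L)
  expect_error(viterbi_decode(numeric(0), numeric(0), p), "empty")
})

test_that("Viterbi equals exhaustive path enumeration on random small instances", {
  set.seed(42)
  for (rep in 1:60) {
    K <- sample(2:3, 1)
    n <- sample(2:10, 1)
    means <- sort(rnorm(K, 0, 1))
    if (any(diff(means) < 0.05)) means <- means + seq(0, by = 0.1, length.out = K)
    sd <- runif(1, 0.1, 0.6)
    pos <- cumsum(c(1, sample.int(5e6, n - 1)))
    obs <- rnorm(n, sample(means, n, TRUE), sd)
    stay1 <- 1 - 10^runif(1, -8, -5)
    params <- cn_hmm_params(states = seq_len(K) - 1, state_means = means,
                            emission_sd = sd, stay_prob_at_1bp = stay1)
    got <- viterbi_decode(obs, pos, params)
    le <- matrix(gaussian_emissions(obs, means, sd), ncol = K)
    bf <- brute_force_viterbi(le, pos, stay1, params$decay_length, params$stay_min)
    expect_equal(attr(got, "log_prob"), bf$log_prob, tolerance = 1e-8)
    if (bf$unique) {
      expect_equal(match(as.vector(got), params$states), bf$path)
    }
  }
})

test_that("copy-number segmentation partitions each chromosome into state runs", {
  # flat zero: one neutral segment covering every SNP
  tr <- make_track(rep(0, 40), position = seq_len(40) * 5e5,
                   smoothed_log2 = rep(0, 40))
  segs <- segment_cn(tr)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, 2L)
  expect_equal(segs$n_snps, 40L)
  expect_equal(segs$start, 5e5)
  expect_equal(segs$end, 40 * 5e5)

  # injected single-copy block recovered within +/- 2 SNPs
  set.seed(9)
  n <- 200
  truth_state <- rep(2L, n); truth_state[81:130] <- 1L
  obs <- rnorm(n, ifelse(truth_state == 2, 0, -1), 0.1)
  tr2 <- make_track(obs, position = seq_len(n) * 1e5, smoothed_log2 = obs)
  segs2 <- segment_cn(tr2)
  expect_equal(segs2$state, c(2L, 1L, 2L))
  expect_lte(abs(segs2$start[2] / 1e5 - 81), 2)
  expect_lte(abs(segs2$end[2] / 1e5 - 130), 2)
  expect_equal(sum(segs2$n_snps), n)

  # two chromosomes segment independently of concatenation order
  tr3 <- make_track(c(rep(0, 10), rep(-1, 10)),
                    chromosome = rep(c("1", "2"), each = 10),
                    position = rep(seq_len(10) * 1e5, 2),
                    smoothed_log2 = c(rep(0, 10), rep(-1, 10)))
  segs3 <- segment_cn(tr3, cn_hmm_params(emission_sd = 0.1))
  expect_equal(nrow(segs3), 2)
  expect_equal(segs3$chromosome, c("1", "2"))
  expect_equal(segs3$state, c(2L, 1L))

  expect_error(segment_cn(make_track(0, smoothed_log2 = NA)), "smoothed")
})

test_that("segmentation is invariant to position offsets and monotone in stickiness", {
  set.seed(10)
  n <- 150
  obs <- rnorm(n, rep(c(0, 0.585, 0), c(60, 40, 50)), 0.25)
  pos <- sort(sample.int(3e7, n))
  tr <- make_track(obs, position = pos, smoothed_log2 = obs)
  segs <- segment_cn(tr)
  tr_off <- tr
  tr_off$position <- tr_off$position + 5e6
  segs_off <- segment_cn(tr_off)
  expect_equal(segs_off$state, segs$state)
  expect_equal(segs_off$start, segs$start + 5e6)

  counts <- sapply(c(0.99, 0.9999, 1 - 1e-6, 1 - 1e-8), function(s) {
    nrow(segment_cn(tr, cn_hmm_params(stay_prob_at_1bp = s)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("LOH segmentation spans informative SNPs and absorbs isolated miscalls", {
  # all retention: one segment per chromosome
  lt <- make_loh_track(rep("retention", 30),
                       chromosome = rep(c("1", "2"), each = 15),
                       position = rep(seq_len(15) * 1e6, 2))
  segs <- segment_loh(lt)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$state, c("retention", "retention"))
  expect_equal(segs$mean_value, c(0, 0))

  # 40 consecutive LOH calls flanked by retention: block recovered within
  # +/- 2 informative SNPs
  set.seed(12)
  calls <- rep("retention", 100)
  calls[31:70] <- "LOH"
  calls[sample(setdiff(1:100, 25:76), 3)] <- "LOH"  # isolated miscalls
  lt2 <- make_loh_track(calls, position = seq_len(100) * 1e6)
  segs2 <- segment_loh(lt2)
  loss <- segs2[segs2$state == "loss", ]
  expect_equal(nrow(loss), 1)
  expect_lte(abs(loss$start / 1e6 - 31), 2)
  expect_lte(abs(loss$end / 1e6 - 70), 2)
  expect_gt(loss$mean_value, 0.9)

  # non-informative SNPs are spanned but not decoded
  calls3 <- c("retention", "non_informative", "retention")
  segs3 <- segment_loh(make_loh_track(calls3))
  expect_equal(segs3$n_snps, 2L)
  expect_equal(segs3$start, 1000)
  expect_equal(segs3$end, 3000)

  # a chromosome with no informative SNPs: low-confidence retention
  segs4 <- segment_loh(make_loh_track(rep("non_informative", 5)))
  expect_equal(segs4$state, "retention")
  expect_true(segs4$low_confidence)
  expect_equal(segs4$n_snps, 0L)
})

test_that("alternating LOH calls decode to retention, matching enumeration", {
  p <- loh_hmm_params()
  is_loh <- rep(c(TRUE, FALSE), 5)
  pos <- seq_len(10) * 1000
  got <- viterbi_decode(is_loh, pos, p)
  expect_equal(as.vector(got), rep("retention", 10))
  bf <- brute_force_viterbi(loh_emissions(is_loh, p$miscall_rate, p$loh_emission),
                            pos, p$stay_prob_at_1bp, p$decay_length, p$stay_min)
  expect_equal(attr(got, "log_prob"), bf$log_prob, tolerance = 1e-9)
})
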