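test_that("segments classify against the three thresholds with a size filter", {
  cfg <- cna_config()
  segs <- make_segments("1",
                        start = c(1e6, 5e6, 9e6, 13e6),
                        end = c(2e6, 6e6, 10e6, 14e6),
                        state = c(3L, 0L, 2L, 0L),
                        n_snps = c(10L, 12L, 15L, 3L),
                        mean_value = c(0.8, -1.8, -0.1, -2))
  regions <- detect_cna_regions(segs, cfg)
  expect_equal(nrow(regions), 2)
  expect_equal(regions$type, c("gain", "homozygous_deletion"))
  # the 3-SNP segment is filtered despite its extreme mean; the neutral one
  # is inside the band
  expect_false(any(regions$n_snps < cfg$min_snps_per_region))

  loss <- detect_cna_regions(make_segments("2", 1e6, 2e6, 1L, 20L, -1.0), cfg)
  expect_equal(loss$type, "loss")

  bad_cfg <- cna_config()
  bad_cfg$gain_threshold <- -0.1
  expect_error(detect_cna_regions(segs, bad_cfg), "invalid configuration")
})

test_that("emitted regions are always consistent with the thresholds that produced them", {
  set.seed(21)
  for (rep in 1:10) {
    cfg <- cna_config(gain_threshold = runif(1, 0.1, 1),
                      loss_threshold = -runif(1, 0.1, 1),
                      homdel_threshold = -runif(1, 1.1, 3))
    segs <- make_segments("3",
                          start = seq(1, by = 2e6, length.out = 12),
                          end = seq(1e6, by = 2e6, length.out = 12),
                          state = rep(2L, 12),
                          n_snps = sample(1:20, 12, TRUE),
                          mean_value = rnorm(12, 0, 1.2))
    regions <- detect_cna_regions(segs, cfg)
    if (!nrow(regions)) next
    expect_true(all(regions$n_snps >= cfg$min_snps_per_region))
    expect_true(all(
      (regions$type == "gain" & regions$mean_log2 >= cfg$gain_threshold) |
      (regions$type == "loss" & regions$mean_log2 <= cfg$loss_threshold &
         regions$mean_log2 > cfg$homdel_threshold) |
      (regions$type == "homozygous_deletion" & regions$mean_log2 <= cfg$homdel_threshold)
    ))
  }
})

test_that("stricter thresholds never yield more regions", {
  set.seed(22)
  segs <- make_segments("5",
                        start = seq(1, by = 2e6, length.out = 30),
                        end = seq(1e6, by = 2e6, length.out = 30),
                        state = rep(2L, 30),
                        n_snps = rep(10L, 30),
                        mean_value = rnorm(30, 0, 0.8))
  scale <- c(1, 1.5, 2, 3, 5)
  counts <- sapply(scale, function(s) {
    nrow(detect_cna_regions(segs, cna_config(gain_threshold = 0.3 * s,
                                             loss_threshold = -0.3 * s,
                                             homdel_threshold = -1.5 * s)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("LOH areas classify as copy-loss-associated or copy-neutral by reciprocal overlap", {
  cfg <- cna_config()
  loss_region <- detect_cna_regions(make_segments("1", 1e6, 2e6, 1L, 20L, -1.0), cfg)

  # exactly coinciding: LOH with full overlap recorded on the CNA region
  loh <- make_segments("1", 1e6, 2e6, "loss", 10L, 0.95)
  out <- classify_loh_regions(loh, loss_region, cfg)
  expect_equal(sort(out$type), c("LOH", "loss"))
  expect_equal(out$loh_overlap_fraction[out$type == "loss"], 1.0)

  # no CNA on the chromosome: copy-neutral LOH
  out2 <- classify_loh_regions(make_segments("6", 1e6, 9e6, "loss", 10L, 0.9),
                               loss_region[0, ], cfg)
  expect_equal(out2$type, "copy_neutral_LOH")

  # 30% coverage of one loss region and nothing else: copy-neutral, and the
  # loss region records fraction 0.3
  loh3 <- make_segments("1", 1e6, 1e6 + 0.3e6 - 1, "loss", 10L, 0.9)
  out3 <- classify_loh_regions(loh3, loss_region, cfg)
  loss_row <- out3[out3$type == "loss", ]
  expect_equal(loss_row$loh_overlap_fraction, 0.3, tolerance = 1e-6)
  expect_true("copy_neutral_LOH" %in% out3$type)

  # retention segments and under-supported LOH runs are never reported
  mixed <- make_segments("2", c(1e6, 5e6), c(2e6, 6e6), c("retention", "loss"),
                         n_snps = c(10L, 3L), mean_value = c(0.1, 1))
  out4 <- classify_loh_regions(mixed, loss_region[0, ], cfg)
  expect_equal(nrow(out4), 0)
})

test_that("region boundaries extend to inter-marker midpoints internally only", {
  segs <- make_segments("1",
                        start = c(1e6, 2.4e6, 4e6),
                        end = c(2e6, 3e6, 5e6),
                        state = c(2L, 1L, 2L),
                        n_snps = c(10L, 10L, 10L),
                        mean_value = c(0, -1, 0))
  regions <- detect_cna_regions(segs, cna_config())
  expect_equal(nrow(regions), 1)
  # internal boundaries move to the gap midpoints; the loss now spans
  # (2e6+2.4e6)/2 + 1 .. (3e6+4e6)/2
  expect_equal(regions$start, 2.2e6 + 1)
  expect_equal(regions$end, 3.5e6)
})

test_that("UCSC URLs follow the documented template", {
  expect_equal(
    make_ucsc_url("1", 1000000, 2000000, "hg18"),
    "http://genome.ucsc.edu/cgi-bin/hgTracks?db=hg18&position=chr1%3A1000000-2000000"
  )
  expect_match(make_ucsc_url("X", 5, 10, "hg18"), "position=chrX%3A5-10", fixed = TRUE)
  # single-SNP region: start == end is still a valid position
  expect_match(make_ucsc_url("7", 123, 123, "hg19"), "db=hg19.*chr7%3A123-123")
  expect_error(make_ucsc_url("1", 1, 2, ""), "non-empty")
})
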