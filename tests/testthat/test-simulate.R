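test_that("simulation is exactly reproducible from the seed and sensitive to it", {
  s1 <- small_sim(seed = 4, n_snps = 300)
  s2 <- small_sim(seed = 4, n_snps = 300)
  expect_identical(as.data.frame(s1$profile), as.data.frame(s2$profile))
  s3 <- small_sim(seed = 5, n_snps = 300)
  expect_false(identical(s1$profile$tumor_intensity, s3$profile$tumor_intensity))
})

test_that("zero noise reproduces the truth log2 ratios exactly", {
  spec <- simulation_spec(
    chrom_info = data.frame(chromosome = "1", length = 1e8,
                            stringsAsFactors = FALSE),
    n_snps = 200, noise_sd = 0, genotype_error = 0, nocall_rate = 0,
    truth = data.frame(chromosome = "1", start = 2e7, end = 6e7,
                       event = "loss", stringsAsFactors = FALSE),
    seed = 3
  )
  sim <- simulate_paired_sample(spec)
  prof <- sim$profile
  expect_true(all(prof$reference_intensity == 1000))
  r <- log2(prof$tumor_intensity / prof$reference_intensity)
  inside <- prof$position >= 2e7 & prof$position <= 6e7
  expect_equal(r[inside], rep(-1, sum(inside)), tolerance = 1e-12)
  expect_equal(r[!inside], rep(0, sum(!inside)), tolerance = 1e-12)
  # loss regions force heterozygous germline SNPs homozygous in the tumor
  het_in <- inside & prof$reference_call == "AB"
  expect_true(all(prof$tumor_call[het_in] %in% c("AA", "BB")))
  het_out <- !inside & prof$reference_call == "AB"
  expect_true(all(prof$tumor_call[het_out] == "AB"))
})

test_that("noise, heterozygosity and dropout rates match their parameters statistically", {
  spec <- simulation_spec(
    chrom_info = data.frame(chromosome = "1", length = 2e8,
                            stringsAsFactors = FALSE),
    n_snps = 5000, seed = 6
  )
  sim <- simulate_paired_sample(spec)
  prof <- sim$profile
  n <- nrow(prof)
  r <- log2(prof$tumor_intensity / 1000)
  # flat truth: mean ~ 0, sd ~ noise_sd (0.25), 4-sigma-of-the-estimate bands
  expect_lt(abs(mean(r)), 4 * spec$noise_sd / sqrt(n))
  expect_lt(abs(sd(r) - spec$noise_sd), 0.02)
  # reference heterozygosity ~ het_fraction * (1 - nocall_rate)
  p_het <- spec$het_fraction * (1 - spec$nocall_rate)
  expect_lt(abs(mean(prof$reference_call == "AB") - p_het), 0.03)
  expect_lt(abs(mean(prof$tumor_call == "NoCall") - spec$nocall_rate), 0.01)
  # fragment lengths span the uniform range
  expect_true(all(prof$fragment_length >= 100 & prof$fragment_length <= 1200))
  expect_gt(mean(prof$fragment_length > 600), 0.45)
  # marker density is proportional to chromosome length
  spec2 <- simulation_spec(
    chrom_info = data.frame(chromosome = c("1", "2"), length = c(2e8, 1e8),
                            stringsAsFactors = FALSE),
    n_snps = 3000, seed = 6
  )
  prof2 <- simulate_paired_sample(spec2)$profile
  expect_equal(sum(prof2$chromosome == "1"), 2000)
  expect_equal(sum(prof2$chromosome == "2"), 1000)
})

test_that("spec validation rejects bad probabilities, events and overlapping truth", {
  expect_error(simulation_spec(het_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_spec(noise_sd = -0.1), ">= 0")
  expect_error(
    simulation_spec(truth = data.frame(chromosome = "1", start = 1, end = 10,
                                       event = "duplication",
                                       stringsAsFactors = FALSE)),
    "unknown truth event"
  )
  expect_error(
    simulation_spec(truth = data.frame(chromosome = "1",
                                       start = c(1, 5e6), end = c(1e7, 6e6),
                                       event = c("loss", "gain3"),
                                       stringsAsFactors = FALSE)),
    "overlap"
  )
  expect_error(simulate_paired_sample(list()), "simulation_spec")
})

test_that("archetype specs carry distinguishable, in-bounds truth tables", {
  oligo <- archetype_spec("oligodendroglioma", seed = 2)
  gbm <- archetype_spec("glioblastoma", seed = 2)
  genome <- hg18_chromosomes("autosomes")
  for (spec in list(oligo, gbm)) {
    tr <- spec$truth
    lens <- genome$length[match(tr$chromosome, genome$chromosome)]
    expect_true(all(tr$start >= 1 & tr$end <= lens))
    expect_true(all(tr$event %in% c("gain3", "gain4", "loss", "homdel", "cnloh")))
  }
  # the diagnostic 1p/19q loss pair separates the two archetypes
  has_1p19q <- function(tr) {
    any(tr$chromosome == "1" & tr$event == "loss") &&
      any(tr$chromosome == "19" & tr$event == "loss")
  }
  expect_true(has_1p19q(oligo$truth))
  expect_false(has_1p19q(gbm$truth))
  expect_true(any(gbm$truth$event == "homdel"))
  expect_error(archetype_spec("astrocytoma"), "unknown archetype")
})

test_that("written sample tables round-trip through the paired reader", {
  sim <- small_sim(seed = 13, n_snps = 80)
  dir <- tempfile()
  paths <- write_sample_tables(sim, dir, prefix = "rt")
  expect_true(all(file.exists(paths)))
  truth_back <- read.delim(paths["truth"])
  expect_equal(nrow(truth_back), nrow(sim$truth))
  expect_equal(truth_back$event, sim$truth$event)
  prof <- suppressMessages(read_paired_snp_tables(paths["tumor"], paths["reference"]))
  expect_equal(nrow(prof), nrow(sim$profile))
})
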