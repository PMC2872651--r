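# In-code fixtures shared across the suite.

# Quick paired-profile builder with sensible defaults.
make_profile <- function(n = 3,
                         chromosome = rep("1", n),
                         position = seq_len(n) * 1000,
                         fragment_length = rep(300, n),
                         tumor_intensity = rep(1000, n),
                         reference_intensity = rep(1000, n),
                         tumor_call = rep("AB", n),
                         reference_call = rep("AB", n),
                         probe_id = sprintf("P%03d", seq_len(n)),
                         genome_build = "hg18") {
  snp_profile(data.frame(
    probe_id = probe_id, chromosome = chromosome, position = position,
    fragment_length = fragment_length, tumor_intensity = tumor_intensity,
    reference_intensity = reference_intensity, tumor_call = tumor_call,
    reference_call = reference_call, stringsAsFactors = FALSE
  ), genome_build = genome_build)
}

# cn_track with log2 values at 6-decimal precision and copy-number columns
# derived exactly from them (the CNT writer's serialized precision).
make_track <- function(log2_ratio,
                       chromosome = rep("1", length(log2_ratio)),
                       position = seq_along(log2_ratio) * 1000,
                       smoothed_log2 = log2_ratio,
                       probe_id = sprintf("P%03d", seq_along(log2_ratio)),
                       loh_call = NULL,
                       genome_build = "hg18") {
  log2_ratio <- round(log2_ratio, 6)
  smoothed_log2 <- round(smoothed_log2, 6)
  track <- data.frame(
    probe_id = probe_id, chromosome = chromosome, position = position,
    log2_ratio = log2_ratio, raw_cn = 2 * 2^log2_ratio,
    smoothed_log2 = smoothed_log2, smoothed_cn = 2 * 2^smoothed_log2,
    stringsAsFactors = FALSE
  )
  if (!is.null(loh_call)) track$loh_call <- loh_call
  structure(track, genome_build = genome_build,
            class = c("cn_track", "data.frame"))
}

make_loh_track <- function(call,
                           chromosome = rep("1", length(call)),
                           position = seq_along(call) * 1000) {
  structure(data.frame(
    probe_id = sprintf("P%03d", seq_along(call)),
    chromosome = chromosome, position = position, call = call,
    stringsAsFactors = FALSE
  ), class = c("loh_track", "data.frame"))
}

make_segments <- function(chromosome, start, end, state,
                          n_snps = rep(10L, length(start)),
                          mean_value = rep(0.5, length(start))) {
  data.frame(chromosome = chromosome, start = start, end = end, state = state,
             n_snps = n_snps, mean_value = mean_value, stringsAsFactors = FALSE)
}

write_profile_tsv <- function(profile, path = tempfile(fileext = ".tsv")) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

# A small two-chromosome simulated sample with one loss and one gain, used
# by report and pipeline tests. Chromosome lengths are shrunk so the run is
# desk-fast.
small_sim <- function(seed = 11, n_snps = 700) {
  spec <- simulation_spec(
    chrom_info = data.frame(chromosome = c("1", "2"),
                            length = c(1e8, 1e8), stringsAsFactors = FALSE),
    n_snps = n_snps,
    truth = data.frame(chromosome = c("1", "2"),
                       start = c(2e7, 5e7), end = c(6e7, 9e7),
                       event = c("loss", "gain3"), stringsAsFactors = FALSE),
    seed = seed
  )
  simulate_paired_sample(spec)
}

small_fit <- function(seed = 11, ...) {
  sim <- small_sim(seed = seed)
  suppressMessages(cna_profile(sim$profile, sample_id = "small-sim", ...))
}

# Full text of an (uncompressed) PDF with the few non-ASCII header bytes
# blanked, so fixed-string matching works in any locale.
read_pdf_text <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  raw[raw > as.raw(127L)] <- as.raw(32L)
  rawToChar(raw)
}

# How well a detected region set recovers a truth table: per truth region,
# the best reciprocal overlap among same-type regions on its chromosome.
truth_recovery <- function(truth, regions) {
  type_map <- c(gain3 = "gain", gain4 = "gain", loss = "loss",
                homdel = "homozygous_deletion", cnloh = "copy_neutral_LOH")
  vapply(seq_len(nrow(truth)), function(i) {
    cand <- regions[regions$chromosome == truth$chromosome[i] &
                      regions$type == type_map[[truth$event[i]]], , drop = FALSE]
    if (!nrow(cand)) return(0)
    ov <- pmax(0, pmin(cand$end, truth$end[i]) - pmax(cand$start, truth$start[i]) + 1)
    max(pmin(ov / (cand$end - cand$start + 1),
             ov / (truth$end[i] - truth$start[i] + 1)))
  }, numeric(1))
}
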