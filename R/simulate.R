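TRUTH_EVENTS <- c("gain3", "gain4", "loss", "homdel", "cnloh")

# Expected tumor/reference log2 ratio per event; homozygous deletions are
# floored at -3 (log2(0/2) is unbounded), matching the copy-number HMM's
# state-0 mean. Copy-neutral LOH leaves the ratio at 0.
.event_log2 <- c(gain3 = log2(3 / 2), gain4 = 1, loss = -1, homdel = -3, cnloh = 0)
.event_cn <- c(gain3 = 3, gain4 = 4, loss = 1, homdel = 0, cnloh = 2)
# Events that turn heterozygous germline SNPs homozygous in the tumor.
.loh_events <- c("loss", "homdel", "cnloh")

#' Specification of a simulated paired sample
#'
#' Describes the genome layout, marker density, noise model and injected
#' ground-truth alterations of a simulated tumor/germline pair. Defaults
#' emulate a degraded-DNA paired genotyping experiment at a scaled ~10k-SNP
#' genome-wide density.
#'
#' @param chrom_info Data frame with columns `chromosome`, `length` (bp);
#'   default the schematic hg18 autosomes ([hg18_chromosomes()]).
#' @param n_snps Total SNP count, distributed over chromosomes in
#'   proportion to length. Default 10000.
#' @param noise_sd SD of the Gaussian log2-ratio noise. Default 0.25.
#' @param het_fraction Probability that a reference SNP is heterozygous
#'   (`AB`). Default 0.3.
#' @param genotype_error Probability that a tumor genotype is flipped to a
#'   different call. Default 0.01.
#' @param nocall_rate Per-sample probability of a `NoCall`. Default 0.02.
#' @param frag_range Range of the uniform integer PCR fragment-length
#'   distribution in bp. Default `c(100, 1200)`.
#' @param truth Data frame of ground-truth regions with columns
#'   `chromosome`, `start`, `end`, `event` (one of `gain3`, `gain4`,
#'   `loss`, `homdel`, `cnloh`); regions must not overlap within a
#'   chromosome.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A `simulation_spec` object. The returned `truth` gains columns
#'   `cn` and `expected_log2`.
#' @export
simulation_spec <- function(chrom_info = hg18_chromosomes("autosomes"),
                            n_snps = 10000,
                            noise_sd = 0.25,
                            het_fraction = 0.3,
                            genotype_error = 0.01,
                            nocall_rate = 0.02,
                            frag_range = c(100, 1200),
                            truth = NULL,
                            seed = 1L) {
  if (is.null(truth)) {
    truth <- data.frame(chromosome = character(0), start = numeric(0),
                        end = numeric(0), event = character(0),
                        stringsAsFactors = FALSE)
  }
  for (p in c(het_fraction, genotype_error, nocall_rate)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(chrom_info$length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  bad <- which(!(truth$event %in% TRUTH_EVENTS))
  if (length(bad)) {
    stop(sprintf("unknown truth event '%s' (expected %s)", truth$event[bad[1]],
                 paste(TRUTH_EVENTS, collapse = "/")), call. = FALSE)
  }
  truth$chromosome <- if (nrow(truth)) normalize_chromosome(truth$chromosome) else character(0)
  if (nrow(truth)) {
    if (any(truth$start < 1) || any(truth$end < truth$start)) {
      stop("truth regions must satisfy 1 <= start <= end", call. = FALSE)
    }
    for (chrom in unique(truth$chromosome)) {
      tr <- truth[truth$chromosome == chrom, , drop = FALSE]
      tr <- tr[order(tr$start), , drop = FALSE]
      if (nrow(tr) > 1 && any(tr$start[-1] <= tr$end[-nrow(tr)])) {
        stop("truth regions overlap on chromosome ", chrom, call. = FALSE)
      }
    }
    truth$cn <- unname(.event_cn[truth$event])
    truth$expected_log2 <- unname(.event_log2[truth$event])
  }
  structure(list(chrom_info = chrom_info, n_snps = n_snps, noise_sd = noise_sd,
                 het_fraction = het_fraction, genotype_error = genotype_error,
                 nocall_rate = nocall_rate, frag_range = frag_range,
                 truth = truth, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Flip each flagged genotype to one of the other calls in {AA, AB, BB}.
.flip_genotypes <- function(calls, flip) {
  alleles <- c("AA", "AB", "BB")
  idx <- which(flip)
  for (i in idx) {
    others <- setdiff(alleles, calls[i])
    calls[i] <- others[sample.int(2, 1)]
  }
  calls
}

#' Simulate a paired tumor/germline SNP profile
#'
#' Draws SNP positions uniformly per chromosome (density proportional to
#' chromosome length), assigns germline genotypes (`AB` with probability
#' `het_fraction`, otherwise `AA`/`BB` equiprobably) at a fixed reference
#' intensity of 1000 units, and generates the tumor as the ground truth
#' dictates: the tumor log2 ratio is the covering truth region's expected
#' value (0 outside any region) plus Gaussian noise, and inside
#' LOH-inducing events (loss, homozygous deletion, copy-neutral LOH)
#' heterozygous germline genotypes become `AA`/`BB` equiprobably. Genotype
#' errors and `NoCall` dropouts are injected at the configured rates. The
#' output is fully reproducible from the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `profile` (a `snp_profile`) and `truth`
#'   (the spec's truth regions with `cn` and `expected_log2`).
#' @export
simulate_paired_sample <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop("'spec' must be a simulation_spec object", call. = FALSE)
  }
  set.seed(spec$seed)
  ci <- spec$chrom_info
  n_per <- pmax(1L, round(spec$n_snps * ci$length / sum(ci$length)))
  rows <- lapply(seq_len(nrow(ci)), function(i) {
    chrom <- ci$chromosome[i]
    n <- n_per[i]
    pos <- sort(sample.int(ci$length[i], n))
    data.frame(
      probe_id = sprintf("SNP_%s_%06d", chrom, seq_len(n)),
      chromosome = chrom,
      position = pos,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$fragment_length <- sample(seq(spec$frag_range[1], spec$frag_range[2]), n,
                               replace = TRUE)

  # covering truth event per SNP (NA outside all regions)
  event <- rep(NA_character_, n)
  tr <- spec$truth
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      hit <- df$chromosome == tr$chromosome[i] &
        df$position >= tr$start[i] & df$position <= tr$end[i]
      event[hit] <- tr$event[i]
    }
  }
  true_log2 <- ifelse(is.na(event), 0, unname(.event_log2[event]))

  ref_int <- rep(1000, n)
  log2_ratio <- true_log2 + stats::rnorm(n, 0, spec$noise_sd)
  tum_int <- 1000 * 2^log2_ratio

  is_het <- stats::runif(n) < spec$het_fraction
  hom_calls <- sample(c("AA", "BB"), n, replace = TRUE)
  ref_call <- ifelse(is_het, "AB", hom_calls)

  in_loh <- !is.na(event) & event %in% .loh_events
  tum_call <- ref_call
  loh_hom <- sample(c("AA", "BB"), n, replace = TRUE)
  tum_call[in_loh & is_het] <- loh_hom[in_loh & is_het]
  tum_call <- .flip_genotypes(tum_call, stats::runif(n) < spec$genotype_error)

  ref_call[stats::runif(n) < spec$nocall_rate] <- "NoCall"
  tum_call[stats::runif(n) < spec$nocall_rate] <- "NoCall"

  df$tumor_intensity <- tum_int
  df$reference_intensity <- ref_int
  df$tumor_call <- tum_call
  df$reference_call <- ref_call

  list(profile = snp_profile(df, genome_build = "hg18"), truth = spec$truth)
}

#' Glioma-archetype simulation specs
#'
#' Ready-made ground-truth layouts mirroring the two diagnostic glioma
#' copy-number archetypes, on the schematic hg18 autosomes at a scaled
#' ~10k-SNP density:
#'
#' * `"oligodendroglioma"`: loss of the chr1 p-arm and of the chr19 q-arm
#'   (the diagnostic 1p/19q codeletion), plus a copy-neutral LOH area on
#'   the chr1 q-arm exercising the allelic-imbalance-without-loss path.
#' * `"glioblastoma"`: gain of all of chr7 (copy number 3) with a focal
#'   higher-level (copy number 4) amplicon, loss of all of chr10 with LOH,
#'   and a focal homozygous deletion on chr9.
#'
#' The 1p/19q loss pair is present in exactly one archetype, so reports of
#' the two are mutually distinguishable.
#'
#' @param name `"oligodendroglioma"` or `"glioblastoma"`.
#' @param n_snps Total SNP count (default 10000).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulation_spec()].
#' @return A [simulation_spec()].
#' @export
archetype_spec <- function(name = c("oligodendroglioma", "glioblastoma"),
                           n_snps = 10000, seed = 1L, ...) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% c("oligodendroglioma", "glioblastoma"))) {
    stop("unknown archetype: '", paste(name, collapse = ","),
         "' (expected \"oligodendroglioma\" or \"glioblastoma\")", call. = FALSE)
  }
  truth <- switch(
    name,
    oligodendroglioma = data.frame(
      chromosome = c("1", "1", "19"),
      start = c(1, 145e6, 29e6),
      end = c(120e6, 247.2e6, 63.8e6),
      event = c("loss", "cnloh", "loss"),
      stringsAsFactors = FALSE
    ),
    glioblastoma = data.frame(
      chromosome = c("7", "7", "7", "9", "10"),
      start = c(1, 60e6 + 1, 85e6 + 1, 21e6, 1),
      end = c(60e6, 85e6, 158.8e6, 41e6, 135.4e6),
      event = c("gain3", "gain4", "gain3", "homdel", "loss"),
      stringsAsFactors = FALSE
    )
  )
  simulation_spec(n_snps = n_snps, truth = truth, seed = seed, ...)
}

#' Write a simulated pair as tumor/reference/truth tables
#'
#' Persists a simulated sample in the separate-table input format
#' (`probe_id`, `chromosome`, `position`, `fragment_length`, `intensity`,
#' `call`) plus a TSV of the ground-truth regions, so file-in/file-out runs
#' can be exercised end to end.
#'
#' @param sim Result of [simulate_paired_sample()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sample"`).
#' @return Named character vector of the three written paths, invisibly.
#' @export
write_sample_tables <- function(sim, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- sim$profile
  paths <- c(
    tumor = file.path(dir, paste0(prefix, "_tumor.tsv")),
    reference = file.path(dir, paste0(prefix, "_reference.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_one <- function(path, intensity, call) {
    out <- data.frame(
      probe_id = prof$probe_id,
      chromosome = prof$chromosome,
      position = format(prof$position, scientific = FALSE, trim = TRUE),
      fragment_length = prof$fragment_length,
      intensity = sprintf("%.6f", intensity),
      call = call,
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(paths["tumor"], prof$tumor_intensity, prof$tumor_call)
  write_one(paths["reference"], prof$reference_intensity, prof$reference_call)
  truth <- sim$truth
  truth$start <- format(truth$start, scientific = FALSE, trim = TRUE)
  truth$end <- format(truth$end, scientific = FALSE, trim = TRUE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
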