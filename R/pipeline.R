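#' Compute a paired copy-number/LOH profile
#'
#' The central constructor of the package: runs the full analysis on a
#' paired tumor/germline SNP profile — PCR fragment-size filtering,
#' median-centered log2 ratios and raw copy numbers, Gaussian smoothing,
#' per-SNP LOH calling, HMM segmentation of both tracks, merging of nearby
#' LOH areas, and detection/classification of altered regions — and returns
#' everything as a classed object with `print`, `summary` and `plot`
#' methods.
#'
#' @param tumor Either a `snp_profile` (joined paired table), the path to a
#'   joined paired TSV, or (with `reference`) the path to a tumor-only
#'   table.
#' @param reference Optional path to a reference-only table; when given,
#'   `tumor` must also be a path and the two are joined on `probe_id`.
#' @param config A [cna_config()]; validated before any computation.
#' @param sample_id Sample label used in outputs.
#' @return A `cna_profile` object: a list with the filtered profile
#'   (`snp_profile`), the per-SNP tracks (`cn_track`, `loh_track`), the raw
#'   and merged segmentations, the classified `regions`, the `config`,
#'   per-stage counts, and the creation time.
#' @export
#' @examples
#' sim <- simulate_paired_sample(simulation_spec(
#'   chrom_info = data.frame(chromosome = "1", length = 2e7),
#'   n_snps = 60, seed = 7
#' ))
#' fit <- cna_profile(sim$profile, sample_id = "demo")
#' print(fit)
cna_profile <- function(tumor, reference = NULL, config = cna_config(),
                        sample_id = "sample") {
  validate_config(config)
  profile <- if (is.character(tumor)) {
    if (!is.null(reference)) {
      read_paired_snp_tables(tumor, reference, config$genome_build)
    } else {
      read_snp_table(tumor, config$genome_build)
    }
  } else if (inherits(tumor, "snp_profile")) {
    tumor
  } else {
    stop("'tumor' must be a snp_profile or a file path", call. = FALSE)
  }
  n_input <- nrow(profile)

  filtered <- filter_by_fragment_size(profile, config$max_frag_size)
  if (nrow(filtered) == 0) stop("no SNPs remain after fragment-size filtering", call. = FALSE)

  track <- compute_log2_ratios(filtered)
  track <- gaussian_smooth(track, smoothing_kernel(config$smooth_window))

  loh_track <- build_loh_track(filtered)
  track$loh_call <- loh_track$call

  cn_params <- cn_hmm_params(
    emission_sd = config$hmm_emission_sd,
    stay_prob_at_1bp = config$hmm_stay_prob,
    decay_length = config$hmm_decay_length
  )
  loh_params <- loh_hmm_params(
    miscall_rate = config$loh_miscall_rate,
    loh_emission = config$loh_emission,
    stay_prob_at_1bp = config$hmm_stay_prob,
    decay_length = config$hmm_decay_length
  )
  cn_segments <- segment_cn(track, cn_params)
  loh_segments <- segment_loh(loh_track, loh_params)
  loh_merged <- merge_loh_segments(loh_segments, config$loh_merge_threshold)

  cna_regions <- detect_cna_regions(cn_segments, config)
  regions <- classify_loh_regions(loh_merged, cna_regions, config)

  structure(
    list(
      sample_id = sample_id,
      config = config,
      profile = filtered,
      cn_track = track,
      loh_track = loh_track,
      cn_segments = cn_segments,
      loh_segments = loh_segments,
      loh_segments_merged = loh_merged,
      regions = regions,
      counts = list(
        snps_input = n_input,
        snps_removed_by_fragment_filter = n_input - nrow(filtered),
        snps_analyzed = nrow(filtered),
        informative_snps = sum(loh_track$call != "non_informative"),
        cn_segments = nrow(cn_segments),
        loh_segments = nrow(loh_segments),
        loh_segments_merged = nrow(loh_merged),
        regions = nrow(regions)
      ),
      created = Sys.time()
    ),
    class = "cna_profile"
  )
}

#' Altered regions of a profile
#'
#' @param x A `cna_profile` object.
#' @return The `cna_regions` data frame.
#' @export
cna_regions <- function(x) {
  if (!inherits(x, "cna_profile")) stop("'x' must be a cna_profile", call. = FALSE)
  x$regions
}

#' @export
print.cna_profile <- function(x, ...) {
  cat(sprintf("Paired copy-number/LOH profile of '%s'\n", x$sample_id))
  cat(sprintf("  SNPs: %d analyzed (%d removed by fragment filter), %d informative\n",
              x$counts$snps_analyzed, x$counts$snps_removed_by_fragment_filter,
              x$counts$informative_snps))
  cat(sprintf("  Segments: %d copy-number, %d LOH (%d after merging)\n",
              x$counts$cn_segments, x$counts$loh_segments,
              x$counts$loh_segments_merged))
  cat(sprintf("  Altered regions: %d\n", nrow(x$regions)))
  if (nrow(x$regions)) {
    tab <- table(x$regions$type)
    cat("   ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cna_profile <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("\nAltered regions:\n")
    df <- object$regions[c("chromosome", "start", "end", "type", "n_snps", "mean_log2")]
    print(format(df, big.mark = ","), row.names = FALSE)
  }
  invisible(object$regions)
}

#' Plot method for paired profiles
#'
#' Dispatches to the genome-wide profile plot, or to a single-chromosome
#' plot when `chromosome` is given.
#'
#' @param x A `cna_profile` object.
#' @param chromosome Optional chromosome label.
#' @param ... Passed to [plot_genome_profile()] / [plot_chromosome()].
#' @return See the underlying plot function.
#' @export
plot.cna_profile <- function(x, chromosome = NULL, ...) {
  if (is.null(chromosome)) {
    plot_genome_profile(x, ...)
  } else {
    plot_chromosome(x, chromosome, ...)
  }
}

#' Run the full file-in/file-out pipeline
#'
#' Orchestrates a complete run: reads the input table(s), computes the
#' profile via [cna_profile()], and writes every artifact beside the
#' report — the CNT-dialect per-SNP track (with LOH calls), the region
#' table as TSV and BED, the PDF report, and a JSON run manifest recording
#' the config snapshot, per-stage counts, warnings, output paths and
#' per-stage elapsed time. The manifest is written on failure too, naming
#' the failing stage.
#'
#' @param tumor Path to the joined paired table, or to a tumor-only table
#'   when `reference` is given.
#' @param reference Optional path to a reference-only table.
#' @param out_dir Output directory (created if needed).
#' @param config A [cna_config()].
#' @param sample_id Sample label; also the output file prefix.
#' @param chromosomes Chromosome pages for the report: `"none"`, `"all"`
#'   or a vector of labels (defaults to the config's
#'   `chromosomes_to_plot`).
#' @param timestamp Optional pinned report timestamp (see
#'   [render_report()]).
#' @return The `cna_profile` object, invisibly, with attribute `files`
#'   naming the written artifacts.
#' @export
run_pipeline <- function(tumor, reference = NULL, out_dir,
                         config = cna_config(), sample_id = "sample",
                         chromosomes = NULL, timestamp = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    sample_id = sample_id,
    inputs = list(tumor = tumor, reference = reference),
    config = as.list(config_echo(config)),
    stages = list(),
    warnings = character(0),
    outputs = list(),
    status = "running"
  )
  manifest_path <- file.path(out_dir, paste0(sample_id, "_manifest.json"))
  write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$status <<- "failed"
        manifest$failed_stage <<- name
        manifest$error <<- conditionMessage(e)
        write_manifest()
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    manifest$stages[[name]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  stage("validate_config", validate_config(config))
  fit <- stage("analyze", cna_profile(tumor, reference, config, sample_id))
  manifest$counts <- fit$counts

  cnt_path <- file.path(out_dir, paste0(sample_id, "_cnt.tsv"))
  tsv_path <- file.path(out_dir, paste0(sample_id, "_regions.tsv"))
  bed_path <- file.path(out_dir, paste0(sample_id, "_regions.bed"))
  pdf_path <- file.path(out_dir, paste0(sample_id, "_report.pdf"))
  stage("write_cnt", write_cnt(fit$cn_track, cnt_path, config))
  stage("write_regions", {
    write_region_table(fit$regions, tsv_path, "tsv")
    write_region_table(fit$regions, bed_path, "bed")
  })
  chroms <- chromosomes %||% config$chromosomes_to_plot
  stage("render_report", render_report(fit, pdf_path, chromosomes = chroms,
                                       timestamp = timestamp))
  manifest$outputs <- list(cnt = cnt_path, regions_tsv = tsv_path,
                           regions_bed = bed_path, report_pdf = pdf_path,
                           manifest = manifest_path)
  manifest$status <- "ok"
  write_manifest()
  attr(fit, "files") <- unlist(manifest$outputs)
  invisible(fit)
}
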