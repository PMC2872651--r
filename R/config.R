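#' Pipeline configuration
#'
#' Collects every tunable of the paired copy-number/LOH pipeline with its
#' default. All base-pair quantities are in bp, all thresholds in log2 units.
#'
#' @param max_frag_size Maximum PCR fragment length in bp; SNPs on longer
#'   fragments are removed before analysis (supports partially degraded DNA).
#'   `0` disables the filter and keeps all SNPs. Default 600.
#' @param smooth_window Full width of the Gaussian smoothing window in bp
#'   (the kernel standard deviation is `smooth_window / 4`). Default 500000.
#' @param gain_threshold Segment mean log2 ratio at or above which a segment
#'   is reported as a gain. Default +0.3.
#' @param loss_threshold Segment mean log2 ratio at or below which a segment
#'   is reported as a loss. Default -0.3.
#' @param homdel_threshold Segment mean log2 ratio at or below which a loss
#'   is reported as a homozygous deletion. Default -1.5.
#' @param loh_merge_threshold Maximum gap in bp between neighboring LOH areas
#'   that are combined into one. Default 2000000 (2 Mbp). Lowering it may
#'   split LOH areas broken up by genotyping-call errors.
#' @param min_snps_per_region Minimum number of supporting SNPs (informative
#'   SNPs for LOH regions) for a region to be reported. Default 5.
#' @param chromosomes_to_plot `"all"`, `"none"`, or a vector of chromosome
#'   labels for per-chromosome report pages.
#' @param genome_build Genome build tag echoed into outputs. Default "hg18".
#' @param seed Integer seed for any stochastic step.
#' @param hmm_emission_sd Gaussian emission SD (log2 units) of the
#'   copy-number HMM. Default 0.25.
#' @param hmm_stay_prob Per-bp probability of remaining in the same hidden
#'   state over a 1 bp step. Default `1 - 1e-7`.
#' @param hmm_decay_length Gap length (bp) beyond which the transition
#'   probability stops decaying. Default 1e7.
#' @param loh_miscall_rate Probability that a retained heterozygous SNP reads
#'   as LOH (genotyping error). Default 0.05.
#' @param loh_emission Probability that an informative SNP inside a true LOH
#'   area reads as LOH. Default 0.95.
#'
#' @return An object of class `cna_config` (a validated named list).
#' @export
#' @examples
#' cfg <- cna_config(max_frag_size = 0)
#' cfg$loh_merge_threshold
cna_config <- function(max_frag_size = 600,
                       smooth_window = 500000,
                       gain_threshold = 0.3,
                       loss_threshold = -0.3,
                       homdel_threshold = -1.5,
                       loh_merge_threshold = 2000000,
                       min_snps_per_region = 5,
                       chromosomes_to_plot = "all",
                       genome_build = "hg18",
                       seed = 1L,
                       hmm_emission_sd = 0.25,
                       hmm_stay_prob = 1 - 1e-7,
                       hmm_decay_length = 1e7,
                       loh_miscall_rate = 0.05,
                       loh_emission = 0.95) {
  cfg <- list(
    max_frag_size = max_frag_size,
    smooth_window = smooth_window,
    gain_threshold = gain_threshold,
    loss_threshold = loss_threshold,
    homdel_threshold = homdel_threshold,
    loh_merge_threshold = loh_merge_threshold,
    min_snps_per_region = min_snps_per_region,
    chromosomes_to_plot = chromosomes_to_plot,
    genome_build = genome_build,
    seed = as.integer(seed),
    hmm_emission_sd = hmm_emission_sd,
    hmm_stay_prob = hmm_stay_prob,
    hmm_decay_length = hmm_decay_length,
    loh_miscall_rate = loh_miscall_rate,
    loh_emission = loh_emission
  )
  class(cfg) <- "cna_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the internal consistency of a [cna_config()] object: threshold
#' ordering (`gain > 0 > loss > homdel`), non-negative base-pair quantities,
#' and probability ranges. Called by every pipeline entry point before any
#' computation.
#'
#' @param config A `cna_config` object (or plain named list with the same
#'   fields).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  stopf <- function(...) stop("invalid configuration: ", sprintf(...), call. = FALSE)
  num1 <- function(field) {
    v <- config[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v)) {
      stopf("'%s' must be a single number", field)
    }
    v
  }
  for (f in c("max_frag_size", "smooth_window", "loh_merge_threshold")) {
    if (num1(f) < 0) stopf("'%s' must be >= 0 bp", f)
  }
  if (num1("smooth_window") <= 0) stopf("'smooth_window' must be > 0 bp")
  gt <- num1("gain_threshold"); lt <- num1("loss_threshold"); ht <- num1("homdel_threshold")
  if (!(gt > 0 && 0 > lt && lt > ht)) {
    stopf("thresholds must satisfy gain_threshold > 0 > loss_threshold > homdel_threshold (got %g, %g, %g)",
          gt, lt, ht)
  }
  if (num1("min_snps_per_region") < 1) stopf("'min_snps_per_region' must be >= 1")
  sp <- num1("hmm_stay_prob")
  if (!(sp > 0 && sp < 1)) stopf("'hmm_stay_prob' must be in (0, 1)")
  if (num1("hmm_emission_sd") <= 0) stopf("'hmm_emission_sd' must be > 0")
  if (num1("hmm_decay_length") <= 0) stopf("'hmm_decay_length' must be > 0")
  eps <- num1("loh_miscall_rate"); le <- num1("loh_emission")
  if (!(eps > 0 && eps < le && le < 1)) {
    stopf("need 0 < loh_miscall_rate < loh_emission < 1 (got %g, %g)", eps, le)
  }
  if (!is.character(config$genome_build) || !nzchar(config$genome_build)) {
    stopf("'genome_build' must be a non-empty string")
  }
  invisible(config)
}

#' Read a configuration file
#'
#' Reads a YAML file whose keys mirror the [cna_config()] argument names and
#' merges it over the defaults. Unknown keys raise an error so typos in
#' config files are caught rather than silently ignored.
#'
#' @param path Path to a YAML configuration file.
#' @param ... Overrides applied on top of the file values (as from CLI
#'   flags).
#' @return A validated `cna_config` object.
#' @export
read_cna_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(cna_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(cna_config, vals)
}

#' @export
print.cna_config <- function(x, ...) {
  cat("Paired CNA/LOH pipeline configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-22s %s\n", f, paste(format(x[[f]]), collapse = ",")))
  }
  invisible(x)
}

# Flat key=value representation used in CNT metadata headers and manifests.
config_echo <- function(config) {
  vals <- vapply(config, function(v) paste(format(v, digits = 15), collapse = ","), character(1))
  stats::setNames(vals, names(config))
}
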