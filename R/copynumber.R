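#' Gaussian smoothing kernel
#'
#' Defines the Gaussian kernel used to smooth per-SNP log2 ratios along the
#' genome. The `window` is the full window width in bp; the kernel standard
#' deviation is `window / 4` so that +/- 2 sigma covers the window, and the
#' kernel is truncated at `truncation` multiples of sigma for speed.
#'
#' @param window Full window width in bp (default 500 kb).
#' @param truncation Truncation radius in multiples of sigma (default 3).
#' @return A `smoothing_kernel` object with fields `window`, `sigma`,
#'   `truncation`.
#' @export
smoothing_kernel <- function(window = 500000, truncation = 3) {
  if (!is.numeric(window) || length(window) != 1 || is.na(window) || window <= 0) {
    stop("kernel window must be a single positive number of bp", call. = FALSE)
  }
  if (!is.numeric(truncation) || truncation <= 0) {
    stop("kernel truncation must be > 0", call. = FALSE)
  }
  structure(list(window = window, sigma = window / 4, truncation = truncation),
            class = "smoothing_kernel")
}

#' Filter SNPs by PCR fragment length
#'
#' Removes SNPs whose PCR fragment length exceeds `max_frag_size`, which
#' improves signal for partially degraded DNA samples. A threshold of 0
#' disables the filter and keeps all SNPs (appropriate for fresh-frozen
#' material).
#'
#' @param profile A `snp_profile`.
#' @param max_frag_size Maximum fragment length in bp (>= 0); 0 keeps
#'   everything.
#' @return The filtered `snp_profile`.
#' @export
filter_by_fragment_size <- function(profile, max_frag_size = 600) {
  if (!is.numeric(max_frag_size) || length(max_frag_size) != 1 ||
      is.na(max_frag_size) || max_frag_size < 0) {
    stop("max_frag_size must be a single number >= 0", call. = FALSE)
  }
  if (max_frag_size == 0) {
    message("filter_by_fragment_size: filter disabled (max_frag_size = 0), 0 SNPs removed")
    return(profile)
  }
  keep <- profile$fragment_length <= max_frag_size
  removed <- sum(!keep)
  message(sprintf("filter_by_fragment_size: removed %d of %d SNPs with fragment length > %g bp",
                  removed, nrow(profile), max_frag_size))
  out <- profile[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    message("filter_by_fragment_size: WARNING - no SNPs remain after filtering")
  }
  rownames(out) <- NULL
  structure(out,
            genome_build = attr(profile, "genome_build"),
            class = class(profile))
}

#' Compute per-SNP log2 ratios and raw copy numbers
#'
#' For each SNP, computes `log2(tumor_intensity / reference_intensity)` and
#' median-centers the values over autosomal SNPs (a robust surrogate for
#' array-level normalization that removes global intensity scaling between
#' the two hybridizations). The raw copy number is `2 * 2^log2_ratio` under
#' a diploid-reference assumption. Sex chromosomes are carried through but
#' excluded from the normalization median.
#'
#' @param profile A `snp_profile` with positive intensities.
#' @return A `cn_track` with `log2_ratio` and `raw_cn` filled and the
#'   smoothed columns unset (`NA`); attribute `normalization_offset` records
#'   the subtracted median.
#' @export
compute_log2_ratios <- function(profile) {
  bad <- which(profile$tumor_intensity <= 0 | profile$reference_intensity <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive intensity for probe '%s'", profile$probe_id[bad[1]]),
         call. = FALSE)
  }
  lr <- log2(profile$tumor_intensity / profile$reference_intensity)
  auto <- is_autosome(profile$chromosome)
  if (any(auto)) {
    m <- stats::median(lr[auto])
  } else {
    warning("no autosomal SNPs available for normalization; ratios left uncentered",
            call. = FALSE)
    m <- 0
  }
  r <- lr - m
  track <- data.frame(
    probe_id = profile$probe_id,
    chromosome = profile$chromosome,
    position = profile$position,
    log2_ratio = r,
    raw_cn = 2 * 2^r,
    smoothed_log2 = NA_real_,
    smoothed_cn = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(track,
            genome_build = attr(profile, "genome_build"),
            normalization_offset = m,
            class = c("cn_track", "data.frame"))
}

# Truncated Gaussian weighted mean of v at each position, one chromosome.
.smooth_chromosome <- function(positions, values, sigma, truncation) {
  n <- length(positions)
  if (n == 1) return(values)
  positions <- as.numeric(positions)  # avoid integer overflow in d * d
  h <- truncation * sigma
  out <- numeric(n)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (positions[i] - positions[lo] > h) lo <- lo + 1L
    if (hi < i) hi <- i
    while (hi < n && positions[hi + 1L] - positions[i] <= h) hi <- hi + 1L
    d <- positions[lo:hi] - positions[i]
    w <- exp(-(d * d) / (2 * sigma * sigma))
    out[i] <- sum(w * values[lo:hi]) / sum(w)
  }
  out
}

#' Smooth a log2-ratio track with a Gaussian kernel
#'
#' Replaces each SNP's log2 ratio by the Gaussian-weighted mean of its
#' chromosome neighbours within `truncation * sigma` bp (the SNP itself
#' always included). Chromosomes are smoothed independently: no information
#' crosses a chromosome boundary. Smoothed copy number is
#' `2 * 2^smoothed_log2`.
#'
#' @param track A `cn_track` from [compute_log2_ratios()].
#' @param kernel A [smoothing_kernel()].
#' @return The track with `smoothed_log2` and `smoothed_cn` filled.
#' @export
gaussian_smooth <- function(track, kernel = smoothing_kernel()) {
  if (!inherits(kernel, "smoothing_kernel")) {
    stop("'kernel' must be a smoothing_kernel object", call. = FALSE)
  }
  sm <- track$log2_ratio
  for (chrom in unique(track$chromosome)) {
    idx <- which(track$chromosome == chrom)
    sm[idx] <- .smooth_chromosome(track$position[idx], track$log2_ratio[idx],
                                  kernel$sigma, kernel$truncation)
  }
  track$smoothed_log2 <- sm
  track$smoothed_cn <- 2 * 2^sm
  track
}
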