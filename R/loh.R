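#' Per-SNP LOH call from paired genotypes
#'
#' Compares tumor and germline reference genotype calls at one or more SNPs.
#' A SNP is informative only when the reference is heterozygous (`AB`). At
#' informative SNPs a homozygous tumor call (`AA`/`BB`) is loss of
#' heterozygosity, a heterozygous tumor call is retention, and a tumor
#' `NoCall` is treated as non-informative (genotype dropout is common in
#' tumors; calling it LOH would inflate false positives). Any SNP with a
#' non-heterozygous reference (including reference `NoCall`) is
#' non-informative.
#'
#' @param tumor_call,reference_call Character vectors of genotype calls in
#'   `AA`, `AB`, `BB`, `NoCall`.
#' @return Character vector in `"LOH"`, `"retention"`, `"non_informative"`.
#' @export
#' @examples
#' call_loh(c("AA", "AB", "BB", "NoCall"), c("AB", "AB", "AA", "AB"))
call_loh <- function(tumor_call, reference_call) {
  if (length(tumor_call) != length(reference_call)) {
    stop("tumor_call and reference_call must have equal length", call. = FALSE)
  }
  for (v in list(tumor_call, reference_call)) {
    bad <- which(!(v %in% GENOTYPE_CALLS))
    if (length(bad)) {
      stop(sprintf("invalid genotype call '%s' (expected AA/AB/BB/NoCall)", v[bad[1]]),
           call. = FALSE)
    }
  }
  out <- rep("non_informative", length(tumor_call))
  inf <- reference_call == "AB"
  out[inf & tumor_call %in% c("AA", "BB")] <- "LOH"
  out[inf & tumor_call == "AB"] <- "retention"
  out
}

#' Build the per-SNP LOH track of a paired profile
#'
#' Applies [call_loh()] to every SNP of a paired profile and reports the
#' informative fraction.
#'
#' @param profile A `snp_profile`.
#' @return A `loh_track` data frame (`probe_id`, `chromosome`, `position`,
#'   `call`), ordered as the profile.
#' @export
build_loh_track <- function(profile) {
  calls <- if (nrow(profile)) {
    call_loh(profile$tumor_call, profile$reference_call)
  } else {
    character(0)
  }
  track <- data.frame(
    probe_id = profile$probe_id,
    chromosome = profile$chromosome,
    position = profile$position,
    call = calls,
    stringsAsFactors = FALSE
  )
  n_inf <- sum(calls != "non_informative")
  message(sprintf("build_loh_track: %d of %d SNPs informative (%.1f%%)",
                  n_inf, nrow(track), if (nrow(track)) 100 * n_inf / nrow(track) else 0))
  structure(track,
            genome_build = attr(profile, "genome_build"),
            class = c("loh_track", "data.frame"))
}

#' Merge neighboring LOH areas
#'
#' Combines loss-state LOH segments on the same chromosome whose gap
#' (`start2 - end1 - 1`) is at most `threshold` bp, repeating until a fixed
#' point. Retention segments lying between a merged pair are absorbed into
#' it: the merged segment's `n_snps` is the total informative SNP count of
#' the combined span and `mean_value` the informative-weighted LOH fraction.
#' Lowering the threshold may split LOH areas broken up by genotyping-call
#' errors; raising it never increases the segment count.
#'
#' @param segments LOH segments as from [segment_loh()] (ordered,
#'   non-overlapping, one sample).
#' @param threshold Maximum gap in bp (inclusive comparison); default 2 Mbp.
#' @return The merged segment data frame.
#' @export
merge_loh_segments <- function(segments, threshold = 2e6) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    stop("invalid configuration: LOH merge threshold must be >= 0 bp", call. = FALSE)
  }
  if (nrow(segments) == 0) return(segments)
  segments <- segments[order(chrom_rank(segments$chromosome), segments$start), , drop = FALSE]
  merged <- lapply(unique(segments$chromosome), function(chrom) {
    segs <- segments[segments$chromosome == chrom, , drop = FALSE]
    loss_idx <- which(segs$state == "loss")
    if (length(loss_idx) < 2) return(segs)
    drop <- rep(FALSE, nrow(segs))
    cur <- loss_idx[1]
    for (nxt in loss_idx[-1]) {
      gap <- segs$start[nxt] - segs$end[cur] - 1
      if (gap <= threshold) {
        between <- seq(cur + 1, nxt - 1)
        between <- between[between < nxt & between > cur]
        # segments already absorbed into 'cur' must not be counted twice
        between <- between[!drop[between]]
        absorb <- c(cur, between, nxt)
        w <- segs$n_snps[absorb]
        mv <- segs$mean_value[absorb]
        tot <- sum(w)
        segs$end[cur] <- segs$end[nxt]
        segs$n_snps[cur] <- tot
        segs$mean_value[cur] <- if (tot > 0) sum(w * mv, na.rm = TRUE) / tot else NA_real_
        if ("low_confidence" %in% names(segs)) {
          segs$low_confidence[cur] <- any(segs$low_confidence[absorb])
        }
        drop[c(between, nxt)] <- TRUE
      } else {
        cur <- nxt
      }
    }
    segs[!drop, , drop = FALSE]
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  attr(out, "track_type") <- "loh"
  out
}
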