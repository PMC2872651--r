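REGION_TYPES <- c("gain", "loss", "homozygous_deletion", "LOH", "copy_neutral_LOH")

#' UCSC Genome Browser URL for a region
#'
#' Builds the browser link embedded in region tables and reports, using
#' 1-based inclusive coordinates and a URL-escaped colon.
#'
#' @param chromosome Chromosome label (without `"chr"` prefix).
#' @param start,end 1-based inclusive span in bp.
#' @param genome_build Assembly tag for the `db=` parameter (non-empty).
#' @return The URL string.
#' @export
#' @examples
#' make_ucsc_url("1", 1000000, 2000000, "hg18")
make_ucsc_url <- function(chromosome, start, end, genome_build = "hg18") {
  if (!is.character(genome_build) || !nzchar(genome_build)) {
    stop("genome_build must be a non-empty string", call. = FALSE)
  }
  sprintf("http://genome.ucsc.edu/cgi-bin/hgTracks?db=%s&position=chr%s%%3A%s-%s",
          genome_build, chromosome,
          format(start, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE))
}

# Extend segment boundaries to breakpoint estimates. Segments span their
# first to last member marker, so each internal boundary understates the
# event by up to one inter-marker gap: the true breakpoint lies anywhere in
# the gap, and its minimax estimate is the gap midpoint. Internal
# boundaries of adjacent segments move to floor(midpoint) / floor(midpoint)
# + 1; chromosome-terminal boundaries are left at the outermost marker.
.extend_to_midpoints <- function(segments) {
  if (nrow(segments) < 2) return(segments)
  segments <- segments[order(chrom_rank(segments$chromosome), segments$start), , drop = FALSE]
  for (chrom in unique(segments$chromosome)) {
    idx <- which(segments$chromosome == chrom)
    if (length(idx) < 2) next
    for (j in seq_len(length(idx) - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      mid <- floor((segments$end[a] + segments$start[b]) / 2)
      segments$end[a] <- mid
      segments$start[b] <- mid + 1
    }
  }
  segments
}

.empty_regions <- function() {
  structure(
    data.frame(chromosome = character(0), start = numeric(0), end = numeric(0),
               type = character(0), n_snps = integer(0), mean_log2 = numeric(0),
               loh_overlap_fraction = numeric(0), ucsc_url = character(0),
               stringsAsFactors = FALSE),
    class = c("cna_regions", "data.frame")
  )
}

#' Detect copy-number-altered regions from segments
#'
#' Applies the three copy-number thresholds to the mean smoothed log2 ratio
#' of each segment: `mean >= gain_threshold` is a gain,
#' `mean <= homdel_threshold` a homozygous deletion,
#' `homdel_threshold < mean <= loss_threshold` a loss; segments inside the
#' neutral band, or supported by fewer than `min_snps_per_region` SNPs, are
#' not reported. Increasing the absolute threshold values makes detection
#' more conservative.
#'
#' Reported region boundaries are breakpoint estimates: each internal
#' segment boundary is moved to the midpoint of the inter-marker gap
#' between adjacent segments (the true breakpoint lies in that gap and the
#' midpoint is its minimax estimate); chromosome-terminal boundaries stay
#' at the outermost marker.
#'
#' @param cn_segments Segments from [segment_cn()].
#' @param config A validated [cna_config()].
#' @return A `cna_regions` data frame sorted by (chromosome, start).
#' @export
detect_cna_regions <- function(cn_segments, config = cna_config()) {
  validate_config(config)
  if (nrow(cn_segments) == 0) return(.empty_regions())
  cn_segments <- .extend_to_midpoints(cn_segments)
  m <- cn_segments$mean_value
  type <- rep(NA_character_, nrow(cn_segments))
  type[m >= config$gain_threshold] <- "gain"
  type[m <= config$loss_threshold & m > config$homdel_threshold] <- "loss"
  type[m <= config$homdel_threshold] <- "homozygous_deletion"
  keep <- !is.na(type) & cn_segments$n_snps >= config$min_snps_per_region
  if (!any(keep)) return(.empty_regions())
  seg <- cn_segments[keep, , drop = FALSE]
  out <- data.frame(
    chromosome = seg$chromosome,
    start = seg$start,
    end = seg$end,
    type = type[keep],
    n_snps = seg$n_snps,
    mean_log2 = seg$mean_value,
    loh_overlap_fraction = 0,
    ucsc_url = make_ucsc_url(seg$chromosome, seg$start, seg$end, config$genome_build),
    stringsAsFactors = FALSE
  )
  out <- out[order(chrom_rank(out$chromosome), out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cna_regions", "data.frame"))
}

# Overlap length of [s1,e1] and [s2,e2] on 1-based inclusive coordinates.
.overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# Reciprocal overlap fraction: min of the two coverage fractions.
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- .overlap_bp(s1, e1, s2, e2)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Classify LOH areas against copy-number regions
#'
#' Turns merged loss-state LOH segments into altered regions and annotates
#' copy-number regions with their LOH overlap. An LOH area is
#' `copy_neutral_LOH` (allelic imbalance without copy loss, e.g.
#' uniparental disomy) when its reciprocal overlap with every loss /
#' homozygous-deletion region stays below 50%, and `LOH`
#' (copy-loss-associated) otherwise. Every copy-number region additionally
#' records the fraction of its span covered by LOH segments
#' (`loh_overlap_fraction`). As in [detect_cna_regions()], internal
#' boundaries are extended to inter-marker gap midpoints (here the markers
#' are the informative SNPs) before classification.
#'
#' @param loh_segments_merged Merged LOH segments from
#'   [merge_loh_segments()].
#' @param cna_regions Copy-number regions from [detect_cna_regions()].
#' @param config A validated [cna_config()] (supplies
#'   `min_snps_per_region` and `genome_build`).
#' @return A `cna_regions` data frame combining the copy-number regions
#'   (with updated `loh_overlap_fraction`) and the classified LOH regions,
#'   sorted by (chromosome, start).
#' @export
classify_loh_regions <- function(loh_segments_merged, cna_regions,
                                 config = cna_config()) {
  validate_config(config)
  loh_segments_merged <- .extend_to_midpoints(loh_segments_merged)
  loss_segs <- loh_segments_merged[loh_segments_merged$state == "loss", , drop = FALSE]
  cn_loss <- cna_regions[cna_regions$type %in% c("loss", "homozygous_deletion"), , drop = FALSE]

  # annotate copy-number regions with LOH coverage
  if (nrow(cna_regions)) {
    cna_regions$loh_overlap_fraction <- vapply(seq_len(nrow(cna_regions)), function(i) {
      same <- loss_segs[loss_segs$chromosome == cna_regions$chromosome[i], , drop = FALSE]
      if (!nrow(same)) return(0)
      ov <- sum(.overlap_bp(cna_regions$start[i], cna_regions$end[i], same$start, same$end))
      ov / (cna_regions$end[i] - cna_regions$start[i] + 1)
    }, numeric(1))
  }

  loh_regions <- .empty_regions()
  keep <- loss_segs$n_snps >= config$min_snps_per_region
  loss_segs <- loss_segs[keep, , drop = FALSE]
  if (nrow(loss_segs)) {
    type <- vapply(seq_len(nrow(loss_segs)), function(i) {
      same <- cn_loss[cn_loss$chromosome == loss_segs$chromosome[i], , drop = FALSE]
      if (!nrow(same)) return("copy_neutral_LOH")
      rec <- .reciprocal_overlap(loss_segs$start[i], loss_segs$end[i],
                                 same$start, same$end)
      if (any(rec >= 0.5)) "LOH" else "copy_neutral_LOH"
    }, character(1))
    loh_regions <- data.frame(
      chromosome = loss_segs$chromosome,
      start = loss_segs$start,
      end = loss_segs$end,
      type = type,
      n_snps = loss_segs$n_snps,
      mean_log2 = NA_real_,
      loh_overlap_fraction = 1,
      ucsc_url = make_ucsc_url(loss_segs$chromosome, loss_segs$start,
                               loss_segs$end, config$genome_build),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(as.data.frame(cna_regions), as.data.frame(loh_regions))
  if (nrow(out)) {
    out <- out[order(chrom_rank(out$chromosome), out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("cna_regions", "data.frame"))
}
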