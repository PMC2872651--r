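# Colors follow the report convention: red = any copy loss or LOH,
# blue = gain.
.region_color <- function(type) {
  ifelse(type == "gain", "#3366BBAA", "#CC3333AA")
}

# Cumulative genome layout for the chromosomes present in a track, using the
# schematic hg18 lengths where known and the last observed SNP otherwise.
.genome_layout <- function(chromosomes, track) {
  chroms <- unique(chromosomes)
  chroms <- chroms[order(chrom_rank(chroms))]
  info <- hg18_chromosomes("all")
  len <- vapply(chroms, function(chrom) {
    known <- info$length[info$chromosome == chrom]
    observed <- max(track$position[track$chromosome == chrom])
    max(known, observed)
  }, numeric(1))
  offset <- cumsum(c(0, len[-length(len)]))
  data.frame(chromosome = chroms, length = len, offset = offset,
             stringsAsFactors = FALSE)
}

#' Genome-wide copy-number/LOH profile plot
#'
#' Draws the raw log2 ratios as a light scatter and the smoothed profile as
#' a dark line over a cumulative genomic coordinate, with chromosome
#' boundary lines and labels, a secondary copy-number axis (`2 * 2^y`), and
#' the altered regions shaded (blue for gains, red for losses, homozygous
#' deletions and LOH).
#'
#' @param x A `cna_profile` object.
#' @param main Plot title; defaults to the sample id.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, a list with the shaded spans
#'   (`data.frame(chromosome, start, end, type, color)`) and the chromosome
#'   layout — useful for programmatic checks of what was drawn.
#' @export
plot_genome_profile <- function(x, main = NULL, ...) {
  track <- x$cn_track
  if (is.null(track) || nrow(track) == 0) stop("profile has an empty track", call. = FALSE)
  regions <- x$regions
  layout_df <- .genome_layout(track$chromosome, track)
  off <- stats::setNames(layout_df$offset, layout_df$chromosome)
  gx <- track$position + off[track$chromosome]
  ylim <- range(c(track$log2_ratio, -2, 2), finite = TRUE)
  graphics::plot(gx, track$log2_ratio, pch = ".", col = "grey60",
                 xlab = "genomic position", ylab = "log2 ratio",
                 xaxt = "n", ylim = ylim,
                 main = main %||% x$sample_id, ...)
  shaded <- data.frame(chromosome = character(0), start = numeric(0),
                       end = numeric(0), type = character(0),
                       color = character(0), stringsAsFactors = FALSE)
  if (!is.null(regions) && nrow(regions)) {
    cols <- .region_color(regions$type)
    graphics::rect(regions$start + off[regions$chromosome], ylim[1],
                   regions$end + off[regions$chromosome], ylim[2],
                   col = cols, border = NA)
    shaded <- data.frame(chromosome = regions$chromosome, start = regions$start,
                         end = regions$end, type = regions$type, color = cols,
                         stringsAsFactors = FALSE)
  }
  bounds <- c(layout_df$offset, sum(layout_df$length[nrow(layout_df)], layout_df$offset[nrow(layout_df)]))
  graphics::abline(v = bounds, col = "grey40", lty = 3)
  graphics::axis(1, at = layout_df$offset + layout_df$length / 2,
                 labels = layout_df$chromosome, tick = FALSE, cex.axis = 0.7,
                 las = 2)
  cn_ticks <- c(1, 2, 3, 4)
  graphics::axis(4, at = log2(cn_ticks / 2), labels = cn_ticks, cex.axis = 0.7)
  graphics::mtext("copy number", side = 4, line = 2, cex = 0.8)
  for (chrom in layout_df$chromosome) {
    idx <- which(track$chromosome == chrom)
    graphics::lines(gx[idx], track$smoothed_log2[idx], col = "navy", lwd = 1.2)
  }
  graphics::abline(h = 0, col = "grey40", lwd = 0.5)
  invisible(list(shaded = shaded, layout = layout_df))
}

# Schematic chromosome bar: length-proportional p and q arm rectangles with
# a notch at the (approximate) centromere; altered spans drawn on the bar.
.draw_chromosome_bar <- function(chrom, chrom_len, centromere, regions) {
  graphics::plot(NA, xlim = c(0, chrom_len), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "")
  notch <- 0.01 * chrom_len
  graphics::rect(0, 0.35, max(1, centromere - notch), 0.65,
                 col = "grey85", border = "grey30")
  graphics::rect(min(chrom_len, centromere + notch), 0.35, chrom_len, 0.65,
                 col = "grey85", border = "grey30")
  graphics::polygon(c(centromere - notch, centromere, centromere + notch,
                      centromere, centromere - notch),
                    c(0.65, 0.5, 0.65, 0.35, 0.65) - c(0, 0.15, 0, -0.15, 0),
                    col = "grey60", border = "grey30")
  if (nrow(regions)) {
    graphics::rect(regions$start, 0.35, regions$end, 0.65,
                   col = .region_color(regions$type), border = NA)
    graphics::text((regions$start + regions$end) / 2, 0.8, labels = regions$type,
                   cex = 0.6, srt = 30, adj = 0)
  }
  graphics::mtext(paste0("chr", chrom), side = 2, las = 1, cex = 0.8)
}

#' Single-chromosome profile plot
#'
#' Draws one chromosome's raw and smoothed log2 profile with altered
#' regions shaded, above a schematic chromosome bar (length-proportional
#' rectangles with a centromere notch) on which the altered spans are
#' marked and labelled.
#'
#' @param x A `cna_profile` object.
#' @param chromosome Chromosome label present in the profile.
#' @param ... Unused.
#' @return Invisibly, the shaded spans drawn for this chromosome.
#' @export
plot_chromosome <- function(x, chromosome, ...) {
  track <- x$cn_track
  chromosome <- sub("^chr", "", as.character(chromosome))
  avail <- unique(track$chromosome)
  if (!(chromosome %in% avail)) {
    stop("unknown chromosome '", chromosome, "'; available: ",
         paste(avail[order(chrom_rank(avail))], collapse = ", "), call. = FALSE)
  }
  idx <- which(track$chromosome == chromosome)
  regions <- x$regions
  regions <- if (!is.null(regions) && nrow(regions)) {
    regions[regions$chromosome == chromosome, , drop = FALSE]
  } else {
    .empty_regions()
  }
  info <- hg18_chromosomes("all")
  chrom_len <- max(info$length[info$chromosome == chromosome],
                   track$position[idx])
  centromere <- info$centromere[info$chromosome == chromosome]
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE)
  graphics::layout(matrix(1:2, ncol = 1), heights = c(4, 1))
  graphics::par(mar = c(2, 4, 3, 4))
  ylim <- range(c(track$log2_ratio[idx], -2, 2), finite = TRUE)
  graphics::plot(track$position[idx], track$log2_ratio[idx], pch = 20,
                 cex = 0.3, col = "grey60", xlim = c(0, chrom_len),
                 ylim = ylim, xlab = "", ylab = "log2 ratio",
                 main = sprintf("%s - chromosome %s", x$sample_id, chromosome))
  if (nrow(regions)) {
    graphics::rect(regions$start, ylim[1], regions$end, ylim[2],
                   col = .region_color(regions$type), border = NA)
  }
  graphics::lines(track$position[idx], track$smoothed_log2[idx],
                  col = "navy", lwd = 1.4)
  graphics::abline(h = 0, col = "grey40", lwd = 0.5)
  graphics::axis(4, at = log2(c(1, 2, 3, 4) / 2), labels = c(1, 2, 3, 4),
                 cex.axis = 0.7)
  graphics::par(mar = c(1, 4, 0, 4))
  .draw_chromosome_bar(chromosome, chrom_len, centromere, regions)
  shaded <- data.frame(chromosome = regions$chromosome, start = regions$start,
                       end = regions$end, type = regions$type,
                       color = if (nrow(regions)) .region_color(regions$type) else character(0),
                       stringsAsFactors = FALSE)
  invisible(list(shaded = shaded, chromosome = chromosome, length = chrom_len))
}

# Region table pages drawn as text. Returns the number of pages emitted.
.draw_region_table <- function(x, timestamp_text, rows_per_page = 26) {
  regions <- x$regions
  header <- c("chrom", "start", "end", "type", "n_snps", "mean_log2", "UCSC link")
  fmt_row <- function(i) {
    c(regions$chromosome[i],
      format(regions$start[i], big.mark = ",", scientific = FALSE),
      format(regions$end[i], big.mark = ",", scientific = FALSE),
      regions$type[i],
      as.character(regions$n_snps[i]),
      ifelse(is.na(regions$mean_log2[i]), "-", sprintf("%.3f", regions$mean_log2[i])),
      regions$ucsc_url[i])
  }
  n <- nrow(regions)
  pages <- max(1, ceiling(max(1, n) / rows_per_page))
  widths <- c(0.04, 0.13, 0.22, 0.34, 0.43, 0.49, 0.56)
  for (pg in seq_len(pages)) {
    graphics::plot.new()
    graphics::par(mar = c(1, 1, 1, 1))
    y <- 0.98
    if (pg == 1) {
      graphics::text(0.0, y, paste0("Genomic alteration report - ", x$sample_id),
                     adj = 0, cex = 1.3, font = 2)
      y <- y - 0.035
      graphics::text(0.0, y, paste0("generated: ", timestamp_text), adj = 0, cex = 0.8)
      y <- y - 0.03
      ce <- config_echo(x$config)
      echo <- paste(names(ce), unname(ce), sep = "=", collapse = "  ")
      for (line in strwrap(echo, width = 130)) {
        graphics::text(0.0, y, line, adj = 0, cex = 0.6, col = "grey30")
        y <- y - 0.022
      }
      y <- y - 0.02
      graphics::text(0.0, y, sprintf("Altered genomic regions (%d)", n),
                     adj = 0, cex = 1.0, font = 2)
      y <- y - 0.03
    }
    graphics::text(widths, y, header, adj = 0, cex = 0.7, font = 2)
    y <- y - 0.025
    if (n == 0) {
      graphics::text(widths[1], y, "no alterations detected", adj = 0,
                     cex = 0.7, col = "grey40")
    } else {
      rows <- seq((pg - 1) * rows_per_page + 1, min(pg * rows_per_page, n))
      for (i in rows) {
        vals <- fmt_row(i)
        graphics::text(widths[-7], y, vals[-7], adj = 0, cex = 0.65)
        graphics::text(widths[7], y, vals[7], adj = 0, cex = 0.45, col = "blue4")
        y <- y - 0.03
      }
    }
  }
  pages
}

# Rewrite the /CreationDate and /ModDate strings of a PDF in place with a
# pinned datetime, preserving byte length so xref offsets stay valid.
.pin_pdf_dates <- function(path, timestamp) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- tryCatch(rawToChar(raw), error = function(e) NULL)
  if (is.null(txt)) {
    warning("could not pin PDF timestamps (binary content)", call. = FALSE)
    return(invisible(path))
  }
  pin <- format(as.POSIXct(timestamp, tz = "UTC"), "%Y%m%d%H%M%S")
  for (key in c("CreationDate", "ModDate")) {
    pat <- paste0("/", key, " \\(D:[^)]*\\)")
    m <- gregexpr(pat, txt, useBytes = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      full <- regmatches(txt, gregexpr(pat, txt, useBytes = TRUE))[[1]][j]
      inner_len <- nchar(full, type = "bytes") - nchar(paste0("/", key, " (D:)"), type = "bytes")
      pinned <- substr(paste0(pin, strrep("0", inner_len)), 1, inner_len)
      repl <- paste0("/", key, " (D:", pinned, ")")
      txt <- sub(pat, repl, txt, useBytes = TRUE)
    }
  }
  writeBin(charToRaw(txt), path)
  invisible(path)
}

# Page count of a PDF written by the base pdf() device ("/Count N" in the
# /Pages object).
pdf_page_count <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  raw[raw > as.raw(127L)] <- as.raw(32L)  # blank the binary header bytes
  txt <- rawToChar(raw)
  m <- regmatches(txt, gregexpr("/Count ([0-9]+)", txt))[[1]]
  if (!length(m)) return(NA_integer_)
  max(as.integer(sub("/Count ", "", m)))
}

#' Render a printable PDF report
#'
#' Writes the clinical-style report: page 1 a header (sample id, timestamp,
#' configuration echo) and the altered-region table with UCSC Genome
#' Browser links printed as text, page 2 the genome-wide profile, followed
#' by one page per requested chromosome. With a pinned `timestamp`,
#' rendering is deterministic: two runs over the same profile produce
#' byte-identical files.
#'
#' @param x A `cna_profile` object.
#' @param path Output PDF path.
#' @param chromosomes `"none"` (default: table + genome profile only),
#'   `"all"`, or a vector of chromosome labels for per-chromosome pages.
#' @param timestamp Optional POSIXct/string; pins the report date (header
#'   text and PDF metadata). When `NULL` the current time is used and
#'   reruns will differ in their date fields.
#' @return The path, invisibly, with attribute `pages`.
#' @export
render_report <- function(x, path, chromosomes = "none", timestamp = NULL) {
  track <- x$cn_track
  avail <- unique(track$chromosome)
  avail <- avail[order(chrom_rank(avail))]
  chroms <- if (identical(chromosomes, "all")) {
    avail
  } else if (is.null(chromosomes) || identical(chromosomes, "none") ||
             length(chromosomes) == 0) {
    character(0)
  } else {
    ch <- sub("^chr", "", as.character(chromosomes))
    bad <- setdiff(ch, avail)
    if (length(bad)) {
      stop("unknown chromosome '", bad[1], "'; available: ",
           paste(avail, collapse = ", "), call. = FALSE)
    }
    ch
  }
  ts <- if (is.null(timestamp)) Sys.time() else as.POSIXct(timestamp, tz = "UTC")
  ts_text <- format(ts, "%Y-%m-%d %H:%M:%S UTC", tz = "UTC")
  # compress = FALSE keeps the content streams as plain text and
  # useKerning = FALSE keeps each drawn string contiguous, so the file is
  # greppable (region-row and URL checks) and timestamp pinning works
  grDevices::pdf(path, width = 11, height = 8, onefile = TRUE,
                 paper = "special", compress = FALSE, useKerning = FALSE)
  ok <- FALSE
  tryCatch({
    graphics::par(mar = c(1, 1, 1, 1))
    table_pages <- .draw_region_table(x, ts_text)
    graphics::par(mar = c(4, 4, 3, 4))
    plot_genome_profile(x)
    for (chrom in chroms) plot_chromosome(x, chrom)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("report rendering failed", call. = FALSE)
  if (!is.null(timestamp)) .pin_pdf_dates(path, ts)
  invisible(structure(path, pages = table_pages + 1 + length(chroms)))
}
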