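SNP_TABLE_COLUMNS <- c(
  "probe_id", "chromosome", "position", "fragment_length",
  "tumor_intensity", "reference_intensity", "tumor_call", "reference_call"
)

GENOTYPE_CALLS <- c("AA", "AB", "BB", "NoCall")

CNT_COLUMNS <- c(
  "probe_id", "chromosome", "position", "log2_ratio", "raw_cn",
  "smoothed_log2", "smoothed_cn"
)

#' Construct a paired SNP profile
#'
#' Validates, normalizes and sorts a data frame of paired tumor/reference
#' SNP observations into a `snp_profile`. Chromosome labels are normalized
#' (leading "chr" stripped), rows are sorted canonically (chromosomes 1-22,
#' X, Y, then position), and duplicate (chromosome, position) rows are
#' resolved by keeping the first occurrence with a warning.
#'
#' @param df Data frame with the eight paired-observation columns
#'   (`probe_id`, `chromosome`, `position`, `fragment_length`,
#'   `tumor_intensity`, `reference_intensity`, `tumor_call`,
#'   `reference_call`).
#' @param genome_build Genome build tag attached to the profile.
#' @return A `snp_profile` (data frame subclass) with attribute
#'   `genome_build`.
#' @export
snp_profile <- function(df, genome_build = "hg18") {
  missing_cols <- setdiff(SNP_TABLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("SNP table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[SNP_TABLE_COLUMNS]
  df$probe_id <- as.character(df$probe_id)
  df$chromosome <- normalize_chromosome(df$chromosome)
  for (f in c("position", "fragment_length")) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad)) {
      stop(sprintf("column '%s': unparseable or non-integer value in data row %d",
                   f, bad[1]), call. = FALSE)
    }
    df[[f]] <- as.numeric(v)
  }
  if (any(df$position < 1)) {
    stop("positions must be >= 1 (1-based coordinates)", call. = FALSE)
  }
  if (any(df$fragment_length < 0)) {
    stop("fragment_length must be >= 0", call. = FALSE)
  }
  for (f in c("tumor_intensity", "reference_intensity")) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("column '%s': unparseable value in data row %d", f, bad[1]),
           call. = FALSE)
    }
    nonpos <- which(v <= 0)
    if (length(nonpos)) {
      stop(sprintf("column '%s': non-positive intensity for probe '%s'",
                   f, df$probe_id[nonpos[1]]), call. = FALSE)
    }
    df[[f]] <- v
  }
  for (f in c("tumor_call", "reference_call")) {
    df[[f]] <- as.character(df[[f]])
    bad <- which(!(df[[f]] %in% GENOTYPE_CALLS))
    if (length(bad)) {
      stop(sprintf("column '%s': invalid genotype call '%s' (expected AA/AB/BB/NoCall)",
                   f, df[[f]][bad[1]]), call. = FALSE)
    }
  }
  dup_pos <- duplicated(df[c("chromosome", "position")])
  if (any(dup_pos)) {
    warning(sprintf("%d duplicate (chromosome, position) row(s) removed (first occurrence kept)",
                    sum(dup_pos)), call. = FALSE)
    df <- df[!dup_pos, , drop = FALSE]
  }
  if (anyDuplicated(df$probe_id)) {
    stop("probe_id values must be unique within a profile", call. = FALSE)
  }
  df <- order_genomic(df)
  rownames(df) <- NULL
  structure(df,
            genome_build = genome_build,
            class = c("snp_profile", "data.frame"))
}

#' Read a paired SNP table
#'
#' Reads a tab-delimited table of paired tumor/reference SNP observations.
#' The header must name all eight columns of the paired record (in any
#' order); extra columns are ignored. The loader is order-invariant: any row
#' permutation of the same table yields the identical sorted profile.
#'
#' @param path Path to a TSV file.
#' @param genome_build Genome build tag attached to the profile.
#' @return A `snp_profile`.
#' @export
read_snp_table <- function(path, genome_build = "hg18") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty input file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (nrow(df) == 0) stop("input file has a header but no data rows: ", path, call. = FALSE)
  prof <- snp_profile(df, genome_build = genome_build)
  message(sprintf("read_snp_table: %d SNPs loaded from %s", nrow(prof), path))
  prof
}

#' Read separate tumor and reference SNP tables
#'
#' Reads a tumor and a germline reference table (columns `probe_id`,
#' `chromosome`, `position`, `fragment_length`, `intensity`, `call`) and
#' joins them on `probe_id` into a paired profile. The two tables must cover
#' the identical probe set with identical probe coordinates.
#'
#' @param tumor_path,reference_path Paths to the tumor and reference TSVs.
#' @param genome_build Genome build tag.
#' @return A `snp_profile`.
#' @export
read_paired_snp_tables <- function(tumor_path, reference_path, genome_build = "hg18") {
  read_one <- function(path, label) {
    if (!file.exists(path)) stop(label, " file not found: ", path, call. = FALSE)
    if (file.size(path) == 0) stop("empty ", label, " file: ", path, call. = FALSE)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "", quote = "")
    need <- c("probe_id", "chromosome", "position", "fragment_length", "intensity", "call")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop(label, " table is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df[need]
  }
  tum <- read_one(tumor_path, "tumor")
  ref <- read_one(reference_path, "reference")
  only_t <- setdiff(tum$probe_id, ref$probe_id)
  only_r <- setdiff(ref$probe_id, tum$probe_id)
  if (length(only_t) || length(only_r)) {
    first <- if (length(only_t)) only_t[1] else only_r[1]
    stop(sprintf("tumor and reference tables cover different probe sets (first mismatched probe: '%s')",
                 first), call. = FALSE)
  }
  ref <- ref[match(tum$probe_id, ref$probe_id), ]
  coord_mismatch <- which(tum$chromosome != ref$chromosome | tum$position != ref$position)
  if (length(coord_mismatch)) {
    stop(sprintf("tumor and reference tables disagree on coordinates for probe '%s'",
                 tum$probe_id[coord_mismatch[1]]), call. = FALSE)
  }
  joined <- data.frame(
    probe_id = tum$probe_id,
    chromosome = tum$chromosome,
    position = tum$position,
    fragment_length = tum$fragment_length,
    tumor_intensity = tum$intensity,
    reference_intensity = ref$intensity,
    tumor_call = tum$call,
    reference_call = ref$call,
    stringsAsFactors = FALSE
  )
  prof <- snp_profile(joined, genome_build = genome_build)
  message(sprintf("read_paired_snp_tables: %d paired SNPs loaded", nrow(prof)))
  prof
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

#' Write a copy-number track in the CNT-like text dialect
#'
#' Persists a per-SNP copy-number track (and its optional per-SNP LOH calls)
#' as a versioned tab-delimited dialect: `#`-prefixed `key=value` metadata
#' lines, then a header row and one row per SNP. Numeric columns are
#' serialized with six decimals. The dialect is CNT-like in content (raw and
#' smoothed log2 profiles plus LOH calls) but is a plain-text format of this
#' package, not a binary-compatible Affymetrix CNT file.
#'
#' @param track A `cn_track` as produced by [compute_log2_ratios()] and
#'   [gaussian_smooth()]; may carry a `loh_call` column.
#' @param path Output path.
#' @param config Optional `cna_config` echoed into the metadata header.
#' @return The path, invisibly.
#' @export
write_cnt <- function(track, path, config = NULL) {
  if (nrow(track) == 0) stop("refusing to write an empty track", call. = FALSE)
  meta <- c(
    format = "pairedCNA-cnt/1",
    tool = paste0("pairedCNA ", as.character(utils::packageVersion("pairedCNA"))),
    genome_build = attr(track, "genome_build") %||% "unknown"
  )
  if (!is.null(config)) {
    ce <- config_echo(config)
    names(ce) <- paste0("config.", names(ce))
    meta <- c(meta, ce)
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeLines(paste0("#", names(meta), "=", unname(meta)), con)
  cols <- CNT_COLUMNS
  has_loh <- "loh_call" %in% names(track)
  if (has_loh) cols <- c(cols, "loh_call")
  out <- data.frame(
    probe_id = track$probe_id,
    chromosome = track$chromosome,
    position = format(track$position, scientific = FALSE, trim = TRUE),
    # cn columns are re-derived from the serialized (6-decimal) log2 values
    # so that a read-back recomputation reproduces them exactly
    log2_ratio = fmt6(track$log2_ratio),
    raw_cn = fmt6(2 * 2^round(track$log2_ratio, 6)),
    smoothed_log2 = fmt6(track$smoothed_log2),
    smoothed_cn = fmt6(2 * 2^round(track$smoothed_log2, 6)),
    stringsAsFactors = FALSE
  )
  if (has_loh) out$loh_call <- track$loh_call
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Read a CNT-dialect track file
#'
#' Reads the text dialect written by [write_cnt()]. The log2 columns are
#' authoritative: the copy-number columns are recomputed as
#' `2 * 2^log2`, and a validation warning is raised if the file's values
#' deviate from the recomputation by more than 1e-6.
#'
#' @param path Path to a CNT-dialect file.
#' @return A `cn_track` with attributes `genome_build` and `metadata` (the
#'   parsed `key=value` header).
#' @export
read_cnt <- function(path) {
  if (!file.exists(path)) stop("CNT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- character(0)
  if (length(meta_lines)) {
    kv <- sub("^#", "", lines[meta_lines])
    eq <- regexpr("=", kv, fixed = TRUE)
    bad <- which(eq < 0)
    if (length(bad)) {
      stop(sprintf("malformed CNT metadata line %d: '%s'",
                   meta_lines[bad[1]], lines[meta_lines[bad[1]]]), call. = FALSE)
    }
    meta <- stats::setNames(substring(kv, eq + 1), substring(kv, 1, eq - 1))
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  if (length(body) < 2) stop("CNT file has no data rows: ", path, call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(CNT_COLUMNS, header)
  if (length(missing_cols)) {
    stop("CNT file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop(sprintf("CNT dialect violation at line '%s': expected %d fields, found %d",
                 body[-1][bad[1]], length(header), nf[bad[1]]), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(ifelse(df[[col]] == "NA", NA, df[[col]])))
    bad <- which(is.na(v) & df[[col]] != "NA")
    if (length(bad)) {
      stop(sprintf("CNT column '%s': unparseable value '%s'", col, df[[col]][bad[1]]),
           call. = FALSE)
    }
    v
  }
  track <- data.frame(
    probe_id = df$probe_id,
    chromosome = normalize_chromosome(df$chromosome),
    position = num("position"),
    log2_ratio = num("log2_ratio"),
    raw_cn = num("raw_cn"),
    smoothed_log2 = num("smoothed_log2"),
    smoothed_cn = num("smoothed_cn"),
    stringsAsFactors = FALSE
  )
  # log2 columns are authoritative; recompute copy numbers from them
  expect_raw <- 2 * 2^track$log2_ratio
  if (any(abs(track$raw_cn - expect_raw) > 1e-6, na.rm = TRUE)) {
    warning("raw_cn column inconsistent with log2_ratio beyond 1e-6; log2_ratio treated as authoritative",
            call. = FALSE)
  }
  track$raw_cn <- expect_raw
  expect_sm <- 2 * 2^track$smoothed_log2
  both <- !is.na(track$smoothed_cn) & !is.na(expect_sm)
  if (any(abs(track$smoothed_cn[both] - expect_sm[both]) > 1e-6)) {
    warning("smoothed_cn column inconsistent with smoothed_log2 beyond 1e-6; smoothed_log2 treated as authoritative",
            call. = FALSE)
  }
  track$smoothed_cn <- expect_sm
  if ("loh_call" %in% header) {
    bad <- which(!(df$loh_call %in% c("LOH", "retention", "non_informative")))
    if (length(bad)) {
      stop(sprintf("CNT column 'loh_call': invalid value '%s'", df$loh_call[bad[1]]),
           call. = FALSE)
    }
    track$loh_call <- df$loh_call
  }
  track <- order_genomic(track)
  rownames(track) <- NULL
  structure(track,
            genome_build = unname(meta["genome_build"]) %||% NA_character_,
            metadata = as.list(meta),
            class = c("cn_track", "data.frame"))
}

#' Write a region table
#'
#' Writes altered regions either as a TSV (chromosome, 1-based inclusive
#' span, type, supporting SNPs, mean log2, LOH overlap and UCSC Genome
#' Browser URL) or as a standard BED file (0-based half-open coordinates,
#' region type in the name column). Rows are sorted by canonical chromosome
#' order, then start.
#'
#' @param regions A `cna_regions` data frame as produced by
#'   [detect_cna_regions()] / [classify_loh_regions()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return The path, invisibly.
#' @export
write_region_table <- function(regions, path, format = c("tsv", "bed")) {
  if (is.character(format) && length(format) == 1 && !(format %in% c("tsv", "bed"))) {
    stop("unknown region table format: '", format, "' (expected \"tsv\" or \"bed\")",
         call. = FALSE)
  }
  format <- match.arg(format)
  if (nrow(regions)) {
    regions <- regions[order(chrom_rank(regions$chromosome), regions$start), , drop = FALSE]
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con), add = TRUE)
  if (format == "tsv") {
    cols <- c("chromosome", "start", "end", "type", "n_snps", "mean_log2",
              "loh_overlap_fraction", "ucsc_url")
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(regions)) {
      out <- data.frame(
        chromosome = regions$chromosome,
        start = format(regions$start, scientific = FALSE, trim = TRUE),
        end = format(regions$end, scientific = FALSE, trim = TRUE),
        type = regions$type,
        n_snps = regions$n_snps,
        mean_log2 = fmt6(regions$mean_log2),
        loh_overlap_fraction = fmt6(regions$loh_overlap_fraction),
        ucsc_url = regions$ucsc_url,
        stringsAsFactors = FALSE
      )
      writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
    }
  } else {
    if (nrow(regions)) {
      out <- data.frame(
        chrom = paste0("chr", regions$chromosome),
        start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
        end = format(regions$end, scientific = FALSE, trim = TRUE),
        name = regions$type,
        stringsAsFactors = FALSE
      )
      writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
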