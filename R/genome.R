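#' @keywords internal
CHROM_LABELS <- c(as.character(1:22), "X", "Y")

# Approximate hg18 chromosome lengths and centromere midpoints (bp), used for
# simulation layout and schematic chromosome plots. Values are rounded to the
# nearest 0.1 Mb and are intentionally schematic, not an annotation source.
.hg18_info <- data.frame(
  chromosome = CHROM_LABELS,
  length = c(
    247200000, 242800000, 199500000, 191300000, 180900000, 170900000,
    158800000, 146300000, 140300000, 135400000, 134500000, 132300000,
    114100000, 106400000, 100300000, 88800000, 78800000, 76100000,
    63800000, 62400000, 46900000, 49700000, 154900000, 57800000
  ),
  centromere = c(
    125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
    59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
    17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
    26500000, 27500000, 13200000, 14700000, 60600000, 12500000
  ),
  stringsAsFactors = FALSE
)

#' Schematic hg18 chromosome layout
#'
#' Chromosome lengths and centromere midpoints (base pairs) for the hg18
#' assembly, rounded to 0.1 Mb. The table is used to lay out simulated
#' profiles and to draw schematic chromosome bars in reports; it is not a
#' cytogenetic annotation resource.
#'
#' @param chromosomes Either `"all"` (chromosomes 1-22, X, Y) or
#'   `"autosomes"` (1-22), or a character vector of chromosome labels.
#' @return A data frame with columns `chromosome`, `length`, `centromere`.
#' @export
#' @examples
#' hg18_chromosomes("autosomes")[1:3, ]
hg18_chromosomes <- function(chromosomes = "all") {
  if (identical(chromosomes, "all")) {
    return(.hg18_info)
  }
  if (identical(chromosomes, "autosomes")) {
    return(.hg18_info[.hg18_info$chromosome %in% as.character(1:22), ])
  }
  labs <- normalize_chromosome(chromosomes)
  .hg18_info[match(labs, .hg18_info$chromosome), ]
}

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix and validates labels against the canonical
#' set 1-22, X, Y. Mitochondrial and unplaced contigs are rejected: the
#' genotyping arrays in scope do not tile them.
#'
#' @param x Character (or integer) vector of chromosome labels.
#' @return Character vector of canonical labels.
#' @export
normalize_chromosome <- function(x) {
  x <- sub("^chr", "", as.character(x))
  bad <- !(x %in% CHROM_LABELS)
  if (any(bad)) {
    stop(
      "unsupported chromosome label(s): ",
      paste(unique(x[bad]), collapse = ", "),
      " (expected 1-22, X or Y; mitochondrial/unplaced contigs are not supported)",
      call. = FALSE
    )
  }
  x
}

# Canonical sort rank: 1..22, X, Y.
chrom_rank <- function(x) {
  match(x, CHROM_LABELS)
}

is_autosome <- function(x) {
  x %in% as.character(1:22)
}

# Stable canonical (chromosome, position) ordering of a data frame.
order_genomic <- function(df) {
  df[order(chrom_rank(df$chromosome), df$position), , drop = FALSE]
}
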