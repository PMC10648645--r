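#' Construct a genetic map
#'
#' A genetic map is an ordered set of (physical position, cumulative genetic
#' distance) anchor points for one chromosome region. Between anchors the
#' cumulative distance is linearly interpolated, the standard treatment of
#' HapMap-style recombination maps. Coordinates are 1-based base pairs.
#'
#' @param pos_bp Integer vector of physical positions (bp), strictly
#'   increasing, at least two.
#' @param cm Numeric vector of cumulative genetic positions (cM),
#'   non-decreasing, same length as `pos_bp`.
#' @param rate_cm_mb Optional per-interval recombination rates (cM/Mb). If
#'   omitted they are recomputed from `cm`; the rate of the last row is 0 by
#'   convention.
#' @param chrom Chromosome label.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `chrom`, `pos_bp`, `rate_cm_mb`, `cm`.
#' @examples
#' gm <- genetic_map(c(1e6, 2e6), c(0, 1))
#' region_length_cm(gm)
#' @export
genetic_map <- function(pos_bp, cm, rate_cm_mb = NULL, chrom = "chr17") {
  if (length(pos_bp) < 2L)
    stop("insufficient map: need at least 2 points", call. = FALSE)
  if (length(cm) != length(pos_bp))
    stop("pos_bp and cm must have equal length", call. = FALSE)
  if (anyNA(pos_bp) || anyNA(cm))
    stop("malformed map: NA positions or distances", call. = FALSE)
  if (any(diff(pos_bp) <= 0))
    stop("malformed map: positions not strictly increasing", call. = FALSE)
  if (any(diff(cm) < 0))
    stop("malformed map: cumulative cM decreases", call. = FALSE)
  if (any(pos_bp < 1))
    stop("malformed map: positions must be >= 1", call. = FALSE)
  if (is.null(rate_cm_mb)) {
    rate_cm_mb <- c(diff(cm) / diff(pos_bp) * 1e6, 0)
  }
  m <- data.frame(chrom = chrom, pos_bp = as.numeric(pos_bp),
                  rate_cm_mb = as.numeric(rate_cm_mb), cm = as.numeric(cm))
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Read a HapMap-style recombination map
#'
#' Expects whitespace/tab-delimited columns
#' `Chromosome Position(bp) Rate(cM/Mb) Map(cM)` (header optional). A
#' three-column file without the chromosome label is also accepted.
#'
#' @param path Path to the text file (or a connection).
#' @param region Optional numeric `c(start_bp, end_bp)`; rows outside the
#'   bounds are dropped.
#' @param chrom Optional chromosome label to select when the file holds one.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, region = NULL, chrom = NULL) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(toks) == 0L ||
    is.na(suppressWarnings(as.numeric(toks[length(toks)])))
  tab <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 3L) {
    tab <- cbind(V0 = if (is.null(chrom)) "chr?" else chrom, tab)
  }
  if (ncol(tab) < 4L)
    stop("malformed map: expected 3 or 4 columns", call. = FALSE)
  names(tab)[1:4] <- c("chrom", "pos_bp", "rate_cm_mb", "cm")
  if (!is.null(chrom)) tab <- tab[tab$chrom == chrom, , drop = FALSE]
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] <= region[2])
    tab <- tab[tab$pos_bp >= region[1] & tab$pos_bp <= region[2], ,
               drop = FALSE]
  }
  if (nrow(tab) < 2L)
    stop("insufficient map: fewer than 2 usable rows", call. = FALSE)
  genetic_map(tab$pos_bp, tab$cm, tab$rate_cm_mb, chrom = tab$chrom[1])
}

#' Write a genetic map in HapMap-style columns
#'
#' @param map A [genetic_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  out <- data.frame(Chromosome = map$chrom, `Position(bp)` = map$pos_bp,
                    `Rate(cM/Mb)` = map$rate_cm_mb, `Map(cM)` = map$cm,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %s, %d points, %.0f..%.0f bp, %.4f cM\n",
              x$chrom[1], nrow(x), x$pos_bp[1], x$pos_bp[nrow(x)],
              region_length_cm(x)))
  invisible(x)
}

#' Total genetic length of the mapped region
#' @param map A [genetic_map()].
#' @return Length in cM.
#' @export
region_length_cm <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  map$cm[nrow(map)] - map$cm[1]
}

#' Convert physical to genetic coordinates
#'
#' Linear interpolation of cumulative cM between map anchors; exact at the
#' anchors. Positions outside the mapped span are an error (the analysis
#' region must be fully covered by the map; no extrapolation).
#'
#' @param map A [genetic_map()].
#' @param pos Physical position(s), bp.
#' @return Cumulative genetic position(s), cM.
#' @export
bp_to_cm <- function(map, pos) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(pos < map$pos_bp[1] | pos > map$pos_bp[nrow(map)]))
    stop("position outside map span", call. = FALSE)
  stats::approx(map$pos_bp, map$cm, xout = pos, method = "linear",
                ties = "ordered")$y
}

#' Convert genetic to physical coordinates
#'
#' Inverse of [bp_to_cm()]. On a plateau (an interval of zero recombination,
#' where one cM value maps to many bp) the leftmost bp is returned, a
#' deterministic tie-break.
#'
#' @param map A [genetic_map()].
#' @param cm Cumulative genetic position(s), cM.
#' @return Physical position(s), bp (possibly fractional between anchors).
#' @export
cm_to_bp <- function(map, cm) {
  stopifnot(inherits(map, "genetic_map"))
  lo <- map$cm[1]; hi <- map$cm[nrow(map)]
  if (any(cm < lo | cm > hi))
    stop("genetic position outside map span", call. = FALSE)
  # ties = min picks the leftmost bp wherever cumulative cM is flat
  stats::approx(map$cm, map$pos_bp, xout = cm, method = "linear",
                ties = min)$y
}

#' Genetic length of a physical segment
#'
#' The cumulative cM distance between two positions, the quantity that turns
#' a shared-haplotype interval (reported by its last matching markers on both
#' sides of the focal variant) into its genetic length.
#'
#' @param map A [genetic_map()].
#' @param left_bp,right_bp Segment endpoints (bp), `left_bp <= right_bp`,
#'   both within the map span. Vectorised.
#' @return Segment length(s) in cM, `>= 0`.
#' @export
segment_length_cm <- function(map, left_bp, right_bp) {
  if (any(left_bp > right_bp))
    stop("inverted endpoints: left_bp > right_bp", call. = FALSE)
  bp_to_cm(map, right_bp) - bp_to_cm(map, left_bp)
}

#' Synthetic recombination map emulating the study region
#'
#' A deterministic map for a ~20 Mb region of chromosome 17 with a total
#' genetic length of exactly 24.6 cM, anchored every 100 kb. The local rate
#' varies smoothly (two broad highs and a cold trough) so that bp<->cM is
#' non-trivial but strictly increasing; no random numbers are used. This
#' stands in for the HapMap Phase II chr17 map over the BRCA1 flanking
#' region, whose exact span the source study does not print.
#'
#' @param start_bp,end_bp Region bounds (bp).
#' @param length_cm Total genetic length (cM).
#' @param n_points Number of anchor points.
#' @return A [genetic_map()].
#' @examples
#' gm <- default_region_map()
#' region_length_cm(gm)  # 24.6
#' @export
default_region_map <- function(start_bp = 30e6, end_bp = 50e6,
                               length_cm = 24.6, n_points = 201L) {
  pos <- seq(start_bp, end_bp, length.out = n_points)
  u <- seq(0, 1, length.out = n_points - 1L)  # per-interval relative rate
  rate <- 1 + 0.8 * sin(2 * pi * u) + 0.5 * cos(5 * pi * u)
  rate <- pmax(rate, 0.05)                    # keep strictly increasing cM
  cm <- c(0, cumsum(rate))
  cm <- cm / cm[length(cm)] * length_cm
  genetic_map(round(pos), cm, chrom = "chr17")
}
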