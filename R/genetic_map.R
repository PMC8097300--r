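#' Construct a genetic map
#'
#' A piecewise-linear map from physical position (bp) to genetic position
#' (cM) for one chromosome.
#'
#' @param bp integer vector of strictly increasing physical positions.
#' @param cm numeric vector of non-decreasing genetic positions (cM).
#' @param chromosome chromosome label.
#' @return An object of class `"genetic_map"`.
#' @export
genetic_map <- function(bp, cm, chromosome = "1") {
  bp <- as.integer(bp); cm <- as.numeric(cm)
  if (length(bp) != length(cm)) stop("bp and cm must have equal length")
  if (length(bp) < 2L) stop("a genetic map needs at least two points")
  if (any(diff(bp) <= 0L)) stop("map bp positions must be strictly increasing")
  if (any(diff(cm) < 0)) stop("map cM positions must be non-decreasing")
  structure(list(bp = bp, cm = cm, chromosome = as.character(chromosome)[1]),
            class = "genetic_map")
}

#' Read a genetic map from a 3-column text file
#'
#' Expects whitespace-separated columns: chromosome, bp position, cM
#' position (no header, or a header that does not parse as numbers — rows
#' whose bp column is non-numeric are dropped).
#'
#' @param path file path.
#' @param chromosome optional label; if given, the map is restricted to it.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, chromosome = NULL) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "bp", "cm"),
                  colClasses = c("character", "character", "character"))
  bp <- suppressWarnings(as.numeric(d$bp))
  keep <- !is.na(bp)
  d <- d[keep, , drop = FALSE]
  if (!is.null(chromosome)) d <- d[d$chrom == as.character(chromosome), , drop = FALSE]
  if (nrow(d) < 2L) stop("genetic map has fewer than two usable rows")
  genetic_map(as.numeric(d$bp), as.numeric(d$cm), d$chrom[1])
}

#' Interpolate genetic position for physical positions
#'
#' Linear interpolation between flanking map points; positions below the
#' first (above the last) map point clamp to the first (last) cM value.
#' Non-decreasing in `bp`.
#'
#' @param map a [genetic_map()].
#' @param bp integer vector of physical positions.
#' @return Numeric vector of genetic positions (cM).
#' @export
interpolate_genetic_position <- function(map, bp) {
  if (!inherits(map, "genetic_map")) stop("map must be a genetic_map")
  if (length(map$bp) == 0L) stop("empty genetic map")
  approx(x = map$bp, y = map$cm, xout = as.numeric(bp), method = "linear",
         rule = 2, ties = "ordered")$y
}
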