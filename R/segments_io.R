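segment_columns <- c("id1", "id2", "hap1", "hap2", "chromosome",
                     "start_site", "end_site", "start_bp", "end_bp",
                     "start_cm", "end_cm", "length_cm")

empty_segments <- function() {
  data.frame(id1 = character(), id2 = character(),
             hap1 = integer(), hap2 = integer(),
             chromosome = character(),
             start_site = integer(), end_site = integer(),
             start_bp = integer(), end_bp = integer(),
             start_cm = numeric(), end_cm = numeric(),
             length_cm = numeric(), stringsAsFactors = FALSE)
}

#' Write IBD segments to a tab-separated file
#'
#' One row per segment with columns `id1, id2, hap1, hap2, chromosome,
#' start_site, end_site, start_bp, end_bp, start_cm, end_cm, length_cm`.
#' `hap1`/`hap2` are 0/1 within-individual haplotype labels, site indices
#' are 0-based, bp are the VCF POS values.
#'
#' @param segments segment data frame as produced by
#'   [compute_ibd_in_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  if (nrow(segments) > 0 && !all(segment_columns %in% names(segments)))
    stop("segments is missing columns: ",
         paste(setdiff(segment_columns, names(segments)), collapse = ", "))
  seg <- if (nrow(segments) == 0) empty_segments() else segments[, segment_columns]
  write.table(format(seg, trim = TRUE, scientific = FALSE, digits = 15),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read IBD segments written by [write_segments()]
#'
#' @param path file path.
#' @return Segment data frame.
#' @export
read_segments <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(id1 = "character", id2 = "character",
                                 hap1 = "integer", hap2 = "integer",
                                 chromosome = "character",
                                 start_site = "integer", end_site = "integer",
                                 start_bp = "integer", end_bp = "integer",
                                 start_cm = "numeric", end_cm = "numeric",
                                 length_cm = "numeric"))
  if (!identical(names(d), segment_columns))
    stop("not a segment table: header mismatch")
  d
}
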