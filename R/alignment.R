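#' Construct a haplotype alignment
#'
#' The in-memory representation of `M` phased haplotypes at `N` biallelic
#' sites on one chromosome. Haplotype rows `2i - 1` and `2i` (1-based) carry
#' the two haplotypes of individual `i`; site indices are 0-based everywhere
#' a `site` is reported.
#'
#' @param alleles integer matrix, `M x N`, entries 0, 1 or `NA` (missing).
#' @param bp integer vector of length `N`; strictly increasing physical
#'   positions (VCF `POS`, 1-based).
#' @param cm numeric vector of length `N`; non-decreasing genetic positions
#'   in centimorgans.
#' @param sample_ids character vector of `M / 2` individual labels.
#' @param chromosome single chromosome label.
#' @return An object of class `"haplotype_alignment"`.
#' @export
haplotype_alignment <- function(alleles, bp, cm, sample_ids, chromosome = "1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  obj <- structure(
    list(alleles = alleles, bp = as.integer(bp), cm = as.numeric(cm),
         sample_ids = as.character(sample_ids),
         chromosome = as.character(chromosome)[1]),
    class = "haplotype_alignment")
  validate_alignment(obj)
  obj
}

validate_alignment <- function(x) {
  stopifnot(inherits(x, "haplotype_alignment"))
  M <- nrow(x$alleles); N <- ncol(x$alleles)
  if (N < 1L) stop("alignment must contain at least one site")
  if (M %% 2L != 0L) stop("number of haplotypes must be even (diploid rows)")
  if (length(x$sample_ids) != M / 2L)
    stop("need one sample id per individual (M/2)")
  if (length(x$bp) != N || length(x$cm) != N)
    stop("bp and cm must have one entry per site")
  if (N > 1L && any(diff(x$bp) <= 0L))
    stop("bp positions must be strictly increasing")
  if (N > 1L && any(diff(x$cm) < 0))
    stop("cm positions must be non-decreasing")
  ok <- x$alleles %in% c(0L, 1L) | is.na(x$alleles)
  if (!all(ok)) stop("alleles must be 0, 1 or NA")
  invisible(x)
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf(
    "haplotype_alignment: %d haplotypes (%d individuals) x %d sites, chr %s, %.2f cM\n",
    nrow(x$alleles), nrow(x$alleles) / 2L, ncol(x$alleles), x$chromosome,
    diff(range(x$cm))))
  invisible(x)
}

n_haplotypes <- function(x) nrow(x$alleles)
n_sites <- function(x) ncol(x$alleles)

#' Subset an alignment or panel to a set of physical positions
#'
#' Keeps only sites whose `bp` position is in `bp`. Used to restrict two
#' data sets genotyped on different site panels to their shared sites before
#' an out-of-sample comparison (the analogue of intersecting two chips'
#' SNP lists). Site intersection is deliberately not automatic in
#' [compute_ibd_out_of_sample()].
#'
#' @param x a `haplotype_alignment` or a `tpbwt_panel`.
#' @param bp integer vector of physical positions to keep.
#' @return An object of the same class as `x`, restricted to the kept sites
#'   (panels are decompressed, subset and recompressed with their own
#'   template set).
#' @export
subset_sites <- function(x, bp) {
  if (inherits(x, "tpbwt_panel")) {
    tpl <- x$templates
    return(compress_panel(subset_sites(decompress_panel(x), bp), tpl))
  }
  validate_alignment(x)
  keep <- x$bp %in% as.integer(bp)
  if (!any(keep)) stop("no sites left after subsetting")
  haplotype_alignment(x$alleles[, keep, drop = FALSE], x$bp[keep],
                      x$cm[keep], x$sample_ids, x$chromosome)
}
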