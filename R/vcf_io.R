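#' Read phased genotypes from a VCF file
#'
#' Loads a single-chromosome VCF of phased biallelic SNPs into a
#' [haplotype_alignment()]. Haplotype row `2i - 1` (1-based) holds the
#' first (left of `|`) allele of sample `i`, row `2i` the second. Missing
#' alleles (`.`) are kept as `NA`; they are imputed inside the sweep, never
#' at load time.
#'
#' @param path VCF file (plain or bgzip; anything `vcfR` reads).
#' @param map a [genetic_map()] used to interpolate each site's cM position.
#' @return A [haplotype_alignment()].
#' @export
read_phased_vcf <- function(path, map) {
  if (!inherits(map, "genetic_map")) stop("map must be a genetic_map")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  chrom <- unique(fix[, "CHROM"])
  if (length(chrom) > 1L)
    stop("VCF must contain a single chromosome, found: ",
         paste(chrom, collapse = ", "))
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] == "" | is.na(fix[, "ALT"])
  if (any(multi))
    stop("multiallelic or ALT-less record at position ",
         fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt[is.na(gt)] <- ".|."  # fully-missing genotypes come back as NA
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1, , drop = TRUE]
    stop("unphased genotype at position ", fix[w[1], "POS"],
         " for sample ", colnames(gt)[w[2]])
  }
  bad <- matrix(!grepl("^[01.]\\|[01.]$", gt), nrow = nrow(gt))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop("unparseable GT '", gt[w[1], w[2]], "' at position ", fix[w[1], "POS"])
  }
  n_site <- nrow(gt); n_ind <- ncol(gt)
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  to_int <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x == "0"] <- 0L; out[x == "1"] <- 1L
    out
  }
  # alleles: haplotypes in rows, sites in columns
  alleles <- matrix(NA_integer_, nrow = 2L * n_ind, ncol = n_site)
  alleles[seq(1L, 2L * n_ind, by = 2L), ] <- t(matrix(to_int(a1), n_site, n_ind))
  alleles[seq(2L, 2L * n_ind, by = 2L), ] <- t(matrix(to_int(a2), n_site, n_ind))
  bp <- as.integer(fix[, "POS"])
  haplotype_alignment(alleles, bp, interpolate_genetic_position(map, bp),
                      colnames(gt), chrom)
}

#' Write a haplotype alignment as a minimal phased VCF
#'
#' Emits an uncompressed VCF 4.2 file with GT-only phased genotypes,
#' REF/ALT fixed to A/G. Inverse of [read_phased_vcf()] on the allele
#' matrix and positions; used by the simulator subcommand and test
#' fixtures.
#'
#' @param alignment a [haplotype_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(alignment, path) {
  validate_alignment(alignment)
  a <- alignment$alleles
  n_ind <- nrow(a) / 2L
  sym <- matrix(".", nrow(a), ncol(a))
  sym[!is.na(a)] <- as.character(a[!is.na(a)])
  gt <- matrix(paste(sym[seq(1L, nrow(a), 2L), , drop = FALSE],
                     sym[seq(2L, nrow(a), 2L), , drop = FALSE], sep = "|"),
               nrow = n_ind)
  # gt is individuals x sites; one VCF row per site
  body <- vapply(seq_len(ncol(a)), function(k) {
    paste(c(alignment$chromosome, alignment$bp[k], sprintf("site%d", k - 1L),
            "A", "G", ".", "PASS", ".", "GT", gt[, k]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", alignment$chromosome),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", alignment$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
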