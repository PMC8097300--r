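raw_alleles <- function(alignment) {
  a <- alignment$alleles
  a[is.na(a)] <- 2L
  a
}

segments_from_raw <- function(raw, alignment, id1_pool = NULL, id2_pool = NULL) {
  if (nrow(raw) == 0) {
    out <- empty_segments()
    attr(out, "max_open_matches") <- attr(raw, "max_open_matches")
    return(out)
  }
  ids <- alignment$sample_ids
  out <- data.frame(
    id1 = ids[raw$hap_a %/% 2L + 1L],
    id2 = ids[raw$hap_b %/% 2L + 1L],
    hap1 = raw$hap_a %% 2L,
    hap2 = raw$hap_b %% 2L,
    chromosome = alignment$chromosome,
    start_site = raw$start_site,
    end_site = raw$end_site,
    start_bp = alignment$bp[raw$start_site + 1L],
    end_bp = alignment$bp[raw$end_site + 1L],
    start_cm = alignment$cm[raw$start_site + 1L],
    end_cm = alignment$cm[raw$end_site + 1L],
    stringsAsFactors = FALSE)
  out$length_cm <- out$end_cm - out$start_cm
  out <- out[order(raw$hap_a, raw$hap_b, out$start_site), ]
  rownames(out) <- NULL
  attr(out, "max_open_matches") <- attr(raw, "max_open_matches")
  out
}

#' Compute in-sample IBD segments
#'
#' Runs the TPBWT sweep over all haplotypes of one alignment and reports
#' every maximal merged match of genetic length at least `params$L_f`
#' between haplotypes of distinct individuals (within-individual pairs are
#' excluded unless `params$include_self_pairs`). Trailing matches reaching
#' the final site are reported after the sweep. Output rows are ordered by
#' haplotype pair and start site.
#'
#' @param alignment a [haplotype_alignment()].
#' @param templates a [template_set()]; default [default_templates()].
#' @param params a [tpbwt_params()].
#' @return A segment data frame (see [write_segments()] for columns).
#' @export
compute_ibd_in_sample <- function(alignment, templates = default_templates(),
                                  params = tpbwt_params()) {
  validate_alignment(alignment)
  stopifnot(inherits(templates, "template_set"), inherits(params, "tpbwt_params"))
  raw <- tpbwt_sweep_cpp(raw_alleles(alignment), alignment$cm,
                         templates$masks, params$L_m, params$L_f, params$M_t,
                         params$phase_correction, params$include_self_pairs, 0L)
  segments_from_raw(raw, alignment)
}

#' Compute out-of-sample IBD segments between two panels
#'
#' Sweeps both sample sets together and reports only the segments shared
#' across them; matches within either set are traversed for ordering but
#' never stored, so the current-match bookkeeping grows with
#' `M_X * M_Y` rather than `(M_X + M_Y)^2`. Both inputs must carry the
#' same sites (chromosome and bp positions) and, if panels, the same
#' template set. `id1` always comes from `x`, `id2` from `y`. With phase
#' correction on, corrections use only cross-panel evidence, so results
#' may legitimately differ from an in-sample run on the union.
#'
#' @param x,y [haplotype_alignment()]s or [compress_panel()] panels.
#' @param templates a [template_set()]; when both inputs are panels their
#'   embedded template set is used and must agree.
#' @param params a [tpbwt_params()].
#' @return A segment data frame; attribute `max_open_matches` records the
#'   peak number of stored cross-pair matches.
#' @export
compute_ibd_out_of_sample <- function(x, y, templates = default_templates(),
                                      params = tpbwt_params()) {
  if (inherits(x, "tpbwt_panel") && inherits(y, "tpbwt_panel")) {
    if (!identical(x$templates$masks, y$templates$masks))
      stop("panels were built with different template sets")
    templates <- x$templates
  } else if (inherits(x, "tpbwt_panel")) {
    templates <- x$templates
  } else if (inherits(y, "tpbwt_panel")) {
    templates <- y$templates
  }
  ax <- if (inherits(x, "tpbwt_panel")) decompress_panel(x) else x
  ay <- if (inherits(y, "tpbwt_panel")) decompress_panel(y) else y
  validate_alignment(ax); validate_alignment(ay)
  if (!identical(ax$chromosome, ay$chromosome))
    stop("panels are on different chromosomes")
  if (!identical(ax$bp, ay$bp))
    stop("panels do not share the same sites; subset_sites() them first")
  comb <- haplotype_alignment(rbind(ax$alleles, ay$alleles), ax$bp, ax$cm,
                              c(ax$sample_ids, ay$sample_ids), ax$chromosome)
  raw <- tpbwt_sweep_cpp(raw_alleles(comb), comb$cm, templates$masks,
                         params$L_m, params$L_f, params$M_t,
                         params$phase_correction, params$include_self_pairs,
                         n_haplotypes(ax))
  segments_from_raw(raw, comb)
}
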