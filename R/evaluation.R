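#' Segment-length bins for binned error rates
#'
#' The default bins are 3-4, 4-5, 5-6, 7-8, 9-10, 10-11, 12-15, 15-18 and
#' over-18 cM, half-open `[lo, hi)` with the last bin unbounded; segments whose
#' length falls in the gaps (6-7, 8-9, 11-12 cM) are excluded from binned
#' rates. `contiguous = TRUE` fills the gaps instead.
#'
#' @param contiguous use gap-free bins.
#' @return Data frame with columns `lo`, `hi`, `label`.
#' @export
ibd_length_bins <- function(contiguous = FALSE) {
  if (contiguous) {
    lo <- c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 15, 18)
    hi <- c(4, 5, 6, 7, 8, 9, 10, 11, 12, 15, 18, Inf)
  } else {
    lo <- c(3, 4, 5, 7, 9, 10, 12, 15, 18)
    hi <- c(4, 5, 6, 8, 10, 11, 15, 18, Inf)
  }
  data.frame(lo = lo, hi = hi,
             label = ifelse(is.finite(hi), sprintf("%g-%g", lo, hi),
                            sprintf(">%g", lo)))
}

bin_index <- function(length_cm, bins) {
  idx <- rep(NA_integer_, length(length_cm))
  for (b in seq_len(nrow(bins))) {
    inb <- length_cm >= bins$lo[b] & length_cm < bins$hi[b]
    idx[inb] <- b
  }
  idx
}

pair_key <- function(id1, id2) {
  paste(pmin(id1, id2), pmax(id1, id2), sep = "\r")
}

# union of [start_site, end_site] intervals, closing gaps of fewer than
# `collapse_gap_sites` sites; returns number of components
n_tracts <- function(start_site, end_site, collapse_gap_sites) {
  if (length(start_site) == 0) return(0L)
  o <- order(start_site, end_site)
  s <- start_site[o]; e <- end_site[o]
  n <- 1L
  reach <- e[1]
  for (i in seq_along(s)[-1]) {
    gap <- s[i] - reach - 1L
    if (gap > 0L && gap >= collapse_gap_sites) n <- n + 1L
    reach <- max(reach, e[i])
  }
  n
}

# merge same-haplotype-pair truth segments separated by gaps below the
# caller's merge resolution; mirrors what any L_m-merging caller reports
collapse_segments <- function(seg, collapse_gap_sites) {
  if (nrow(seg) <= 1 || collapse_gap_sites <= 0) return(seg)
  key <- paste(seg$id1, seg$id2, seg$hap1, seg$hap2, sep = "\r")
  out <- lapply(split(seg, key), function(d) {
    d <- d[order(d$start_site), , drop = FALSE]
    if (nrow(d) > 1) {
      gap <- d$start_site[-1] - d$end_site[-nrow(d)] - 1L
      grp <- cumsum(c(TRUE, !(gap < collapse_gap_sites)))
      starts <- which(!duplicated(grp))
      ends <- c(starts[-1] - 1L, nrow(d))
      d2 <- d[starts, , drop = FALSE]
      d2$end_site <- d$end_site[ends]
      d2$end_bp <- d$end_bp[ends]
      d2$end_cm <- d$end_cm[ends]
      d2$length_cm <- d2$end_cm - d2$start_cm
      d <- d2
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-pair IBD summary statistics
#'
#' For each individual pair, computes the true and estimated total IBD
#' length (`lambda`, `lambda_hat`; cM, summed over haplotype combinations,
#' so fully IBD2 regions count twice and totals can reach `2 * gamma`) and
#' the true and estimated IBD tract counts (`eta`, `eta_hat`).
#'
#' Counting convention: a caller that merges subsegment gaps below `L_m`
#' sites cannot resolve truth gaps below that size, so before counting,
#' truth segments on the same haplotype pair separated by fewer than
#' `collapse_gap_sites` sites are merged (gap length included, as the
#' caller includes it), and tract counts on both sides are connected
#' components of the pair-level intervals under the same gap closure.
#' Truth tracts shorter than `min_cm` (the caller's reporting floor) are
#' dropped. Set `collapse_gap_sites = 0` for raw counts.
#'
#' @param truth true segment data frame (needs `id1`, `id2`, `hap1`,
#'   `hap2`, site and cm columns).
#' @param estimated estimated segment data frame.
#' @param gamma_cm genome length in cM.
#' @param pairs data frame `id1`, `id2` of pairs to summarize; defaults to
#'   all pairs present in `truth`.
#' @param min_cm minimum segment length considered, matching the caller's
#'   `L_f`; default 3.
#' @param collapse_gap_sites gap-closure resolution in sites, matching the
#'   caller's `L_m`; default 0 (no closure).
#' @return Data frame with one row per pair: `id1`, `id2`, `lambda`,
#'   `lambda_hat`, `eta`, `eta_hat`, `gamma`.
#' @export
pair_summary <- function(truth, estimated, gamma_cm, pairs = NULL,
                         min_cm = 3, collapse_gap_sites = 0L) {
  if (gamma_cm <= 0) stop("gamma_cm must be > 0")
  if (is.null(pairs)) {
    pairs <- unique(truth[, c("id1", "id2")])
  }
  truth <- collapse_segments(truth, collapse_gap_sites)
  truth <- truth[truth$length_cm >= min_cm, , drop = FALSE]
  estimated <- estimated[estimated$length_cm >= min_cm, , drop = FALSE]
  tk <- pair_key(truth$id1, truth$id2)
  ek <- pair_key(estimated$id1, estimated$id2)
  out <- pairs
  out$lambda <- out$lambda_hat <- numeric(nrow(pairs))
  out$eta <- out$eta_hat <- integer(nrow(pairs))
  out$gamma <- gamma_cm
  for (p in seq_len(nrow(pairs))) {
    k <- pair_key(pairs$id1[p], pairs$id2[p])
    tr <- truth[tk == k, , drop = FALSE]
    es <- estimated[ek == k, , drop = FALSE]
    out$lambda[p] <- sum(tr$length_cm)
    out$lambda_hat[p] <- sum(es$length_cm)
    out$eta[p] <- n_tracts(tr$start_site, tr$end_site, collapse_gap_sites)
    out$eta_hat[p] <- n_tracts(es$start_site, es$end_site, collapse_gap_sites)
  }
  out[, c("id1", "id2", "lambda", "lambda_hat", "eta", "eta_hat", "gamma")]
}

#' Signed error in the estimated genome fraction that is IBD
#'
#' `(lambda_hat - lambda) / gamma`: the proportion of the genome
#' erroneously inferred (positive) or missed (negative) as IBD for a pair.
#'
#' @param summary a [pair_summary()] row or data frame (vectorized).
#' @return Numeric vector of signed fractions.
#' @export
genome_fraction_error <- function(summary) {
  if (any(summary$gamma <= 0)) stop("gamma must be > 0")
  (summary$lambda_hat - summary$lambda) / summary$gamma
}

#' Signed error in the estimated IBD segment count
#'
#' `eta_hat - eta` for each pair.
#'
#' @param summary a [pair_summary()] row or data frame (vectorized).
#' @return Integer vector of signed count errors.
#' @export
segment_count_error <- function(summary) {
  summary$eta_hat - summary$eta
}

# total length of `iv` (2-col matrix lo,hi) covered by intervals in `by`
covered_length <- function(lo, hi, by_lo, by_hi) {
  if (length(by_lo) == 0) return(0)
  clo <- pmax(lo, by_lo); chi <- pmin(hi, by_hi)
  keep <- chi > clo
  if (!any(keep)) return(0)
  clo <- clo[keep]; chi <- chi[keep]
  o <- order(clo)
  clo <- clo[o]; chi <- chi[o]
  tot <- 0; cur_lo <- clo[1]; cur_hi <- chi[1]
  for (i in seq_along(clo)[-1]) {
    if (clo[i] > cur_hi) {
      tot <- tot + cur_hi - cur_lo
      cur_lo <- clo[i]; cur_hi <- chi[i]
    } else cur_hi <- max(cur_hi, chi[i])
  }
  tot + cur_hi - cur_lo
}

#' Binned false negative and false positive IBD rates
#'
#' Four rate vectors over segment-length bins, following the segment /
#' coverage distinction. With true segments `T` and estimated segments `E`
#' (matched on the individual pair, haplotypes ignored; any positive cM
#' overlap counts):
#' * FN by segment: proportion of true segments in a bin overlapping no
#'   estimated segment.
#' * FN by coverage: proportion of the length of true segments in a bin
#'   not covered by any estimated segment.
#' * FP by segment: number of estimated segments in a bin overlapping no
#'   true segment, divided by the total number of true segments in the bin
#'   (`fp_denominator = "estimated"` divides by estimated counts instead).
#' * FP by coverage: length of estimated segments in a bin not covered by
#'   any true segment, divided by the total length of true segments in the
#'   bin (or of estimated segments, under the alternative denominator).
#'
#' Bins with an empty denominator yield `NA`, not 0.
#'
#' @param truth,estimated segment data frames.
#' @param bins a [ibd_length_bins()] data frame.
#' @param fp_denominator `"true"` (as printed) or `"estimated"`.
#' @return Data frame: bin columns plus `fn_segment`, `fn_coverage`,
#'   `fp_segment`, `fp_coverage`, `n_true`, `n_estimated`.
#' @export
fn_fp_rates <- function(truth, estimated, bins = ibd_length_bins(),
                        fp_denominator = c("true", "estimated")) {
  fp_denominator <- match.arg(fp_denominator)
  tk <- pair_key(truth$id1, truth$id2)
  ek <- pair_key(estimated$id1, estimated$id2)
  tbin <- bin_index(truth$length_cm, bins)
  ebin <- bin_index(estimated$length_cm, bins)
  t_hit <- logical(nrow(truth)); t_cov <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    es <- which(ek == tk[i])
    ov <- es[estimated$start_cm[es] < truth$end_cm[i] &
               estimated$end_cm[es] > truth$start_cm[i]]
    t_hit[i] <- length(ov) > 0
    t_cov[i] <- covered_length(truth$start_cm[i], truth$end_cm[i],
                               estimated$start_cm[ov], estimated$end_cm[ov])
  }
  e_hit <- logical(nrow(estimated)); e_cov <- numeric(nrow(estimated))
  for (i in seq_len(nrow(estimated))) {
    tr <- which(tk == ek[i])
    ov <- tr[truth$start_cm[tr] < estimated$end_cm[i] &
               truth$end_cm[tr] > estimated$start_cm[i]]
    e_hit[i] <- length(ov) > 0
    e_cov[i] <- covered_length(estimated$start_cm[i], estimated$end_cm[i],
                               truth$start_cm[ov], truth$end_cm[ov])
  }
  out <- bins
  out$n_true <- out$n_estimated <- integer(nrow(bins))
  out$fn_segment <- out$fn_coverage <- out$fp_segment <- out$fp_coverage <-
    rep(NA_real_, nrow(bins))
  for (b in seq_len(nrow(bins))) {
    ti <- which(tbin == b); ei <- which(ebin == b)
    out$n_true[b] <- length(ti); out$n_estimated[b] <- length(ei)
    t_len <- sum(truth$length_cm[ti])
    e_len <- sum(estimated$length_cm[ei])
    if (length(ti) > 0) {
      out$fn_segment[b] <- sum(!t_hit[ti]) / length(ti)
      if (t_len > 0)
        out$fn_coverage[b] <- (t_len - sum(t_cov[ti])) / t_len
    }
    n_den <- if (fp_denominator == "true") length(ti) else length(ei)
    l_den <- if (fp_denominator == "true") t_len else e_len
    if (length(ei) > 0 && n_den > 0)
      out$fp_segment[b] <- sum(!e_hit[ei]) / n_den
    if (length(ei) > 0 && l_den > 0)
      out$fp_coverage[b] <- (e_len - sum(e_cov[ei])) / l_den
  }
  out
}

#' Trio validation of IBD segments
#'
#' A segment shared between a child and a distant relative is "trio
#' validated" if the relative also shares at least one overlapping segment
#' with one or more of the child's parents. Per length bin, `hmean` is the
#' proportion of child-relative segments that were trio validated.
#'
#' @param child_vs_relative segments between children and relatives.
#' @param parents_vs_relative segments between parents and relatives.
#' @param trios data frame `child`, `parent1`, `parent2`.
#' @param bins a [ibd_length_bins()] data frame.
#' @return Data frame: bin columns plus `hmean`, `n_total`, `n_validated`.
#'   Segments whose child has no parents in `trios` are skipped with a
#'   warning.
#' @export
trio_validation <- function(child_vs_relative, parents_vs_relative, trios,
                            bins = ibd_length_bins()) {
  seg <- child_vs_relative
  is_child1 <- seg$id1 %in% trios$child
  is_child2 <- seg$id2 %in% trios$child
  known <- is_child1 | is_child2
  if (any(!known)) {
    warning(sum(!known), " segment(s) skipped: child not present in trios")
    seg <- seg[known, , drop = FALSE]
    is_child1 <- is_child1[known]
  }
  if (nrow(seg) == 0) {
    out <- bins
    out$hmean <- NA_real_; out$n_total <- out$n_validated <- 0L
    return(out)
  }
  child <- ifelse(is_child1, seg$id1, seg$id2)
  relative <- ifelse(is_child1, seg$id2, seg$id1)
  trow <- match(child, trios$child)
  pk <- pair_key(parents_vs_relative$id1, parents_vs_relative$id2)
  validated <- vapply(seq_len(nrow(seg)), function(i) {
    keys <- pair_key(c(trios$parent1[trow[i]], trios$parent2[trow[i]]),
                     c(relative[i], relative[i]))
    cand <- which(pk %in% keys)
    any(parents_vs_relative$start_cm[cand] < seg$end_cm[i] &
          parents_vs_relative$end_cm[cand] > seg$start_cm[i])
  }, logical(1))
  sbin <- bin_index(seg$length_cm, bins)
  out <- bins
  out$n_total <- out$n_validated <- integer(nrow(bins))
  out$hmean <- NA_real_
  for (b in seq_len(nrow(bins))) {
    si <- which(sbin == b)
    out$n_total[b] <- length(si)
    out$n_validated[b] <- sum(validated[si])
    if (length(si) > 0) out$hmean[b] <- mean(validated[si])
  }
  out[, c("lo", "hi", "label", "hmean", "n_total", "n_validated")]
}
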