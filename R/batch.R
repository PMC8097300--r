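#' Plan the jobs of a batched in-sample analysis
#'
#' Splitting `M` haplotypes into `b` batches requires `b` in-sample
#' computes (each also writing a compressed panel) followed by
#' `choose(b, 2)` out-of-sample comparisons between batch panels; with
#' `b = 20` that is 190 cross jobs. All jobs are independent and can be
#' dispatched in parallel externally.
#'
#' @param b number of batches.
#' @return Data frame `job` (`"in_sample"` / `"out_of_sample"`), `batch1`,
#'   `batch2` (`NA` for in-sample jobs).
#' @export
batch_plan <- function(b) {
  b <- as.integer(b)
  if (b < 1L) stop("need at least one batch")
  ins <- data.frame(job = "in_sample", batch1 = seq_len(b), batch2 = NA_integer_,
                    stringsAsFactors = FALSE)
  if (b == 1L) return(ins)
  cross <- t(utils::combn(b, 2L))
  rbind(ins, data.frame(job = "out_of_sample", batch1 = cross[, 1],
                        batch2 = cross[, 2], stringsAsFactors = FALSE))
}

#' Batched in-sample IBD over several sample batches
#'
#' Computes IBD within each batch, then between every pair of batches via
#' the out-of-sample sweep, and merges the segment tables. All batches
#' must share the same sites. With phase correction off, the merged output
#' equals a direct single in-sample run over the pooled samples; with
#' correction on, cross-batch jobs see only cross-batch evidence, so
#' results can differ (documented in the methods vignette).
#'
#' @param batches list of [haplotype_alignment()]s over identical sites.
#' @param templates a [template_set()].
#' @param params a [tpbwt_params()].
#' @param panel_dir optional directory; when given, each batch's compressed
#'   panel is written there as `batch<i>.tpbwt`.
#' @return Merged segment data frame.
#' @export
run_batched_in_sample <- function(batches, templates = default_templates(),
                                  params = tpbwt_params(), panel_dir = NULL) {
  if (!is.list(batches) || length(batches) < 1L)
    stop("batches must be a non-empty list of alignments")
  b <- length(batches)
  for (i in seq_len(b)) {
    validate_alignment(batches[[i]])
    if (!identical(batches[[i]]$bp, batches[[1]]$bp) ||
        !identical(batches[[i]]$chromosome, batches[[1]]$chromosome))
      stop("batch ", i, " does not share sites with batch 1")
  }
  if (!is.null(panel_dir)) {
    for (i in seq_len(b))
      write_panel(compress_panel(batches[[i]], templates),
                  file.path(panel_dir, sprintf("batch%d.tpbwt", i)))
  }
  out <- lapply(seq_len(b), function(i)
    compute_ibd_in_sample(batches[[i]], templates, params))
  if (b > 1L) {
    cross <- t(utils::combn(b, 2L))
    for (r in seq_len(nrow(cross))) {
      out[[length(out) + 1L]] <-
        compute_ibd_out_of_sample(batches[[cross[r, 1]]], batches[[cross[r, 2]]],
                                  templates, params)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$id1, res$id2, res$hap1, res$hap2, res$start_site), ]
  rownames(res) <- NULL
  res
}
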