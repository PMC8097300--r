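#' TPBWT sweep parameters
#'
#' @param L_m minimum subsegment length in sites. A matching subsegment
#'   must span at least `L_m` sites (of the full alignment, not per-template
#'   processed sites) to be emitted; gaps of fewer than `L_m` sites between
#'   subsegments of the same haplotype pair are merged. Default 200.
#' @param L_f minimum reported segment length in cM
#'   (`cm[end] - cm[start]`). Default 3.0.
#' @param M_t maximum run of consecutive missing sites (as seen by a
#'   template) a match is extended through before it is terminated.
#'   Default 10.
#' @param phase_correction apply the phase switch correction heuristic.
#'   Default `TRUE`.
#' @param include_self_pairs report within-individual (ROH-like) matches
#'   between an individual's own two haplotypes. Default `FALSE`.
#' @param haploid treat the data as haploid: disables phase correction
#'   (there is no complementary haplotype to swap). Default `FALSE`.
#' @return An object of class `"tpbwt_params"`.
#' @export
tpbwt_params <- function(L_m = 200L, L_f = 3.0, M_t = 10L,
                         phase_correction = TRUE,
                         include_self_pairs = FALSE,
                         haploid = FALSE) {
  L_m <- as.integer(L_m); M_t <- as.integer(M_t); L_f <- as.numeric(L_f)
  if (L_m < 1L) stop("L_m must be >= 1")
  if (L_f < 0) stop("L_f must be >= 0")
  if (M_t < 0L) stop("M_t must be >= 0")
  structure(list(L_m = L_m, L_f = L_f, M_t = M_t,
                 phase_correction = isTRUE(phase_correction) && !isTRUE(haploid),
                 include_self_pairs = isTRUE(include_self_pairs),
                 haploid = isTRUE(haploid)),
            class = "tpbwt_params")
}
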