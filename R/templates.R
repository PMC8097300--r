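#' Construct a template set
#'
#' Templates are repeating binary masks over sites: template `j` processes
#' site `k` iff `masks[j, (k mod period) + 1] == 1`. Masked sites are
#' skipped by that template, so an error at a masked site cannot terminate
#' its matches. Every residue class must be processed by at least one
#' template.
#'
#' @param masks binary matrix, templates in rows, one column per position
#'   of the repeating cycle.
#' @return An object of class `"template_set"` with fields `t`, `period`,
#'   `masks`.
#' @export
template_set <- function(masks) {
  masks <- as.matrix(masks)
  storage.mode(masks) <- "integer"
  if (!all(masks %in% c(0L, 1L))) stop("masks must be binary")
  if (nrow(masks) < 1L) stop("need at least one template")
  if (any(colSums(masks) == 0L))
    stop("every cycle position must be processed by at least one template")
  structure(list(t = nrow(masks), period = ncol(masks), masks = masks),
            class = "template_set")
}

#' The default six-template arrangement
#'
#' Six period-4 masks processing two of every four sites:
#' `0101, 1010, 0011, 1100, 0110, 1001` (1 = process, 0 = mask). Their
#' masked-position pairs cover all \eqn{C(4,2) = 6} ways two errors can
#' fall in a four-site window, so any match interrupted by at most two
#' errors within any four-site window survives in at least one template.
#' Each residue class is processed by exactly three of the six templates.
#'
#' @return A [template_set()] with `t = 6`, `period = 4`.
#' @export
default_templates <- function() {
  template_set(rbind(
    c(0L, 1L, 0L, 1L),
    c(1L, 0L, 1L, 0L),
    c(0L, 0L, 1L, 1L),
    c(1L, 1L, 0L, 0L),
    c(0L, 1L, 1L, 0L),
    c(1L, 0L, 0L, 1L)))
}

#' Single all-sites template (plain PBWT)
#'
#' With one template that processes every site, the sweep collapses to the
#' positional Burrows-Wheeler transform: exact IBS matching with no error
#' tolerance.
#'
#' @return A [template_set()] with `t = 1`, `period = 1`.
#' @export
pbwt_templates <- function() template_set(matrix(1L, 1L, 1L))

#' Number of templates needed for an error guarantee
#'
#' `choose(n, k)` templates are required to guarantee that every match
#' across any window of `n` sites survives at most `k` errors in the
#' window (one template per way of masking the k error positions).
#'
#' @param window_n window size in sites.
#' @param max_errors_k maximum number of errors per window to tolerate.
#' @return Integer template count.
#' @export
template_count <- function(window_n, max_errors_k) {
  if (length(window_n) != 1L || length(max_errors_k) != 1L)
    stop("scalar arguments expected")
  if (max_errors_k < 0 || window_n < 0) stop("n and k must be non-negative")
  if (max_errors_k > window_n) stop("k must not exceed n")
  as.integer(round(choose(window_n, max_errors_k)))
}

#' Probability of exactly j errors in an n-site window
#'
#' Binomial probability mass `C(n, j) p^j (1 - p)^(n - j)` under
#' independent per-site errors at rate `p`. With `p = 0.001`, the
#' probability of three errors in a four-site window — the event the
#' default templates do not protect against — is 3.996e-9.
#'
#' @param n window size in sites.
#' @param j number of errors.
#' @param p per-site error probability.
#' @return Probability.
#' @export
binomial_error_probability <- function(n, j, p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (j < 0 || j > n) stop("j must be in [0, n]")
  dbinom(j, size = n, prob = p)
}
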