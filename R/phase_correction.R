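#' Classify a pair of adjacent IBD matches
#'
#' Given an existing match and a newly found match between the same two
#' individuals `P` and `Q`, decides which scenario best explains their
#' arrangement. A new segment that begins within `tolerance_sites` of the
#' old segment's end (small gap or small overlap) and extends beyond it is
#' "adjacent"; the haplotypes it sits on then determine the label:
#' same haplotypes in both individuals -> `merge_same` (fragments of one
#' segment broken by error); complementary haplotype in both ->
#' `switch_both`; same in `P` but complementary in `Q` -> `switch_Q`;
#' complementary in `P` only -> `switch_P`. Anything else is `unrelated`.
#'
#' This is the decision table the sweep applies internally while merging
#' current matches; it is exposed for inspection and testing.
#'
#' @param existing list/row with `hapP`, `hapQ` (0/1 within-individual
#'   labels), `start`, `end` (site indices).
#' @param new same structure for the newly found match.
#' @param tolerance_sites adjacency tolerance in sites; the sweep uses
#'   `L_m`.
#' @return One of `"merge_same"`, `"switch_both"`, `"switch_P"`,
#'   `"switch_Q"`, `"unrelated"`.
#' @export
classify_adjacent_segments <- function(existing, new, tolerance_sites) {
  for (f in c("hapP", "hapQ", "start", "end")) {
    if (is.null(existing[[f]]) || is.null(new[[f]]))
      stop("matches need fields hapP, hapQ, start, end")
  }
  if (!all(c(existing$hapP, existing$hapQ, new$hapP, new$hapQ) %in% 0:1))
    stop("haplotype labels must be 0 or 1")
  adjacent <- new$start >= existing$end - tolerance_sites &&
    new$start <= existing$end + tolerance_sites &&
    new$end > existing$end
  if (!adjacent) return("unrelated")
  same_p <- new$hapP == existing$hapP
  same_q <- new$hapQ == existing$hapQ
  if (same_p && same_q) "merge_same"
  else if (!same_p && !same_q) "switch_both"
  else if (same_p) "switch_Q"
  else "switch_P"
}

#' Create a per-individual phase swap state
#'
#' Tracks, for every individual, whether its two haplotypes are currently
#' logically exchanged and where the last inferred switch occurred.
#'
#' @param n_individuals number of individuals.
#' @return An object of class `"swap_state"`.
#' @export
new_swap_state <- function(n_individuals) {
  structure(list(swapped = rep(FALSE, n_individuals),
                 last_switch_site = rep(NA_integer_, n_individuals)),
            class = "swap_state")
}

#' Toggle an individual's haplotype orientation at a site
#'
#' From `site` onward the individual's two haplotypes are logically
#' exchanged for all templates; toggling twice restores the original
#' orientation. Inside the sweep this is what stitches segments across an
#' inferred phase switch: matches keyed to the pre-switch haplotype label
#' simply continue on the swapped rows.
#'
#' @param state a [new_swap_state()].
#' @param individual 1-based individual index.
#' @param site 0-based site index of the inferred switch.
#' @return The updated `swap_state`.
#' @export
apply_phase_switch <- function(state, individual, site) {
  stopifnot(inherits(state, "swap_state"))
  if (individual < 1L || individual > length(state$swapped))
    stop("individual index out of range")
  state$swapped[individual] <- !state$swapped[individual]
  state$last_switch_site[individual] <- as.integer(site)
  state
}
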