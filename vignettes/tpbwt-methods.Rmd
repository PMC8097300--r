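---
title: "Methods: templated PBWT IBD inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: templated PBWT IBD inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpbwt)
```

## The problem

Two individuals who inherited a chromosomal segment from a common ancestor
carry identical alleles over that segment: it is identical by descent
(IBD). Detecting IBD segments from phased genotypes is a core step in
relatedness estimation, pedigree reconstruction and demographic inference,
but two kinds of error fragment the signal. A *genotyping error* flips a
single allele and terminates any exact haplotype match crossing it. A
*phase switch error* — a statistical-phasing mistake — exchanges the
maternal/paternal assignment of all downstream alleles, so every IBD
segment spanning the switch is split into two fragments that sit on
complementary haplotypes of the mis-phased individual. Fragments below the
caller's reporting floor are dropped, which simultaneously underestimates
the total IBD fraction and overestimates the segment count.

## The sweep

The positional Burrows–Wheeler transform (PBWT) finds all exact
identical-by-state runs among `M` haplotypes at `N` sites in a single
left-to-right pass: at each site it keeps the haplotypes sorted by
reversed prefix (the positional prefix array, `ppa`) together with the
site at which each adjacent pair's match began (the divergence array,
`div`). This package extends that pass with a third dimension of `t`
repeating binary *templates*. Template `j` processes site `k` only when
`masks[j, k mod period] = 1`; an error at a masked site is invisible to
that template, so the match survives there. Each template maintains its
own `ppa`/`div` columns, and the fragments all templates emit feed one
shared pair of current-match arrays (`Ps`/`Pe`), where overlapping
fragments merge into maximal segments. With a single all-sites template
the sweep *is* the PBWT, which is both a design statement and a test
oracle (`pbwt_templates()`).

The default arrangement (`default_templates()`) is six period-4 masks,
`0101, 1010, 0011, 1100, 0110, 1001`; their masked-position pairs
enumerate all `choose(4, 2) = 6` ways two errors can fall within a
four-site window, so any match broken by at most two errors in any such
window survives in at least one template. The unprotected event — three
errors in a four-site window — has probability
`binomial_error_probability(4, 3, 0.001)` = 4 × 0.001³ × 0.999 ≈ 4.0e-9
at a typical microarray error rate. In general `template_count(n, k)`
templates guarantee windows of `n` sites against `k` errors; more
templates buy robustness at a linear cost in time (`O(N M t)` worst case,
roughly halved with the defaults because each template processes two of
every four sites).

### Tunable parameters

* `L_m` (sites, default 200): a matching subsegment must span at least
  `L_m` sites of the full alignment to be emitted, and two subsegments of
  the same haplotype pair separated by a gap of fewer than `L_m` sites are
  merged. One parameter plays both roles deliberately: gaps are typically
  the corpses of fragments that fell below the emission floor, so the
  merge tolerance should equal that floor.
* `L_f` (cM, default 3.0): minimum genetic length for a segment to be
  reported, measured site-anchored as `cm[end] − cm[start]`. `L_m` may be
  kept sensitive (low) while `L_f` suppresses short identical-by-state
  runs that are not IBD.
* `M_t` (default 10): maximum run of consecutive missing sites a match is
  extended through. Missing alleles are imputed locally per template from
  the `ppa` neighbour with the longer current match (the smaller
  divergence; ties prefer the predecessor). Because masked sites are
  invisible to a template, the run is counted in each template's own
  processed sites. When the run exceeds `M_t` the haplotype's matches are
  terminated; the pseudo-formal description of the sweep leaves the
  termination mechanics open, and we emit the dying matches against the
  haplotype's current sorted block before isolating it, so no
  above-threshold fragment is silently lost.
* `phase_correction` (default on): the switch-repair heuristic below.
* Boundary convention: a block of haplotypes is split where
  `div > k − L_m`, so emitted fragments span at least `L_m` sites
  (an "at least `L_m`" reading rather than "more than `L_m`"; the
  difference is a single site and the choice matches the brute-force
  oracle the tests use).

## Phase correction

When a new fragment between individuals `P` and `Q` begins within `L_m`
sites of the end of an open match for the same pair and extends beyond it,
its haplotype placement is informative (`classify_adjacent_segments()`):
same haplotypes in both individuals — fragments of one segment broken by
error, merge; complementary in both — a switch in both; complementary in
exactly one — a switch in that individual. On an inferred switch the
implicated individual's two haplotype rows are logically exchanged *for
all templates* from that point on, and the fragment is merged onto the
open match, stitching the segment. Because the swap is global, a switch
detected through one pair repairs every segment that individual shares
with anyone — corrections are cohort-consistent, and triangulation
(A–B and A–C overlapping implies B–C overlapping) is preserved. Toggling
twice restores the original orientation, which is how the heuristic
"stops swapping" when the pattern recurs.

Two implementation details matter. First, reported haplotype labels are
the logical (post-correction) labels, which is exactly what stitching
means: before the switch they are the individual's original labels.
Second, after a toggle, templates whose internal state still reflects the
old labels re-emit the same physical match on the complementary slot; a
fragment contained in a complementary open match and starting within
`L_m` sites of that individual's last toggle is recognised as this
duplicate and absorbed rather than stored or allowed to re-toggle.
Without the absorb rule every stitched segment would be accompanied by a
spurious complementary copy.

The heuristic is applied to all pairs, including parent–child, where the
adjacency pattern can also be produced by *real* ancestral recombination:
a child's haplotype is a mosaic of one parent's two haplotypes, so at
every inherited crossover the child's sharing with a grandparent hops
between the grandparent's haplotypes contiguously. On error-free pedigree
data the corrector therefore fires at genuine junctions and stitches
abutting true segments together — it is *not* a no-op on clean related
data, only on data without such junctions. For haploid data
(`haploid = TRUE`) the heuristic is disabled; there is no complementary
haplotype to swap.

## Compressed panels and out-of-sample computes

At each processed site a template's sorted order groups haplotypes with
shared recent history, so linkage disequilibrium produces long
single-allele runs; `compress_panel()` records those runs per (site,
template) — a site covered by three templates is encoded three times.
The panel's orderings evolve by a fixed stable three-way partition
(0, 1, missing), independent of the sweep's neighbour imputation, so the
format is self-contained and `decompress_panel()` is exact. The binary
layout (`write_panel()`/`read_panel()`) is little-endian: magic `TPBW`,
version byte, `int32` M/N/t/period, mask bytes, length-prefixed
chromosome and sample ids, `int32` bp, `float64` cM, then per template
and processed site a varint run count followed by one ULEB128 varint per
run encoding `(length << 2) | symbol`.

For out-of-sample analysis (`compute_ibd_out_of_sample()`) two sample
sets are swept together but only cross-set matches are stored and
reported, so the current-match bookkeeping grows as `M_X × M_Y` rather
than `(M_X + M_Y)²` (the peak stored-pair count is exposed as the
`max_open_matches` attribute). The combined sorted order is the linear
sum of the two panels' orders — each panel's haplotypes keep their own
relative order — which is what allows alleles to be read only at run
starts of either panel; `merge_orderings()` implements and is tested for
exactly this property, while the segment path itself decompresses panels
and runs the compiled sweep (the correctness-first choice at the problem
sizes this package targets). Site intersection across genotyping chips is
deliberately explicit (`subset_sites()`), not automatic. With phase
correction on, out-of-sample corrections see only cross-panel evidence,
so results may legitimately differ from an in-sample run on the union;
the equivalence tests therefore run with correction off. Batched
in-sample analysis (`run_batched_in_sample()`, `batch_plan()`) composes
`b` in-sample jobs with `choose(b, 2)` cross jobs; all jobs are
independent and externally parallelisable.

## The pedigree simulator

`simulate_pedigree()` gene-drops founder haplotypes through a
three-generation pedigree: each transmission draws a crossover count from
Poisson(length/100 cM), places the crossovers uniformly, and splices the
parent's two haplotypes, tracking founder-haplotype ancestry exactly.
True IBD segments for the labeled pairs are maximal intervals where a
pair carries the same founder haplotype, snapped to sites with the same
site-anchored length convention the caller uses. The default pedigree is
the minimal one containing all five labeled relationship types
(parent–child, grandparent–grandchild, aunt–niece, first cousins,
siblings): one grandparent couple whose two children marry two founder
spouses, with three grandchildren.

Founders are drawn with independent sites at allele frequencies uniform
on (0.05, 0.95) — no linkage disequilibrium and no population structure.
All haplotype sharing in the simulation is therefore created by gene
dropping, which is what a correctness test needs; what passing tests do
*not* show is performance on real panels where background LD produces
long identical-by-state runs among nominally unrelated haplotypes, where
allele frequencies are skewed, and where switch errors cluster in
low-heterozygosity regions. The default problem size is 15,000 sites over
100 cM (150 sites/cM, the density regime of a dense genotyping array,
where `L_m = 200` sites ≈ 1.3 cM); evaluation runs use 20 replicate
pedigrees, chosen as the smallest design that separates the on/off
corrector comparison decisively.

Error injectors mirror the measurement model: `add_genotype_errors()`
flips one of the two alleles (equal probability) of a genotype with
probability 0.001 per call; `add_switch_errors()` toggles downstream
phase at each heterozygous site with probability 0.0025, reproducing a
0.25% switch error rate. Switches at homozygous sites are unobservable
and therefore not simulated; the direct injection reproduces the *rate*
of a statistical phaser's errors, not their spatial clustering.

## Evaluation conventions

Per-pair accuracy uses the summary statistics `λ` (true total IBD, cM,
summed over haplotype combinations, so IBD2 counts twice), `λ̂`, `η`
(true segment count) and `η̂`, with errors `(λ̂ − λ)/γ`
(`genome_fraction_error()`) and `η̂ − η` (`segment_count_error()`).
A caller that merges sub-`L_m` gaps cannot resolve truth gaps below that
size, and the phase corrector stitches truth segments that abut at
ancestral junctions; raw per-haplotype-pair truth counts would therefore
disagree with *any* faithful caller's output even on error-free input.
`pair_summary()` consequently counts *tracts*: truth segments on the same
haplotype pair separated by fewer than `collapse_gap_sites` (set to the
caller's `L_m`) are merged gap-inclusive, and `η`/`η̂` count connected
components of the pair-level intervals under the same gap closure,
applied symmetrically to truth and estimate. With
`collapse_gap_sites = 0` the raw counts are recovered.

Binned false negative / false positive rates (`fn_fp_rates()`) follow the
segment/coverage duality — proportion of segments with no overlapping
counterpart, and proportion of length not covered — over the length bins
3–4, 4–5, 5–6, 7–8, 9–10, 10–11, 12–15, 15–18, >18 cM (the gaps are kept;
`ibd_length_bins(contiguous = TRUE)` fills them). The FP denominators use
true-segment counts and lengths, with the estimated-segment alternative
exposed as an option. Overlap is judged on individual-pair cM intervals,
ignoring haplotype, and any positive overlap counts. Empty bins yield
`NA`, never 0. Trio validation (`trio_validation()`) labels a
child–relative segment validated when the relative also shares an
overlapping segment with at least one of the child's parents, and reports
the per-bin validated proportion (`hmean`) with counts.

## Numerical and degenerate-input choices

Sites are 0-based internally and in reported `start_site`/`end_site`;
reported bp are the (1-based) VCF POS values at the segment's first and
last site. Genetic positions come from linear interpolation of the
3-column genetic map, clamping outside the map range. Missing genotypes
are preserved at load and imputed only transiently inside the sweep. The
divergence sentinel for the first element of an allele class is the next
processed site ("no match yet"). Stable counting sort preserves prior
`ppa` order within allele classes, which PBWT correctness requires. Ties
in the missing-data neighbour rule prefer the predecessor. The sweep is
deterministic: identical input and parameters give identical output, and
all simulator randomness flows through R's seeded RNG.

## Known limitations

* The corrector's toggle dynamics around dense switch clusters can drop
  fragments shorter than `L_m` between two inferred switches; stitching
  then relies on the gap-merge tolerance.
* Founder haplotypes without LD make the false-positive regime of the
  tests optimistic relative to real panels.
* Out-of-sample mode never updates a stored panel with corrections
  discovered during a compare; panels are immutable.
* The worst-case `O(N M t)` complexity is a design property documented
  here rather than asserted by a timing test.
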