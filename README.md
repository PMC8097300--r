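# tpbwt

Error-robust identity-by-descent (IBD) inference from phased genotypes
with the templated positional Burrows–Wheeler transform (TPBWT), for
population and statistical geneticists who need phase-aware IBD segments
from biobank-style phased VCF panels — plus the simulation and evaluation
machinery to benchmark an IBD caller against known truth.

## The method

The PBWT finds all exact identical-by-state runs among *M* haplotypes at
*N* biallelic sites in one left-to-right pass by keeping, at each site
*k*, the haplotypes sorted by reversed prefix (positional prefix array
`ppa`) along with where each adjacent pair's match began (divergence
array `div`). Exactness makes it brittle: one genotyping error or phase
switch fragments long IBD segments.

The TPBWT sweeps an *N* × *M* × *t* structure instead: *t* repeating
binary *templates* mask out sites (template *j* processes site *k* iff
T(*j*, *k*) = 1), each template keeps its own `ppa`/`div` columns, and
the match fragments found under all templates are merged in shared
current-match arrays (P_s, P_e). The default six period-4 templates
(`∅h∅h, h∅h∅, ∅∅hh, hh∅∅, ∅hh∅, h∅∅h`) guarantee any match survives up to
two errors in any four-site window; in general C(n, k) templates protect
windows of *n* sites against *k* errors. A subsegment must span ≥ L_m
sites to be merged (default 200), gaps < L_m sites are closed, and
segments are reported when their genetic length reaches L_f cM (default
3.0). Missing alleles are extended through (up to M_t consecutive sites)
by locally matching the `ppa` neighbour with the longer current match.
While merging, a heuristic classifies adjacent fragments on complementary
haplotypes as phase switch errors and swaps the implicated individual's
haplotypes for all templates from that point on — corrections are
cohort-consistent, so one detected switch repairs every segment that
individual shares. With *t* = 1 and no masking the method collapses to
the PBWT (worst case O(*NMt*)).

The package also provides a run-length compressed haplotype panel format
(`.tpbwt`), out-of-sample comparison of new samples against a panel with
M_X × M_Y match bookkeeping, batched in-sample analysis, a gene-dropping
pedigree simulator (Poisson recombination, 1 crossover per 100 cM;
genotype-error and phase-switch injectors), and evaluation metrics:
per-pair errors (η̂ − η) and (λ̂ − λ)/γ, binned false positive/negative
rates by segment and by coverage, and trio validation (`hmean`).

## Worked example

Simulate a three-generation pedigree over a 100 cM chromosome
(15,000 sites), inject realistic noise (genotype errors at 0.001, phase
switches at 0.25% of het sites), call IBD, and score the calls against
the gene-dropping truth:

```r
library(tpbwt)
set.seed(7)
founders <- simulate_founders(4, n_sites = 15000, length_cm = 100)
sim      <- simulate_pedigree(default_pedigree(), founders)
noisy    <- add_switch_errors(add_genotype_errors(sim$alignment, 0.001),
                              0.0025)$alignment
segments <- compute_ibd_in_sample(noisy, default_templates(), tpbwt_params())
nrow(segments)
#> [1] 93
head(segments[segments$id1 == "P1" & segments$id2 == "C1",
              c("hap1","hap2","start_bp","end_bp","length_cm")], 4)
#>  hap1 hap2 start_bp    end_bp length_cm
#>     0    0        1  29055271 29.055270
#>     0    0 81352091 100000001 18.647910
#>     1    0 31508768  36902461  5.393693
#>     1    1 39502635  82805521 43.302887

st <- pair_summary(sim$truth, segments, gamma_cm = 100,
                   pairs = sim$pedigree$pairs[, c("id1", "id2")],
                   min_cm = 3, collapse_gap_sites = 200)
cbind(type = sim$pedigree$pairs$type,
      st[, c("lambda", "lambda_hat", "eta", "eta_hat")],
      gfe = round(genome_fraction_error(st), 4))
#>                    type    lambda lambda_hat eta eta_hat     gfe
#>            parent_child  99.98667   96.39976   1       3 -0.0359
#>  grandparent_grandchild  46.75645   48.30989   2       2  0.0155
#>              aunt_niece  88.95926   86.90579   2       4 -0.0205
#>           first_cousins  28.60191   25.10167   1       1 -0.0350
#>                siblings 118.62791  108.42056   1       3 -0.1021
```

Each segment row reports both individuals, their 0/1 haplotype labels,
0-based site extents, bp (VCF POS) and cM extents. In the summary,
`lambda` is the true total IBD in cM (haplotype-resolved, so fully-IBD2
sibling regions count twice and totals can exceed the 100 cM chromosome),
`lambda_hat` its estimate, `eta`/`eta_hat` the true and estimated IBD
tract counts, and `gfe = (lambda_hat - lambda) / gamma` the signed
genome-fraction error. Despite ~14 phase switches per individual the
caller recovers the totals to within a few percent of the genome;
disabling `phase_correction` roughly doubles the summed errors (see the
acceptance suite). The methods vignette
(`vignettes/tpbwt-methods.Rmd`) documents the algorithm, parameter
semantics, the evaluation counting conventions, and what the LD-free
simulator does and does not emulate.

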