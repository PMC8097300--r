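#' Simulate unrelated founder haplotypes
#'
#' Generates independent biallelic sites with allele frequencies drawn
#' uniformly from `maf_range`, evenly spaced on a linear genetic map
#' (about 1 Mb per cM). Founders carry no linkage disequilibrium — LD is
#' not needed for pedigree-based correctness tests, where all sharing is
#' created by gene dropping; see the methods vignette for what this does
#' and does not emulate.
#'
#' @param n_individuals number of founder individuals (two haplotypes each).
#' @param n_sites number of sites; default 15000, roughly chip-density
#'   (150 sites/cM) over the default chromosome.
#' @param length_cm chromosome genetic length in cM; default 100.
#' @param chromosome chromosome label.
#' @param maf_range range of per-site allele frequencies.
#' @return A [haplotype_alignment()] with sample ids `F1, F2, ...`.
#' @export
simulate_founders <- function(n_individuals, n_sites = 15000L,
                              length_cm = 100, chromosome = "1",
                              maf_range = c(0.05, 0.95)) {
  n_sites <- as.integer(n_sites)
  freqs <- runif(n_sites, maf_range[1], maf_range[2])
  M <- 2L * n_individuals
  alleles <- matrix(rbinom(M * n_sites, 1L, rep(freqs, each = M)), M, n_sites)
  cm <- seq(0, length_cm, length.out = n_sites)
  bp <- as.integer(round(cm * 1e6)) + 1L
  haplotype_alignment(alleles, bp, cm, paste0("F", seq_len(n_individuals)),
                      chromosome)
}

#' The default three-generation pedigree
#'
#' One grandparent couple whose two children (siblings) marry two founder
#' spouses; the first couple has two children and the second has one, so a
#' single pedigree contains at least one pair of each labeled relationship
#' type: parent-child, grandparent-grandchild, aunt-niece, first cousins
#' and siblings.
#'
#' @return A list with `members` (data frame `id`, `father`, `mother`;
#'   founders have `NA` parents) and `pairs` (data frame `type`, `id1`,
#'   `id2`).
#' @export
default_pedigree <- function() {
  members <- data.frame(
    id     = c("GF", "GM", "SP1", "SP2", "P1", "P2", "C1", "C2", "C3"),
    father = c(NA, NA, NA, NA, "GF", "GF", "P1", "P1", "P2"),
    mother = c(NA, NA, NA, NA, "GM", "GM", "SP1", "SP1", "SP2"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    type = c("parent_child", "grandparent_grandchild", "aunt_niece",
             "first_cousins", "siblings"),
    id1 = c("P1", "GF", "P2", "C1", "C1"),
    id2 = c("C1", "C1", "C1", "C3", "C2"),
    stringsAsFactors = FALSE)
  list(members = members, pairs = pairs)
}

#' Sample crossover positions along a chromosome
#'
#' Poisson model with 1 expected crossover per 100 cM: the crossover count
#' is `Poisson(length_cm / 100)` and positions are i.i.d. uniform along
#' the chromosome, returned sorted.
#'
#' @param length_cm chromosome length in cM.
#' @return Sorted numeric vector of crossover positions in (0, length_cm).
#' @export
sample_crossovers <- function(length_cm) {
  if (length_cm < 0) stop("length_cm must be >= 0")
  if (length_cm == 0) return(numeric(0))
  n <- rpois(1L, length_cm / 100)
  sort(runif(n, 0, length_cm))
}

restrict_track <- function(track, lo, hi) {
  keep <- track$end_cm > lo & track$start_cm < hi
  tr <- track[keep, , drop = FALSE]
  if (nrow(tr) > 0) {
    tr$start_cm <- pmax(tr$start_cm, lo)
    tr$end_cm <- pmin(tr$end_cm, hi)
  }
  tr
}

merge_track <- function(track) {
  if (nrow(track) <= 1) return(track)
  new_grp <- c(TRUE, track$founder_hap[-1] != track$founder_hap[-nrow(track)])
  starts <- which(new_grp)
  ends <- c(starts[-1] - 1L, nrow(track))
  data.frame(start_cm = track$start_cm[starts], end_cm = track$end_cm[ends],
             founder_hap = track$founder_hap[starts], row.names = NULL)
}

# one meiosis: recombine a parent's two haplotypes into a gamete
make_gamete <- function(hapA, hapB, trackA, trackB, cm) {
  L0 <- cm[1]; L1 <- cm[length(cm)]
  xo <- L0 + sample_crossovers(L1 - L0)
  start_phase <- sample(0:1, 1L)
  bounds <- c(L0, xo, L1 + 1e-9)
  phase <- (start_phase + seq_len(length(bounds) - 1L) - 1L) %% 2L
  site_iv <- findInterval(cm, bounds, rightmost.closed = FALSE)
  site_iv[site_iv < 1L] <- 1L
  site_phase <- phase[site_iv]
  allele <- ifelse(site_phase == 0L, hapA, hapB)
  pieces <- lapply(seq_along(phase), function(i) {
    src <- if (phase[i] == 0L) trackA else trackB
    restrict_track(src, bounds[i], bounds[i + 1L])
  })
  track <- merge_track(do.call(rbind, pieces))
  list(allele = as.integer(allele), track = track)
}

#' Gene-drop haplotypes over a pedigree
#'
#' Assigns founder haplotypes from `founders` to the pedigree founders,
#' then simulates each transmission by drawing crossovers
#' ([sample_crossovers()]) and splicing the parent's two haplotypes.
#' Founder-haplotype ancestry is tracked exactly for every transmitted
#' haplotype, so the true IBD segments for the labeled pairs are known
#' perfectly: a true segment is a maximal interval over which the pair
#' carries the same founder haplotype, on any combination of their
#' haplotypes.
#'
#' @param pedigree a pedigree as returned by [default_pedigree()].
#' @param founders a [haplotype_alignment()] with at least as many
#'   individuals as the pedigree has founders.
#' @return A list: `alignment` (all pedigree members, in `members` order),
#'   `truth` (true IBD segment data frame for the labeled pairs, with
#'   segment columns plus `type` and `founder_hap`), `tracks` (per member,
#'   per haplotype ancestry tracks), `pedigree`.
#' @export
simulate_pedigree <- function(pedigree = default_pedigree(), founders) {
  validate_alignment(founders)
  members <- pedigree$members
  is_founder <- is.na(members$father)
  n_founder <- sum(is_founder)
  if (length(founders$sample_ids) < n_founder)
    stop(sprintf("pedigree needs %d founder individuals, founders has %d",
                 n_founder, length(founders$sample_ids)))
  cm <- founders$cm
  N <- length(cm)
  n_mem <- nrow(members)
  alleles <- matrix(NA_integer_, 2L * n_mem, N)
  tracks <- vector("list", n_mem)
  names(tracks) <- members$id
  founder_idx <- 0L
  full_track <- function(label)
    data.frame(start_cm = cm[1], end_cm = cm[N] + 1e-9, founder_hap = label)
  for (m in seq_len(n_mem)) {
    if (is_founder[m]) {
      founder_idx <- founder_idx + 1L
      rows <- c(2L * founder_idx - 1L, 2L * founder_idx)
      alleles[2L * m - 1L, ] <- founders$alleles[rows[1], ]
      alleles[2L * m, ] <- founders$alleles[rows[2], ]
      tracks[[m]] <- list(full_track(rows[1] - 1L), full_track(rows[2] - 1L))
    } else {
      fa <- match(members$father[m], members$id)
      mo <- match(members$mother[m], members$id)
      if (is.na(fa) || is.na(mo) || fa >= m || mo >= m)
        stop("pedigree members must be listed parents-first")
      g_pat <- make_gamete(alleles[2L * fa - 1L, ], alleles[2L * fa, ],
                           tracks[[fa]][[1]], tracks[[fa]][[2]], cm)
      g_mat <- make_gamete(alleles[2L * mo - 1L, ], alleles[2L * mo, ],
                           tracks[[mo]][[1]], tracks[[mo]][[2]], cm)
      alleles[2L * m - 1L, ] <- g_pat$allele
      alleles[2L * m, ] <- g_mat$allele
      tracks[[m]] <- list(g_pat$track, g_mat$track)
    }
  }
  alignment <- haplotype_alignment(alleles, founders$bp, cm, members$id,
                                   founders$chromosome)
  truth <- true_ibd_segments(pedigree$pairs, tracks, alignment)
  list(alignment = alignment, truth = truth, tracks = tracks,
       pedigree = pedigree)
}

# shared-label intervals between two ancestry tracks
intersect_tracks <- function(t1, t2) {
  bounds <- sort(unique(c(t1$start_cm, t1$end_cm, t2$start_cm, t2$end_cm)))
  if (length(bounds) < 2) return(NULL)
  lo <- bounds[-length(bounds)]
  hi <- bounds[-1]
  mid <- (lo + hi) / 2
  lab1 <- t1$founder_hap[findInterval(mid, t1$start_cm)]
  lab2 <- t2$founder_hap[findInterval(mid, t2$start_cm)]
  shared <- !is.na(lab1) & !is.na(lab2) & lab1 == lab2
  if (!any(shared)) return(NULL)
  d <- data.frame(start_cm = lo[shared], end_cm = hi[shared],
                  founder_hap = lab1[shared])
  # merge contiguous pieces with the same label
  brk <- c(TRUE, d$start_cm[-1] > d$end_cm[-nrow(d)] + 1e-12 |
             d$founder_hap[-1] != d$founder_hap[-nrow(d)])
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, nrow(d))
  data.frame(start_cm = d$start_cm[starts], end_cm = d$end_cm[ends],
             founder_hap = d$founder_hap[starts], row.names = NULL)
}

#' True IBD segments for labeled pairs from ancestry tracks
#'
#' Intersects the ancestry tracks of every haplotype combination of each
#' labeled pair and snaps the shared intervals to sites. Segment genetic
#' length uses the same site-anchored convention as the caller
#' (`cm[end_site] - cm[start_site]`). No length filtering is applied here;
#' filtering happens in evaluation.
#'
#' @param pairs data frame `type`, `id1`, `id2`.
#' @param tracks per-member track list from [simulate_pedigree()].
#' @param alignment the members' [haplotype_alignment()].
#' @return True segment data frame (segment columns plus `type`,
#'   `founder_hap`).
#' @export
true_ibd_segments <- function(pairs, tracks, alignment) {
  cm <- alignment$cm
  N <- length(cm)
  L1 <- cm[N]
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    id1 <- pairs$id1[p]; id2 <- pairs$id2[p]
    for (h1 in 1:2) for (h2 in 1:2) {
      iv <- intersect_tracks(tracks[[id1]][[h1]], tracks[[id2]][[h2]])
      if (is.null(iv)) next
      for (r in seq_len(nrow(iv))) {
        s <- iv$start_cm[r]; e <- iv$end_cm[r]
        last <- abs(e - (L1 + 1e-9)) < 1e-6 || e >= L1
        keep <- cm >= s - 1e-9 & (if (last) cm <= e else cm < e - 1e-9)
        if (!any(keep)) next
        ks <- which(keep)
        out[[length(out) + 1L]] <- data.frame(
          type = pairs$type[p], id1 = id1, id2 = id2,
          hap1 = h1 - 1L, hap2 = h2 - 1L,
          chromosome = alignment$chromosome,
          start_site = ks[1] - 1L, end_site = ks[length(ks)] - 1L,
          start_bp = alignment$bp[ks[1]], end_bp = alignment$bp[ks[length(ks)]],
          start_cm = cm[ks[1]], end_cm = cm[ks[length(ks)]],
          length_cm = cm[ks[length(ks)]] - cm[ks[1]],
          founder_hap = iv$founder_hap[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    z <- cbind(data.frame(type = character()), empty_segments(),
               data.frame(founder_hap = integer()))
    return(z)
  }
  d <- do.call(rbind, out)
  d <- d[order(d$id1, d$id2, d$hap1, d$hap2, d$start_site), ]
  rownames(d) <- NULL
  d
}

#' Inject genotyping errors
#'
#' At each site of each individual, with probability `rate` the genotype
#' call receives an error: one of the two alleles, chosen with probability
#' 1/2 each, is flipped 0 <-> 1 (e.g. 0/0 becomes 1|0 or 0|1 with equal
#' probability). Missing alleles are left untouched.
#'
#' @param alignment a [haplotype_alignment()].
#' @param rate per-genotype error probability; default 0.001.
#' @return The perturbed alignment.
#' @export
add_genotype_errors <- function(alignment, rate = 0.001) {
  validate_alignment(alignment)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  a <- alignment$alleles
  n_ind <- nrow(a) / 2L; N <- ncol(a)
  hit <- which(matrix(runif(n_ind * N) < rate, n_ind, N), arr.ind = TRUE)
  if (nrow(hit) > 0) {
    hap <- rbinom(nrow(hit), 1L, 0.5)
    rows <- 2L * (hit[, 1] - 1L) + 1L + hap
    idx <- cbind(rows, hit[, 2])
    val <- a[idx]
    flip <- !is.na(val)
    a[idx[flip, , drop = FALSE]] <- 1L - val[flip]
  }
  haplotype_alignment(a, alignment$bp, alignment$cm, alignment$sample_ids,
                      alignment$chromosome)
}

#' Inject phase switch errors
#'
#' At each heterozygous site of each individual, with probability
#' `switch_rate`, the downstream phase is toggled: the suffixes of the two
#' haplotypes starting at that site are exchanged. Unordered genotypes are
#' unchanged — only the assignment of alleles to haplotypes is perturbed,
#' emulating statistical-phasing switch errors. Switches are applied at
#' heterozygous sites only, since a switch at a homozygous site is
#' unobservable.
#'
#' @param alignment a [haplotype_alignment()].
#' @param switch_rate per-heterozygous-site switch probability; default
#'   0.0025, i.e. a mean switch error rate of 0.25 percent.
#' @return A list: `alignment` (perturbed) and `switches` (data frame
#'   `individual` (id), `site` (0-based position of each realized switch)).
#' @export
add_switch_errors <- function(alignment, switch_rate = 0.0025) {
  validate_alignment(alignment)
  if (switch_rate < 0 || switch_rate > 1) stop("switch_rate must be in [0, 1]")
  a <- alignment$alleles
  n_ind <- nrow(a) / 2L
  sw_ind <- character(0); sw_site <- integer(0)
  for (i in seq_len(n_ind)) {
    r1 <- 2L * i - 1L; r2 <- 2L * i
    het <- which(!is.na(a[r1, ]) & !is.na(a[r2, ]) & a[r1, ] != a[r2, ])
    if (length(het) == 0) next
    sel <- het[runif(length(het)) < switch_rate]
    if (length(sel) == 0) next
    state <- cumsum(seq_len(ncol(a)) %in% sel) %% 2L == 1L
    tmp <- a[r1, state]
    a[r1, state] <- a[r2, state]
    a[r2, state] <- tmp
    sw_ind <- c(sw_ind, rep(alignment$sample_ids[i], length(sel)))
    sw_site <- c(sw_site, sel - 1L)
  }
  list(alignment = haplotype_alignment(a, alignment$bp, alignment$cm,
                                       alignment$sample_ids,
                                       alignment$chromosome),
       switches = data.frame(individual = sw_ind, site = sw_site,
                             stringsAsFactors = FALSE))
}
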