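test_that("two identical haplotypes yield one full-length match per pairing", {
  set.seed(1)
  N <- 400
  h <- rbinom(N, 1L, 0.5)
  aln <- haplotype_alignment(rbind(h, 1L - h, h, 1L - h),
                             seq_len(N) * 100L, seq(0, 50, length.out = N),
                             c("A", "B"))
  for (tpl in list(pbwt_templates(), default_templates())) {
    seg <- compute_ibd_in_sample(aln, tpl, tpbwt_params(L_m = 50, L_f = 3))
    expect_equal(nrow(seg), 2L)  # (0,0) and (1,1) pairings; trailing report
    expect_equal(seg$start_site, c(0L, 0L))
    expect_equal(seg$end_site, c(N - 1L, N - 1L))
    expect_equal(seg$length_cm, c(50, 50))
  }
})

test_that("alternating vs complementary alternating haplotypes share nothing", {
  N <- 400
  alt <- rep(c(0L, 1L), N / 2)
  a <- rbind(alt, alt, 1L - alt, 1L - alt)
  aln <- haplotype_alignment(a, seq_len(N) * 100L, seq(0, 50, length.out = N),
                             c("A", "B"))
  for (tpl in list(pbwt_templates(), default_templates())) {
    seg <- compute_ibd_in_sample(aln, tpl, tpbwt_params(L_m = 20, L_f = 0))
    expect_equal(nrow(seg), 0L)
  }
})

test_that("a single planted error splits the PBWT match but not the templated one", {
  set.seed(2)
  N <- 1000
  shared <- rbinom(N, 1L, 0.5)
  a <- rbind(shared, rbinom(N, 1L, 0.5), shared, rbinom(N, 1L, 0.5))
  a[3, 500] <- 1L - a[3, 500]  # one genotyping error inside the match
  aln <- haplotype_alignment(a, seq_len(N) * 100L, seq(0, 20, length.out = N),
                             c("A", "B"))
  p <- tpbwt_params(L_m = 100, L_f = 0, phase_correction = FALSE)
  plain <- compute_ibd_in_sample(aln, pbwt_templates(), p)
  shared_plain <- plain[plain$hap1 == 0 & plain$hap2 == 0, ]
  expect_equal(nrow(shared_plain), 1L)  # split halves re-merged (gap < L_m)
  # but with L_m = 1 the PBWT reports the two halves separately
  p1 <- tpbwt_params(L_m = 1, L_f = 4, phase_correction = FALSE)
  plain1 <- compute_ibd_in_sample(aln, pbwt_templates(), p1)
  expect_equal(nrow(plain1[plain1$hap1 == 0 & plain1$hap2 == 0, ]), 2L)
  # templates mask the error: one unbroken segment spanning everything
  tmpl <- compute_ibd_in_sample(aln, default_templates(), p)
  tseg <- tmpl[tmpl$hap1 == 0 & tmpl$hap2 == 0, ]
  expect_equal(nrow(tseg), 1L)
  expect_equal(tseg$start_site, 0L)
  expect_equal(tseg$end_site, N - 1L)
})

test_that("missing data is extended through up to M_t consecutive sites", {
  set.seed(3)
  N <- 60
  h <- rbinom(N, 1L, 0.5)
  a <- rbind(h, rbinom(N, 1L, 0.5), h, rbinom(N, 1L, 0.5))
  a[3, 30] <- NA  # one missing site inside the shared region
  aln <- haplotype_alignment(a, seq_len(N) * 100L, seq(0, 6, length.out = N),
                             c("A", "B"))
  tpl <- pbwt_templates()
  ext <- compute_ibd_in_sample(aln, tpl,
    tpbwt_params(L_m = 10, L_f = 0, M_t = 1, phase_correction = FALSE))
  ext <- ext[ext$hap1 == 0 & ext$hap2 == 0, ]
  expect_equal(nrow(ext), 1L)  # extended through the missing site
  expect_equal(c(ext$start_site, ext$end_site), c(0L, N - 1L))
  cut <- compute_ibd_in_sample(aln, tpl,
    tpbwt_params(L_m = 1, L_f = 0, M_t = 0, phase_correction = FALSE))
  cut <- cut[cut$hap1 == 0 & cut$hap2 == 0, ]
  expect_equal(nrow(cut), 2L)  # terminated at it (L_m = 1: no gap merging)
  # and both behaviours match the brute-force matcher with missing treated
  # as wildcard / mismatch respectively
  bf_wild <- brute_force_ibd(aln, 10, 0, missing_wildcard = TRUE)
  bf_miss <- brute_force_ibd(aln, 1, 0, missing_wildcard = FALSE)
  expect_equal(est_hap_indices(ext, aln)[, c("start_site", "end_site")],
               bf_wild[bf_wild$hap_a == 0 & bf_wild$hap_b == 2,
                       c("start_site", "end_site")],
               ignore_attr = TRUE)
  expect_equal(est_hap_indices(cut, aln)[, c("start_site", "end_site")],
               bf_miss[bf_miss$hap_a == 0 & bf_miss$hap_b == 2,
                       c("start_site", "end_site")],
               ignore_attr = TRUE)
})

test_that("open matches merge across overlaps and sub-L_m gaps, else report", {
  # pair shares [0,100] and [160,399] (gap 59 < L_m=100 -> one segment),
  # and a second pair shares [0,100] and [300,399] (gap 199 >= 100 -> two,
  # with the first reported only because it exceeds L_f)
  set.seed(4)
  N <- 400
  mk <- function(gap_start) {
    h <- rbinom(N, 1L, 0.5)
    other <- rbinom(N, 1L, 0.5)
    x <- h
    x[101:(gap_start - 1)] <- 1L - h[101:(gap_start - 1)]  # destroy the middle
    rbind(h, other, x, rbinom(N, 1L, 0.5))
  }
  cm <- seq(0, 40, length.out = N)
  aln1 <- haplotype_alignment(mk(161), seq_len(N) * 100L, cm, c("A", "B"))
  p <- tpbwt_params(L_m = 100, L_f = 3, phase_correction = FALSE)
  seg1 <- compute_ibd_in_sample(aln1, pbwt_templates(), p)
  seg1 <- seg1[seg1$hap1 == 0 & seg1$hap2 == 0, ]
  expect_equal(nrow(seg1), 1L)
  expect_equal(c(seg1$start_site, seg1$end_site), c(0L, N - 1L))
  aln2 <- haplotype_alignment(mk(301), seq_len(N) * 100L, cm, c("A", "B"))
  seg2 <- compute_ibd_in_sample(aln2, pbwt_templates(), p)
  seg2 <- seg2[seg2$hap1 == 0 & seg2$hap2 == 0, ]
  expect_equal(nrow(seg2), 2L)
  # sub-L_f open matches are silently dropped when displaced
  p_hi <- tpbwt_params(L_m = 100, L_f = 15, phase_correction = FALSE)
  seg3 <- compute_ibd_in_sample(aln2, pbwt_templates(), p_hi)
  seg3 <- seg3[seg3$hap1 == 0 & seg3$hap2 == 0, ]
  expect_equal(nrow(seg3), 0L)  # 10 cM head and 10 cM tail both < 15 cM
})

test_that("trailing matches are reported iff they pass the L_f threshold", {
  # five pairs share suffixes of decreasing genetic length; two fall
  # below L_f
  set.seed(5)
  N <- 500
  cm <- seq(0, 50, length.out = N)
  starts <- c(1, 101, 201, 401, 451)  # suffix lengths 50, 40, 30, 10, 5 cM
  rows <- list()
  ids <- character(0)
  base <- rbinom(N, 1L, 0.5)
  for (i in seq_along(starts)) {
    h <- rbinom(N, 1L, 0.5)
    h[starts[i]:N] <- base[starts[i]:N]
    rows[[2 * i - 1]] <- h
    rows[[2 * i]] <- rbinom(N, 1L, 0.5)
    ids <- c(ids, paste0("I", i))
  }
  aln <- haplotype_alignment(do.call(rbind, c(rows, list(base, rbinom(N, 1L, 0.5)))),
                             seq_len(N) * 100L, cm, c(ids, "REF"))
  p <- tpbwt_params(L_m = 20, L_f = 15, phase_correction = FALSE)
  seg <- compute_ibd_in_sample(aln, pbwt_templates(), p)
  with_ref <- seg[seg$id2 == "REF" & seg$hap1 == 0 & seg$hap2 == 0, ]
  expect_equal(nrow(with_ref), 3L)  # 50, 40, 30 cM pass; 10 and 5 do not
  expect_true(all(with_ref$end_site == N - 1L))
})

test_that("with one all-sites template the sweep equals the brute-force scan", {
  # the collapse-to-PBWT property on random alignments (more seeds in the
  # acceptance suite)
  for (s in 1:10) {
    set.seed(100 + s)
    aln <- random_alignment(20, 200)
    p <- tpbwt_params(L_m = 5, L_f = 0, M_t = 0, phase_correction = FALSE)
    est <- est_hap_indices(compute_ibd_in_sample(aln, pbwt_templates(), p), aln)
    bf <- brute_force_ibd(aln, 5, 0)
    expect_equal(est, bf, ignore_attr = TRUE)
  }
})

test_that("output is invariant to permuting individuals (up to relabeling)", {
  set.seed(6)
  N <- 600
  base <- random_alignment(12, N, length_cm = 30)
  # plant a shared segment so there is something to find
  base$alleles[5, 100:450] <- base$alleles[9, 100:450]
  p <- tpbwt_params(L_m = 50, L_f = 3, phase_correction = FALSE)
  seg0 <- compute_ibd_in_sample(base, default_templates(), p)
  perm <- sample(6)
  rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  aln2 <- haplotype_alignment(base$alleles[rows, ], base$bp, base$cm,
                              base$sample_ids[perm])
  seg1 <- compute_ibd_in_sample(aln2, default_templates(), p)
  canon <- function(d) {
    sw <- d$id1 > d$id2
    tmp <- d$id1[sw]; d$id1[sw] <- d$id2[sw]; d$id2[sw] <- tmp
    tmp <- d$hap1[sw]; d$hap1[sw] <- d$hap2[sw]; d$hap2[sw] <- tmp
    d <- d[order(d$id1, d$id2, d$hap1, d$hap2, d$start_site), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(canon(seg0), canon(seg1), ignore_attr = TRUE)
})

test_that("self-pair (ROH-like) matches are excluded unless requested", {
  set.seed(7)
  N <- 300
  h <- rbinom(N, 1L, 0.5)
  a <- rbind(h, h, rbinom(N, 1L, 0.5), rbinom(N, 1L, 0.5))
  aln <- haplotype_alignment(a, seq_len(N) * 100L, seq(0, 30, length.out = N),
                             c("A", "B"))
  p0 <- tpbwt_params(L_m = 30, L_f = 3, phase_correction = FALSE)
  expect_equal(nrow(compute_ibd_in_sample(aln, pbwt_templates(), p0)), 0L)
  p1 <- tpbwt_params(L_m = 30, L_f = 3, phase_correction = FALSE,
                     include_self_pairs = TRUE)
  roh <- compute_ibd_in_sample(aln, pbwt_templates(), p1)
  expect_equal(nrow(roh), 1L)
  expect_equal(roh$id1, "A")
  expect_equal(roh$id2, "A")
})
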