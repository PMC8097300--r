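test_that("a duplicated individual across panels yields full cross segments", {
  set.seed(30)
  N <- 400
  h1 <- rbinom(N, 1L, 0.5); h2 <- rbinom(N, 1L, 0.5)
  cm <- seq(0, 40, length.out = N)
  x <- haplotype_alignment(rbind(h1, h2), seq_len(N) * 100L, cm, "NEW")
  y <- haplotype_alignment(rbind(h1, h2), seq_len(N) * 100L, cm, "OLD")
  seg <- compute_ibd_out_of_sample(x, y, default_templates(),
                                   tpbwt_params(L_m = 50, L_f = 3,
                                                phase_correction = FALSE))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$id1, c("NEW", "NEW"))
  expect_equal(seg$id2, c("OLD", "OLD"))
  expect_equal(seg$start_site, c(0L, 0L))
  expect_equal(seg$end_site, c(N - 1L, N - 1L))
})

test_that("panels sharing no alleles yield no cross segments", {
  N <- 200
  h <- matrix(0L, 2, N)
  cm <- seq(0, 20, length.out = N)
  x <- haplotype_alignment(h, seq_len(N) * 100L, cm, "A")
  y <- haplotype_alignment(1L - h, seq_len(N) * 100L, cm, "B")
  seg <- compute_ibd_out_of_sample(x, y, pbwt_templates(),
                                   tpbwt_params(L_m = 10, L_f = 0,
                                                phase_correction = FALSE))
  expect_equal(nrow(seg), 0L)
})

test_that("out-of-sample equals the concatenated in-sample run filtered to cross pairs", {
  p <- tpbwt_params(L_m = 30, L_f = 1, phase_correction = FALSE)
  for (s in 1:10) {
    set.seed(300 + s)
    comb <- random_alignment(50, 400, length_cm = 40,
                             ids = c(paste0("X", 1:10), paste0("Y", 1:15)))
    # plant some cross and within segments
    comb$alleles[3, 50:250] <- comb$alleles[25, 50:250]
    comb$alleles[30, 100:350] <- comb$alleles[45, 100:350]
    comb$alleles[1, 200:390] <- comb$alleles[5, 200:390]
    x <- haplotype_alignment(comb$alleles[1:20, ], comb$bp, comb$cm,
                             paste0("X", 1:10))
    y <- haplotype_alignment(comb$alleles[21:50, ], comb$bp, comb$cm,
                             paste0("Y", 1:15))
    oos <- compute_ibd_out_of_sample(x, y, default_templates(), p)
    ins <- compute_ibd_in_sample(comb, default_templates(), p)
    cross <- ins[substr(ins$id1, 1, 1) != substr(ins$id2, 1, 1), ]
    rownames(cross) <- NULL
    expect_equal(oos, cross, ignore_attr = TRUE)
    # cross bookkeeping never stores within-panel pairs
    expect_lte(attr(oos, "max_open_matches"), 20L * 30L)
  }
})

test_that("compressed panels feed the out-of-sample compute", {
  set.seed(31)
  comb <- random_alignment(20, 300, length_cm = 30,
                           ids = c(paste0("X", 1:5), paste0("Y", 1:5)))
  comb$alleles[2, 30:280] <- comb$alleles[15, 30:280]
  x <- compress_panel(haplotype_alignment(comb$alleles[1:10, ], comb$bp,
                                          comb$cm, paste0("X", 1:5)),
                      default_templates())
  y <- compress_panel(haplotype_alignment(comb$alleles[11:20, ], comb$bp,
                                          comb$cm, paste0("Y", 1:5)),
                      default_templates())
  p <- tpbwt_params(L_m = 40, L_f = 3, phase_correction = FALSE)
  seg <- compute_ibd_out_of_sample(x, y, params = p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$id1, "X1")
  expect_equal(seg$id2, "Y3")
  # template-set mismatch between panels is an error
  y2 <- compress_panel(decompress_panel(y), pbwt_templates())
  expect_error(compute_ibd_out_of_sample(x, y2, params = p),
               "different template sets")
})

test_that("merged orderings are the linear sum of the two panels' orderings", {
  set.seed(32)
  N <- 120
  ax <- random_alignment(10, N, ids = paste0("X", 1:5))
  ay <- haplotype_alignment(matrix(rbinom(16 * N, 1L, 0.5), 16, N),
                            ax$bp, ax$cm, paste0("Y", 1:8))
  tpl <- default_templates()
  px <- compress_panel(ax, tpl)
  py <- compress_panel(ay, tpl)
  mo <- merge_orderings(px, py)
  # recompute the combined ordering from scratch on the concatenation
  comb <- rbind(ax$alleles, ay$alleles)
  comb[is.na(comb)] <- 2L
  for (j in 1:6) {
    proc <- which(tpl$masks[j, ((seq_len(N) - 1L) %% 4L) + 1L] == 1L)
    ord <- seq_len(26) - 1L
    for (k in proc) {
      got <- mo[[j]][[k]]
      expect_identical(got, ord)
      # restriction to X equals ppa(X); to Y equals ppa(Y)
      ak <- comb[ord + 1L, k]
      ord <- c(ord[ak == 0L], ord[ak == 1L], ord[ak == 2L])
    }
  }
  # an empty Y panel leaves the X ordering untouched
  empty <- structure(list(version = 1L, M = 0L, N = N, templates = tpl,
                          sample_ids = character(0), chromosome = "1",
                          bp = ax$bp, cm = ax$cm,
                          runs = lapply(1:6, function(j) {
                            rj <- vector("list", N)
                            proc <- which(tpl$masks[j, ((seq_len(N) - 1L) %% 4L) + 1L] == 1L)
                            for (k in proc) rj[[k]] <- list(sym = integer(0),
                                                            len = integer(0))
                            rj
                          })),
                     class = "tpbwt_panel")
  mo_x <- merge_orderings(px, empty)
  ord <- seq_len(10) - 1L
  ax2 <- ax$alleles
  for (k in which(tpl$masks[1, ((seq_len(N) - 1L) %% 4L) + 1L] == 1L)) {
    expect_identical(mo_x[[1]][[k]], ord)
    ak <- ax2[ord + 1L, k]
    ord <- c(ord[ak == 0L], ord[ak == 1L])
  }
})

test_that("site mismatch between panels is rejected; subset_sites repairs it", {
  set.seed(33)
  a <- random_alignment(6, 100, ids = paste0("X", 1:3))
  b <- random_alignment(6, 100, ids = paste0("Y", 1:3))
  b2 <- subset_sites(b, b$bp[-c(5, 50)])
  expect_error(compute_ibd_out_of_sample(a, b2), "share the same sites")
  a2 <- subset_sites(a, b2$bp)
  expect_equal(a2$bp, b2$bp)
  expect_silent(compute_ibd_out_of_sample(
    a2, b2, pbwt_templates(), tpbwt_params(L_m = 5, L_f = 0,
                                           phase_correction = FALSE)))
})
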