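# fixtures are generated in code; no data files

random_alignment <- function(M, N, length_cm = N / 10, p = 0.5,
                             ids = paste0("I", seq_len(M / 2))) {
  a <- matrix(rbinom(M * N, 1L, p), M, N)
  cm <- seq(0, length_cm, length.out = N)
  haplotype_alignment(a, as.integer(seq_len(N) * 100L), cm, ids)
}

# global haplotype indices (0-based) for a segment table
est_hap_indices <- function(seg, alignment) {
  data.frame(
    hap_a = 2L * (match(seg$id1, alignment$sample_ids) - 1L) + seg$hap1,
    hap_b = 2L * (match(seg$id2, alignment$sample_ids) - 1L) + seg$hap2,
    start_site = seg$start_site, end_site = seg$end_site)
}

# Independent O(M^2 N) oracle: per haplotype pair, maximal runs of
# identity (missing treated as mismatch or wildcard) of >= Lm sites,
# gaps of < Lm sites merged, then the Lf genetic-length filter.
brute_force_ibd <- function(aln, Lm, Lf, missing_wildcard = FALSE,
                            include_self = FALSE) {
  a <- aln$alleles
  M <- nrow(a); cm <- aln$cm
  out <- list()
  for (x in 1:(M - 1)) for (y in (x + 1):M) {
    if (!include_self && (x - 1) %/% 2 == (y - 1) %/% 2) next
    eq <- a[x, ] == a[y, ]
    eq[is.na(eq)] <- missing_wildcard
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= Lm)
    if (!length(runs)) next
    iv <- cbind(starts[runs], ends[runs])
    merged <- iv[1, , drop = FALSE]
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv[i, 1] - merged[nrow(merged), 2] - 1L < Lm)
        merged[nrow(merged), 2] <- iv[i, 2]
      else merged <- rbind(merged, iv[i, ])
    }
    for (i in seq_len(nrow(merged))) {
      s <- merged[i, 1]; e <- merged[i, 2]
      if (cm[e] - cm[s] >= Lf)
        out[[length(out) + 1L]] <- data.frame(
          hap_a = x - 1L, hap_b = y - 1L,
          start_site = s - 1L, end_site = e - 1L)
    }
  }
  if (!length(out))
    return(data.frame(hap_a = integer(), hap_b = integer(),
                      start_site = integer(), end_site = integer()))
  d <- do.call(rbind, out)
  d <- d[order(d$hap_a, d$hap_b, d$start_site), ]
  rownames(d) <- NULL
  d
}

linear_map <- function(bp0, cm0, bp1, cm1) genetic_map(c(bp0, bp1), c(cm0, cm1))

make_segment <- function(id1, id2, start_cm, end_cm, hap1 = 0L, hap2 = 0L,
                         sites_per_cm = 10) {
  data.frame(id1 = id1, id2 = id2, hap1 = hap1, hap2 = hap2,
             chromosome = "1",
             start_site = as.integer(round(start_cm * sites_per_cm)),
             end_site = as.integer(round(end_cm * sites_per_cm)),
             start_bp = as.integer(round(start_cm * 1e6)) + 1L,
             end_bp = as.integer(round(end_cm * 1e6)) + 1L,
             start_cm = start_cm, end_cm = end_cm,
             length_cm = end_cm - start_cm, stringsAsFactors = FALSE)
}
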