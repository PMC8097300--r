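PANEL_MAGIC <- charToRaw("TPBW")
PANEL_VERSION <- 1L
SYM_MISSING <- 2L

processed_sites <- function(templates, N) {
  lapply(seq_len(templates$t), function(j) {
    which(templates$masks[j, ((seq_len(N) - 1L) %% templates$period) + 1L] == 1L)
  })
}

# stable 3-way partition (0, 1, missing) used for the panel orderings;
# deterministic and independent of the sweep's neighbour imputation so
# that decompression is exact.
advance_order <- function(ord, alleles_k) {
  a <- alleles_k[ord]
  c(ord[a == 0L], ord[a == 1L], ord[a == SYM_MISSING])
}

#' Run-length compress a haplotype panel in TPBWT order
#'
#' For every template `j` and every site it processes, the alleles are
#' recorded in that template's positional-prefix-array order and run-length
#' encoded. Sorted order groups haplotypes with shared recent history, so
#' linkage disequilibrium yields long single-allele runs. A site processed
#' by three templates is encoded three times (once per ordering). Missing
#' alleles are stored explicitly as a third symbol so decompression is
#' exact.
#'
#' @param alignment a [haplotype_alignment()].
#' @param templates a [template_set()]; embedded in the panel, since the
#'   orderings are template-dependent.
#' @return An object of class `"tpbwt_panel"`.
#' @export
compress_panel <- function(alignment, templates = default_templates()) {
  validate_alignment(alignment)
  stopifnot(inherits(templates, "template_set"))
  a <- raw_alleles(alignment)
  M <- nrow(a); N <- ncol(a)
  proc <- processed_sites(templates, N)
  runs <- vector("list", templates$t)
  for (j in seq_len(templates$t)) {
    ord <- seq_len(M)
    rj <- vector("list", N)
    for (k in proc[[j]]) {
      r <- rle(a[ord, k])
      rj[[k]] <- list(sym = as.integer(r$values), len = as.integer(r$lengths))
      ord <- advance_order(ord, a[, k])
    }
    runs[[j]] <- rj
  }
  structure(list(version = PANEL_VERSION, M = M, N = N,
                 templates = templates, sample_ids = alignment$sample_ids,
                 chromosome = alignment$chromosome,
                 bp = alignment$bp, cm = alignment$cm, runs = runs),
            class = "tpbwt_panel")
}

#' @export
print.tpbwt_panel <- function(x, ...) {
  n_runs <- sum(vapply(x$runs, function(rj)
    sum(vapply(rj, function(r) if (is.null(r)) 0L else length(r$sym), integer(1))),
    integer(1)))
  cat(sprintf("tpbwt_panel: %d haplotypes x %d sites, %d templates, %d allele runs\n",
              x$M, x$N, x$templates$t, n_runs))
  invisible(x)
}

#' Reconstruct the haplotype alignment from a compressed panel
#'
#' Replays every template's ordering in parallel; at each site the runs of
#' the first template processing it are expanded through that template's
#' current ordering to recover the allele column, and all covering
#' templates' orderings are then advanced. Exact inverse of
#' [compress_panel()].
#'
#' @param panel a `tpbwt_panel`.
#' @return A [haplotype_alignment()].
#' @export
decompress_panel <- function(panel) {
  stopifnot(inherits(panel, "tpbwt_panel"))
  tpl <- panel$templates
  M <- panel$M; N <- panel$N
  a <- matrix(SYM_MISSING, M, N)
  ords <- rep(list(seq_len(M)), tpl$t)
  residue <- ((seq_len(N) - 1L) %% tpl$period) + 1L
  for (k in seq_len(N)) {
    covering <- which(tpl$masks[, residue[k]] == 1L)
    j0 <- covering[1]
    r <- panel$runs[[j0]][[k]]
    a[ords[[j0]], k] <- rep(r$sym, r$len)
    for (j in covering) ords[[j]] <- advance_order(ords[[j]], a[, k])
  }
  a[a == SYM_MISSING] <- NA_integer_
  haplotype_alignment(a, panel$bp, panel$cm, panel$sample_ids, panel$chromosome)
}

#' Iterate the allele runs of one (site, template)
#'
#' @param panel a `tpbwt_panel`.
#' @param site 0-based site index.
#' @param template 1-based template index.
#' @return A data frame with columns `allele` (0, 1 or `NA`) and `length`,
#'   in the template's ordering at that site; run lengths sum to `M`.
#'   Asking for a site the template masks is an error.
#' @export
iterate_runs <- function(panel, site, template) {
  stopifnot(inherits(panel, "tpbwt_panel"))
  if (site < 0L || site >= panel$N) stop("site index out of range")
  if (template < 1L || template > panel$templates$t)
    stop("template index out of range")
  r <- panel$runs[[template]][[site + 1L]]
  if (is.null(r))
    stop(sprintf("template %d masks site %d", template, site))
  allele <- r$sym
  allele[allele == SYM_MISSING] <- NA_integer_
  data.frame(allele = allele, length = r$len)
}

## ---- binary format ----------------------------------------------------
## little-endian; layout:
##   magic "TPBW", version byte
##   int32: M, N, t, period
##   masks: t*period bytes (row-major by template)
##   chromosome: int32 length + bytes
##   sample ids: int32 count, then per id int32 length + bytes
##   bp: N x int32;  cm: N x float64
##   per template, per processed site (ascending): varint run count,
##   then one varint per run encoding (length << 2) | symbol  (ULEB128)

encode_varint <- function(v) {
  out <- raw(0)
  for (x in v) {
    b <- raw(0)
    repeat {
      lo <- bitwAnd(x, 0x7FL)
      x <- bitwShiftR(x, 7L)
      b <- c(b, as.raw(if (x > 0L) bitwOr(lo, 0x80L) else lo))
      if (x == 0L) break
    }
    out <- c(out, b)
  }
  out
}

new_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes; env$pos <- 1L
  env
}

need_bytes <- function(rd, n) {
  if (rd$pos + n - 1L > length(rd$bytes))
    stop(sprintf("truncated TPBWT panel file at byte offset %d", rd$pos - 1L))
}

read_raw_n <- function(rd, n) {
  need_bytes(rd, n)
  out <- rd$bytes[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + n
  out
}

read_int32 <- function(rd, n = 1L) {
  readBin(read_raw_n(rd, 4L * n), "integer", n = n, size = 4L,
          endian = "little")
}

read_varint <- function(rd) {
  x <- 0L; shift <- 0L
  repeat {
    b <- as.integer(read_raw_n(rd, 1L))
    x <- bitwOr(x, bitwShiftL(bitwAnd(b, 0x7FL), shift))
    if (b < 0x80L) break
    shift <- shift + 7L
  }
  x
}

#' Write a compressed panel to a .tpbwt binary file
#'
#' Little-endian binary layout documented in the package source; runs are
#' ULEB128 varints of `(length << 2) | symbol`. Round trips bit-exactly
#' through [read_panel()].
#'
#' @param panel a `tpbwt_panel`.
#' @param path output path (conventionally `.tpbwt`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "tpbwt_panel"))
  tpl <- panel$templates
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(PANEL_MAGIC, con)
  writeBin(as.raw(PANEL_VERSION), con)
  writeBin(as.integer(c(panel$M, panel$N, tpl$t, tpl$period)), con,
           size = 4L, endian = "little")
  writeBin(as.raw(t(tpl$masks)), con)
  chr <- charToRaw(panel$chromosome)
  writeBin(length(chr), con, size = 4L, endian = "little")
  writeBin(chr, con)
  writeBin(length(panel$sample_ids), con, size = 4L, endian = "little")
  for (s in panel$sample_ids) {
    b <- charToRaw(s)
    writeBin(length(b), con, size = 4L, endian = "little")
    writeBin(b, con)
  }
  writeBin(panel$bp, con, size = 4L, endian = "little")
  writeBin(panel$cm, con, size = 8L, endian = "little")
  proc <- processed_sites(tpl, panel$N)
  for (j in seq_len(tpl$t)) {
    pieces <- lapply(proc[[j]], function(k) {
      r <- panel$runs[[j]][[k]]
      c(encode_varint(length(r$sym)),
        encode_varint(bitwOr(bitwShiftL(r$len, 2L), r$sym)))
    })
    writeBin(do.call(c, c(pieces, list(raw(0)))), con)
  }
  invisible(path)
}

#' Read a .tpbwt panel file
#'
#' @param path file written by [write_panel()].
#' @return A `tpbwt_panel`.
#' @export
read_panel <- function(path) {
  rd <- new_reader(readBin(path, "raw", n = file.info(path)$size))
  if (!identical(read_raw_n(rd, 4L), PANEL_MAGIC))
    stop("not a TPBWT panel (bad magic)")
  ver <- as.integer(read_raw_n(rd, 1L))
  if (ver != PANEL_VERSION)
    stop("unsupported TPBWT panel version ", ver)
  hdr <- read_int32(rd, 4L)
  M <- hdr[1]; N <- hdr[2]; t <- hdr[3]; period <- hdr[4]
  if (M < 2L || N < 1L || t < 1L || period < 1L)
    stop("corrupt TPBWT panel header")
  masks <- matrix(as.integer(read_raw_n(rd, t * period)), nrow = t,
                  ncol = period, byrow = TRUE)
  tpl <- template_set(masks)
  chrom <- rawToChar(read_raw_n(rd, read_int32(rd)))
  n_ids <- read_int32(rd)
  sample_ids <- vapply(seq_len(n_ids), function(i)
    rawToChar(read_raw_n(rd, read_int32(rd))), character(1))
  bp <- read_int32(rd, N)
  cm <- readBin(read_raw_n(rd, 8L * N), "double", n = N, size = 8L,
                endian = "little")
  proc <- processed_sites(tpl, N)
  runs <- vector("list", t)
  for (j in seq_len(t)) {
    rj <- vector("list", N)
    for (k in proc[[j]]) {
      n_runs <- read_varint(rd)
      v <- vapply(seq_len(n_runs), function(i) read_varint(rd), integer(1))
      sym <- bitwAnd(v, 3L)
      len <- bitwShiftR(v, 2L)
      if (sum(len) != M)
        stop(sprintf("corrupt run block (template %d, site %d): lengths sum to %d, expected %d",
                     j, k - 1L, sum(len), M))
      rj[[k]] <- list(sym = sym, len = len)
    }
    runs[[j]] <- rj
  }
  structure(list(version = ver, M = M, N = N, templates = tpl,
                 sample_ids = sample_ids, chromosome = chrom,
                 bp = bp, cm = cm, runs = runs),
            class = "tpbwt_panel")
}

#' Merged haplotype orderings of two compressed panels
#'
#' The combined positional prefix array of two sample sets is the linear
#' sum of the two panels' totally ordered sets: within the combined order
#' the X haplotypes keep their `ppa(X)` relative order and the Y haplotypes
#' their `ppa(Y)` order. This lets the combined order be advanced while
#' querying alleles only at the starts of either panel's runs, which is
#' what makes out-of-sample sweeps over compressed panels cheap. Returns
#' the combined ordering at every processed (site, template); X haplotypes
#' are numbered `0 .. M_X - 1`, Y haplotypes `M_X .. M_X + M_Y - 1`.
#'
#' @param panel_x,panel_y `tpbwt_panel`s over the same sites and template
#'   set. Either may be empty-ish only in the sense of tests; normally both
#'   hold samples.
#' @return A list with one element per template; each is a list over sites
#'   (NULL at masked sites) of integer orderings of length `M_X + M_Y`.
#' @export
merge_orderings <- function(panel_x, panel_y) {
  stopifnot(inherits(panel_x, "tpbwt_panel"), inherits(panel_y, "tpbwt_panel"))
  if (!identical(panel_x$templates$masks, panel_y$templates$masks))
    stop("panels were built with different template sets")
  if (!identical(panel_x$bp, panel_y$bp))
    stop("panels do not share the same sites")
  tpl <- panel_x$templates
  MX <- panel_x$M; MY <- panel_y$M
  proc <- processed_sites(tpl, panel_x$N)
  out <- vector("list", tpl$t)
  for (j in seq_len(tpl$t)) {
    ord <- seq_len(MX + MY) - 1L
    oj <- vector("list", panel_x$N)
    for (k in proc[[j]]) {
      oj[[k]] <- ord
      rx <- panel_x$runs[[j]][[k]]
      ry <- panel_y$runs[[j]][[k]]
      # expand each panel's runs; because the combined order restricted to
      # a panel equals that panel's own ordering, walking the combined
      # order consumes each panel's runs sequentially.
      ax <- rep(rx$sym, rx$len)
      ay <- rep(ry$sym, ry$len)
      from_x <- ord < MX
      alleles <- integer(MX + MY)
      alleles[from_x] <- ax
      alleles[!from_x] <- ay
      ord <- c(ord[alleles == 0L], ord[alleles == 1L],
               ord[alleles == SYM_MISSING])
    }
    out[[j]] <- oj
  }
  out
}
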