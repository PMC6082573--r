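# Independent brute-force oracles. These deliberately re-derive results by
# a different route than the package implementation so agreement is
# informative.

# Byte-level .bed decoder using rawToBits (the package decodes by integer
# arithmetic on whole bytes).
oracle_read_bed <- function(path, n, m) {
  raw <- readBin(path, "raw", n = file.size(path))
  stopifnot(raw[1] == as.raw(0x6c), raw[2] == as.raw(0x1b), raw[3] == as.raw(0x01))
  payload <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    bits <- as.integer(rawToBits(payload[((j - 1) * bpv + 1):(j * bpv)]))
    for (i in seq_len(n)) {
      code <- bits[2 * i - 1] + 2L * bits[2 * i]
      out[i, j] <- switch(code + 1L, 2L, NA_integer_, 1L, 0L)
    }
  }
  out
}

# Exact HWE p-value by the upward probability recurrence (the package uses
# direct log-factorial enumeration).
oracle_hwe <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  n_rare <- min(2 * n_hom_minor + n_het, 2 * n_hom_major + n_het)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  hets <- hets[(n - hets - (n_rare - hets) / 2) >= 0]
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    ha <- (n_rare - h) / 2
    hb <- n - h - ha
    probs[k] <- probs[k - 1] * 4 * ha * hb / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[hets == n_het]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

# Naive per-window enumeration of hit rates.
oracle_scan <- function(calls, params) {
  n <- length(calls)
  w <- params$window_snps
  hr <- numeric(n)
  if (n < w) return(hr)
  qual <- vapply(seq_len(n - w + 1), function(s) {
    win <- calls[s:(s + w - 1)]
    sum(win == 1L, na.rm = TRUE) <= params$window_het_max &&
      sum(is.na(win)) <= params$window_missing_max
  }, logical(1))
  for (i in seq_len(n)) {
    s <- max(1, i - w + 1):min(i, n - w + 1)
    hr[i] <- mean(qual[s])
  }
  hr
}

# Exact minimum vertex cover size by exhaustive subset search (n <= ~12).
oracle_min_vertex_cover <- function(adj) {
  n <- nrow(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(edges)) return(0L)
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k)
    for (c in seq_len(ncol(combs))) {
      cover <- combs[, c]
      if (all(edges[, 1] %in% cover | edges[, 2] %in% cover)) return(k)
    }
  }
  n
}

# bases of [s1, e1] intervals covered by a set of [s2, e2] intervals
interval_coverage <- function(truth, called) {
  if (!nrow(truth)) return(c(covered = 0, total = 0))
  total <- sum(truth$end - truth$start + 1)
  covered <- 0
  for (t in seq_len(nrow(truth))) {
    if (nrow(called)) {
      ov <- pmin(called$end, truth$end[t]) - pmax(called$start, truth$start[t]) + 1
      covered <- covered + sum(pmax(ov, 0))
    }
  }
  c(covered = covered, total = total)
}

# small genotypes fixture with controllable dimensions
make_genotypes <- function(calls, bp = NULL, chrom = "1") {
  n <- nrow(calls)
  m <- ncol(calls)
  genotypes(
    calls = calls,
    variants = data.frame(
      chrom = chrom, id = sprintf("s%04d", seq_len(m)), cm = 0,
      bp = bp %||% (1000L * seq_len(m)), a1 = "A", a2 = "G"
    ),
    samples = data.frame(
      fid = sprintf("f%03d", seq_len(n)),
      iid = sprintf("i%03d", seq_len(n)), sex = 1L
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

published_betas <- function() {
  read.delim(system.file("extdata", "biobank_froh_betas.tsv", package = "autozyg"))
}
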