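#' ROH calling parameters
#'
#' The PLINK-style sliding-window parameters used by [call_roh()]. Defaults
#' are the standard set for ~1 SNP / 10 kb array data after LD pruning:
#' 65-SNP windows with no heterozygote and at most 3 missing calls allowed,
#' runs of at least 65 SNPs and 10 kb, split at inter-SNP gaps over 500 kb,
#' and a final density requirement of at least 1 SNP per 200 kb
#' (`--homozyg-window-snp 65 --homozyg-snp 65 --homozyg-kb 10
#' --homozyg-gap 500 --homozyg-window-missing 3 --homozyg-window-het 0
#' --homozyg-density 200`). `hit_rate_min` is the fraction of qualifying
#' windows a SNP must sit in to be considered homozygous (PLINK's
#' `--homozyg-window-threshold`, tool default 0.05).
#'
#' @param window_snps window size in SNPs.
#' @param window_het_max maximum heterozygous calls per qualifying window.
#' @param window_missing_max maximum missing calls per qualifying window.
#' @param min_snps minimum SNPs per reported segment.
#' @param min_kb minimum segment length in kb.
#' @param gap_kb maximum gap between consecutive SNPs within a segment (kb).
#' @param density_kb_per_snp maximum average spacing within a segment (kb/SNP).
#' @param hit_rate_min per-SNP qualifying-window rate threshold.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 65, window_het_max = 0,
                       window_missing_max = 3, min_snps = 65, min_kb = 10,
                       gap_kb = 500, density_kb_per_snp = 200,
                       hit_rate_min = 0.05) {
  if (window_het_max >= window_snps) {
    abort_autozyg("window_het_max must be below window_snps", "autozyg_config_error")
  }
  if (min_kb < 0 || hit_rate_min <= 0 || hit_rate_min > 1) {
    abort_autozyg("min_kb must be >= 0 and hit_rate_min in (0, 1]", "autozyg_config_error")
  }
  structure(
    list(
      window_snps = as.integer(window_snps),
      window_het_max = as.integer(window_het_max),
      window_missing_max = as.integer(window_missing_max),
      min_snps = as.integer(min_snps), min_kb = min_kb, gap_kb = gap_kb,
      density_kb_per_snp = density_kb_per_snp, hit_rate_min = hit_rate_min
    ),
    class = "roh_params"
  )
}

#' Per-SNP qualifying-window hit rates for one chromosome of one individual
#'
#' Slides a `window_snps`-wide window across the call vector; a window
#' qualifies if it contains at most `window_het_max` heterozygous and at
#' most `window_missing_max` missing calls. Each SNP's hit rate is the
#' fraction of windows containing it that qualify. Chromosomes shorter than
#' one window yield all-zero hit rates.
#'
#' @param calls integer vector of 0/1/2/NA calls, ordered by bp.
#' @param params a [roh_params()] object.
#' @return Numeric vector of hit rates, one per SNP.
#' @export
scan_windows <- function(calls, params = roh_params()) {
  n <- length(calls)
  w <- params$window_snps
  if (n < w) return(numeric(n))
  het <- cumsum(c(0L, !is.na(calls) & calls == 1L))
  mis <- cumsum(c(0L, is.na(calls)))
  starts <- seq_len(n - w + 1L)
  qual <- (het[starts + w] - het[starts]) <= params$window_het_max &
    (mis[starts + w] - mis[starts]) <= params$window_missing_max
  cq <- cumsum(c(0L, qual))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n - w + 1L)
  (cq[hi + 1L] - cq[lo]) / (hi - lo + 1L)
}

#' Assemble ROH segments from hit rates
#'
#' SNPs with hit rate at or above `hit_rate_min` form maximal candidate
#' runs. Runs are terminated by heterozygous SNPs and split at inter-SNP
#' gaps exceeding `gap_kb`; leading and trailing missing calls are trimmed
#' so segment boundaries are the first and last homozygous SNP of the run
#' (no extension into flanking gaps). A run is reported if it has at least
#' `min_snps` SNPs, spans at least `min_kb` kb, and its average SNP spacing
#' does not exceed `density_kb_per_snp`. Segment length is
#' `end_bp - start_bp + 1`.
#'
#' @param hit_rates numeric vector from [scan_windows()].
#' @param calls the matching call vector.
#' @param positions the matching bp positions (strictly increasing).
#' @param params a [roh_params()] object.
#' @return data.frame with columns `start_idx`, `end_idx`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp` (zero rows if no segment qualifies).
#' @export
assemble_segments <- function(hit_rates, calls, positions, params = roh_params()) {
  if (length(hit_rates) != length(calls) || length(calls) != length(positions)) {
    abort_autozyg("hit_rates, calls and positions must be aligned", "autozyg_integrity_error")
  }
  m <- assemble_core(hit_rates, calls, positions, params)
  data.frame(
    start_idx = as.integer(m[, 1]), end_idx = as.integer(m[, 2]),
    start_bp = positions[m[, 1]], end_bp = positions[m[, 2]],
    n_snps = as.integer(m[, 2] - m[, 1] + 1),
    length_bp = positions[m[, 2]] - positions[m[, 1]] + 1,
    row.names = NULL
  )
}

# hot path shared with call_roh: returns a 2-column matrix of
# (first, last) SNP indices of each qualifying segment
assemble_core <- function(hit_rates, calls, positions, params) {
  empty <- matrix(numeric(0), 0, 2)
  cand <- hit_rates >= params$hit_rate_min
  # heterozygous SNPs can never belong to a run
  cand[!is.na(calls) & calls == 1L] <- FALSE
  idx <- which(cand)
  if (!length(idx)) return(empty)
  # break runs at non-candidate SNPs and at large physical gaps
  brk <- diff(idx) > 1L | diff(positions[idx]) > params$gap_kb * 1000
  run_id <- cumsum(c(TRUE, brk))
  # per run: first/last SNP after trimming leading/trailing missing calls
  bounds <- vapply(split(idx, run_id), function(run) {
    hom <- which(!is.na(calls[run]))
    if (!length(hom)) return(c(NA_real_, NA_real_))
    c(run[hom[1]], run[hom[length(hom)]])
  }, numeric(2))
  start_i <- bounds[1, ]
  end_i <- bounds[2, ]
  ok <- !is.na(start_i)
  start_i <- start_i[ok]
  end_i <- end_i[ok]
  n_snps <- end_i - start_i + 1
  len <- positions[end_i] - positions[start_i] + 1
  keep <- n_snps >= params$min_snps &
    len / 1000 >= params$min_kb &
    len / n_snps <= params$density_kb_per_snp * 1000
  if (!any(keep)) return(empty)
  cbind(start_i[keep], end_i[keep])
}

autosome_labels <- as.character(1:22)

#' Call runs of homozygosity for a cohort
#'
#' Runs the sliding-window scan and segment assembly for every individual on
#' every autosome. Non-autosomal chromosomes (anything not labelled 1-22)
#' are excluded with a message. Output is deterministic for a fixed input
#' and equivariant under permutation of individuals.
#'
#' @param g a `genotypes` object (QC'd and LD-pruned).
#' @param params a [roh_params()] object.
#' @return A `roh_segments` data.frame: `iid`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`.
#' @export
call_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotypes"))
  chroms <- as.character(g$variants$chrom)
  non_auto <- !(chroms %in% autosome_labels)
  if (any(non_auto)) {
    message(sprintf("excluding %d non-autosomal variants from ROH calling", sum(non_auto)))
  }
  chr_idx <- split(which(!non_auto), chroms[!non_auto])
  res <- vector("list", length(chr_idx) * nrow(g$calls))
  k <- 0L
  for (ch in names(chr_idx)) {
    cols <- chr_idx[[ch]]
    pos <- g$variants$bp[cols]
    calls_t <- t(g$calls[, cols, drop = FALSE]) # variants x individuals: contiguous per-individual access
    for (i in seq_len(nrow(g$calls))) {
      calls <- calls_t[, i]
      seg <- assemble_core(scan_windows(calls, params), calls, pos, params)
      if (nrow(seg)) {
        k <- k + 1L
        res[[k]] <- cbind(
          i = i, ch = match(ch, names(chr_idx)),
          start_bp = pos[seg[, 1]], end_bp = pos[seg[, 2]],
          n_snps = seg[, 2] - seg[, 1] + 1,
          length_bp = pos[seg[, 2]] - pos[seg[, 1]] + 1
        )
      }
    }
  }
  out <- if (k) {
    m <- do.call(rbind, res[seq_len(k)])
    data.frame(
      iid = g$samples$iid[m[, "i"]], chrom = names(chr_idx)[m[, "ch"]],
      start_bp = m[, "start_bp"], end_bp = m[, "end_bp"],
      n_snps = as.integer(m[, "n_snps"]), length_bp = m[, "length_bp"],
      row.names = NULL
    )
  } else {
    data.frame(
      iid = character(0), chrom = character(0), start_bp = integer(0),
      end_bp = integer(0), n_snps = integer(0), length_bp = numeric(0)
    )
  }
  # fixed presentation order: individual as given, then chromosome, then bp
  out <- out[order(match(out$iid, g$samples$iid), out$chrom, out$start_bp), ]
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Genomic inbreeding coefficients from ROH segments
#'
#' `F_ROH` is the summed length of an individual's autosomal ROH segments
#' divided by the SNP-mappable autosome length (2.77e9 bases for human
#' array data; synthetic genomes pass their own length). Segments longer
#' than `long_threshold_bp` (8.5 Mb, tracts expected from a common ancestor
#' within ~6 generations under a 1 cM/Mb map) contribute to `f_roh_long`,
#' the rest to `f_roh_short`; the two partition `f_roh` exactly.
#'
#' @param segments a `roh_segments` data.frame (whole cohort or one
#'   individual).
#' @param ids optional character vector of individual ids to report
#'   (individuals without segments get zeros); defaults to the ids present
#'   in `segments`.
#' @param denominator_bp total mappable genome length in bases.
#' @param long_threshold_bp segment length separating recent from distant
#'   inbreeding.
#' @return data.frame with columns `iid`, `f_roh`, `f_roh_long`,
#'   `f_roh_short`.
#' @export
compute_froh <- function(segments, ids = NULL, denominator_bp = 2.77e9,
                         long_threshold_bp = 8.5e6) {
  stopifnot(denominator_bp > 0)
  if (nrow(segments) && any(segments$length_bp <= 0)) {
    abort_autozyg("segment with non-positive length", "autozyg_integrity_error")
  }
  ids <- ids %||% unique(segments$iid)
  sum_by <- function(len, iid) {
    s <- tapply(len, factor(iid, levels = ids), sum, default = 0)
    as.numeric(s)
  }
  long <- segments$length_bp > long_threshold_bp
  data.frame(
    iid = ids,
    f_roh = sum_by(segments$length_bp, segments$iid) / denominator_bp,
    f_roh_long = sum_by(segments$length_bp[long], segments$iid[long]) / denominator_bp,
    f_roh_short = sum_by(segments$length_bp[!long], segments$iid[!long]) / denominator_bp
  )
}

#' Excess SNP-by-SNP homozygosity
#'
#' The method-of-moments inbreeding estimate from genotyped SNPs (PLINK's
#' `--het`): per individual, `f_snp = (O - E) / (T - E)` where `O` is the
#' observed homozygous count over the individual's non-missing variants,
#' `T` that variant count, and `E` the Hardy-Weinberg expectation
#' `sum_j 1 - 2 p_j (1 - p_j) * 2N_j / (2N_j - 1)` using cohort allele
#' frequencies (`N_j` = allele-frequency sample size; the `2N/(2N-1)`
#' small-sample correction can be disabled). Because it is computed from
#' genotyped (overwhelmingly common) SNPs, `f_snp` indexes excess
#' homozygosity at common variants only.
#'
#' @param g a `genotypes` object (post-QC).
#' @param small_sample_correction apply the `2N/(2N-1)` factor to expected
#'   heterozygosity.
#' @return data.frame with columns `iid`, `f_snp`, `n_obs`. Individuals with
#'   a degenerate denominator (`T == E`) get `NA` with a warning.
#' @export
compute_fsnp <- function(g, small_sample_correction = TRUE) {
  stopifnot(inherits(g, "genotypes"))
  nonmiss <- !is.na(g$calls)
  n_j <- colSums(nonmiss)
  p <- colSums(g$calls, na.rm = TRUE) / (2 * n_j)
  exp_het <- 2 * p * (1 - p)
  if (small_sample_correction) {
    exp_het <- exp_het * (2 * n_j) / pmax(2 * n_j - 1, 1)
  }
  exp_hom <- 1 - exp_het
  hom <- (g$calls != 1L)
  hom[!nonmiss] <- FALSE
  o <- rowSums(hom)
  e <- as.numeric(nonmiss %*% exp_hom)
  t_obs <- rowSums(nonmiss)
  denom <- t_obs - e
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (o - e) / denom)
  if (anyNA(f)) {
    warning(sprintf("f_snp undefined (T == E) for %d individual(s)", sum(is.na(f))),
      call. = FALSE
    )
  }
  data.frame(iid = g$samples$iid, f_snp = f, n_obs = t_obs)
}

#' Per-individual autozygosity statistics
#'
#' Convenience wrapper combining [call_roh()], [compute_froh()] and
#' [compute_fsnp()] into one table.
#'
#' @param g a `genotypes` object (QC'd and LD-pruned).
#' @param params a [roh_params()] object.
#' @param denominator_bp mappable genome length for the F_ROH denominator.
#' @param long_threshold_bp recent/distant split length.
#' @param small_sample_correction passed to [compute_fsnp()].
#' @return data.frame: `iid`, `f_roh`, `f_roh_long`, `f_roh_short`, `f_snp`.
#' @export
compute_fstats <- function(g, params = roh_params(), denominator_bp = 2.77e9,
                           long_threshold_bp = 8.5e6,
                           small_sample_correction = TRUE) {
  segs <- call_roh(g, params)
  froh <- compute_froh(segs,
    ids = g$samples$iid, denominator_bp = denominator_bp,
    long_threshold_bp = long_threshold_bp
  )
  fsnp <- compute_fsnp(g, small_sample_correction)
  cbind(froh, f_snp = fsnp$f_snp[match(froh$iid, fsnp$iid)])
}
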