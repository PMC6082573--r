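#' Quality-control thresholds
#'
#' Container of the variant- and sample-level QC cutoffs used by
#' [filter_variants()] and [filter_samples()], with the defaults standard in
#' ROH analyses: exact Hardy-Weinberg p < 1e-6, MAF < 0.05, variant and
#' sample missingness > 0.02, pairwise relatedness cutoff pi-hat 0.2 (a
#' stricter 0.05 alternative is common as a sensitivity analysis).
#'
#' @param hwe_p_min variants with exact HWE p below this are removed.
#' @param maf_min variants with minor allele frequency below this are removed.
#' @param variant_missing_max maximum tolerated per-variant missing rate.
#' @param sample_missing_max maximum tolerated per-sample missing rate.
#' @param kinship_max pi-hat above which a pair counts as related.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.05,
                          variant_missing_max = 0.02,
                          sample_missing_max = 0.02,
                          kinship_max = 0.2) {
  vals <- c(hwe_p_min, maf_min, variant_missing_max, sample_missing_max, kinship_max)
  if (any(vals <= 0 | vals >= 1)) {
    abort_autozyg("all QC thresholds must lie in (0, 1)", "autozyg_config_error")
  }
  structure(
    list(
      hwe_p_min = hwe_p_min, maf_min = maf_min,
      variant_missing_max = variant_missing_max,
      sample_missing_max = sample_missing_max,
      kinship_max = kinship_max
    ),
    class = "qc_thresholds"
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele totals, the
#' p-value is the summed probability of every heterozygote count (of the
#' same parity) whose conditional probability does not exceed that of the
#' observed count. The exact test is used rather than the chi-square
#' approximation because QC operates in the far tail (p < 1e-6) where the
#' approximation is unreliable.
#'
#' @param n_het number of heterozygotes.
#' @param n_hom_minor number of minor-allele homozygotes.
#' @param n_hom_major number of major-allele homozygotes.
#' @return The exact two-sided p-value. A monomorphic variant returns 1 by
#'   convention. The test is symmetric in the two homozygote counts.
#' @references Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact
#'   tests of Hardy-Weinberg equilibrium. Am J Hum Genet 76:887-893.
#' @examples
#' hwe_exact_test(n_het = 57, n_hom_minor = 14, n_hom_major = 50)
#' @export
hwe_exact_test <- function(n_het, n_hom_minor, n_hom_major) {
  stopifnot(is_count(n_het), is_count(n_hom_minor), is_count(n_hom_major))
  n <- n_het + n_hom_minor + n_hom_major
  if (n < 1) abort_autozyg("at least one genotype required", "autozyg_config_error")
  n_rare <- min(2 * n_hom_minor + n_het, 2 * n_hom_major + n_het)
  if (n_rare == 0) return(1)
  # feasible heterozygote counts share the parity of the rare-allele total
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  hom_r <- (n_rare - hets) / 2
  hom_c <- n - hets - hom_r
  keep <- hom_c >= 0
  hets <- hets[keep]; hom_r <- hom_r[keep]; hom_c <- hom_c[keep]
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial(hets) - lfactorial(hom_r) - lfactorial(hom_c) +
    lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_het]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# per-variant genotype counts on the folded (minor-allele) scale
variant_counts <- function(calls) {
  n_nonmiss <- colSums(!is.na(calls))
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(calls == 2L, na.rm = TRUE)
  n_hom_ref <- n_nonmiss - n_het - n_hom_alt
  af <- (2 * n_hom_alt + n_het) / (2 * n_nonmiss)
  list(
    n_nonmiss = n_nonmiss, n_het = n_het,
    n_hom_alt = n_hom_alt, n_hom_ref = n_hom_ref,
    maf = pmin(af, 1 - af)
  )
}

#' Variant-level QC filter
#'
#' Removes variants that (a) deviate from Hardy-Weinberg equilibrium at the
#' exact-test threshold, (b) exceed the missing-call-rate limit, or (c) fall
#' below the minor-allele-frequency floor. Rules are applied in that order
#' and each removal is attributed to the first rule that catches it.
#'
#' @param g a `genotypes` object.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with elements `genotypes` (the filtered object) and
#'   `report` (data.frame of rule, n_removed).
#' @export
filter_variants <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotypes"))
  if (ncol(g$calls) == 0L) abort_autozyg("no variants to filter", "autozyg_config_error")
  cnt <- variant_counts(g$calls)
  hwe_p <- vapply(
    seq_along(cnt$n_het),
    function(j) {
      hom <- sort(c(cnt$n_hom_alt[j], cnt$n_hom_ref[j]))
      hwe_exact_test(cnt$n_het[j], hom[1], hom[2])
    },
    numeric(1)
  )
  miss_rate <- 1 - cnt$n_nonmiss / nrow(g$calls)
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_miss <- !fail_hwe & miss_rate > thresholds$variant_missing_max
  fail_maf <- !fail_hwe & !fail_miss & cnt$maf < thresholds$maf_min
  keep <- !(fail_hwe | fail_miss | fail_maf)
  report <- data.frame(
    rule = c("hwe", "missingness", "maf"),
    n_removed = c(sum(fail_hwe), sum(fail_miss), sum(fail_maf))
  )
  if (!any(keep)) {
    warning("variant QC removed every variant", call. = FALSE)
  }
  list(genotypes = g[, keep], report = report)
}

#' Sample-level QC filter
#'
#' Removes individuals whose missing genotype call rate exceeds the
#' threshold.
#'
#' @inheritParams filter_variants
#' @return A list with elements `genotypes` and `report`.
#' @export
filter_samples <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotypes"))
  miss_rate <- rowMeans(is.na(g$calls))
  keep <- miss_rate <= thresholds$sample_missing_max
  if (!any(keep)) warning("sample QC removed every individual", call. = FALSE)
  list(
    genotypes = g[keep, ],
    report = data.frame(rule = "sample_missingness", n_removed = sum(!keep))
  )
}

# VIFs of a set of genotype columns: diagonal of the inverse correlation
# matrix; a ridge fallback handles exactly collinear columns (VIF -> Inf).
window_vifs <- function(x) {
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  out <- tryCatch(diag(solve(r)), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)) || any(out < 0)) {
    out <- diag(solve(r + diag(1e-10, ncol(r))))
  }
  out
}

#' LD pruning by variance inflation factor
#'
#' Mirrors PLINK's `--indep` pruning: a window of `window_snps` variants
#' slides along each chromosome in steps of `step` variants; within each
#' window, the variant with the largest VIF (computed by multiple regression
#' of each variant on all others in the window, i.e. the diagonal of the
#' inverse correlation matrix) is removed while any VIF exceeds `vif_max`.
#' Removals are permanent across windows. `--indep 50 5 10` corresponds to
#' the defaults.
#'
#' @param g a `genotypes` object (post-QC).
#' @param window_snps window size in SNPs.
#' @param step window advance in SNPs.
#' @param vif_max VIF cutoff (10 is equivalent to a multiple R^2 of 0.90).
#' @return Integer vector of kept variant column indices (ascending).
#' @export
vif_prune <- function(g, window_snps = 50, step = 5, vif_max = 10) {
  stopifnot(inherits(g, "genotypes"), window_snps >= 2, step >= 1)
  m <- ncol(g$calls)
  removed <- logical(m)
  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    if (length(idx) < 2L) next
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[!removed[win]]
      # non-constant columns only; a window with fewer than 2 is skipped
      sds <- apply(g$calls[, win, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
      win <- win[!is.na(sds) & sds > 0]
      if (length(win) < 2L) next
      repeat {
        v <- window_vifs(g$calls[, win, drop = FALSE])
        worst <- which.max(v)
        if (v[worst] <= vif_max || length(win) < 2L) break
        removed[win[worst]] <- TRUE
        win <- win[-worst]
        if (length(win) < 2L) break
      }
    }
  }
  which(!removed)
}

#' Genomic relationship (kinship) matrix
#'
#' Entry (i, j) is the mean over variants of
#' `(x_i - 2p)(x_j - 2p) / (2p(1 - p))`, where `x` is the minor-allele count
#' and `p` the cohort minor-allele frequency; variants with a missing call
#' in either individual are excluded pairwise. This is the standard GRM
#' estimator of pairwise relatedness (pi-hat scale: ~1 for self/duplicates,
#' ~0.5 full sibs, ~0 unrelated).
#'
#' @param g a `genotypes` object; variants must be polymorphic.
#' @return A symmetric numeric matrix with iid dimnames; pairs with no
#'   usable variants are `NA`.
#' @export
compute_kinship <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    abort_autozyg("kinship requires polymorphic variants (run QC first)", "autozyg_config_error")
  }
  w <- sweep(g$calls, 2L, 2 * p)
  w <- sweep(w, 2L, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(w)
  w[!obs] <- 0
  num <- tcrossprod(w)
  den <- tcrossprod(obs * 1)
  k <- num / den
  k[den == 0] <- NA_real_
  dimnames(k) <- list(g$samples$iid, g$samples$iid)
  k
}

#' Select a maximal unrelated subset of individuals
#'
#' Greedy heuristic for the minimum-removal objective: repeatedly drop the
#' individual involved in the most remaining pairs with relatedness above
#' `cutoff` (ties broken by input order) until no related pair remains.
#'
#' @param kinship symmetric relatedness matrix, e.g. from [compute_kinship()].
#' @param cutoff pi-hat value above which a pair counts as related.
#' @return Integer vector of retained row indices (ascending).
#' @export
select_unrelated <- function(kinship, cutoff = 0.2) {
  stopifnot(is.matrix(kinship), nrow(kinship) == ncol(kinship))
  adj <- kinship > cutoff
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  keep <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj)
    if (max(deg) == 0) break
    drop <- which.max(deg) # which.max takes the first maximum: input order
    keep[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  which(keep)
}
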