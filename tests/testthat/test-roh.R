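p65 <- roh_params()

test_that("window scan obeys the heterozygote and missingness limits", {
  # 65 clean homozygous SNPs: the single window qualifies, all hit rates 1
  calls <- rep(0L, 65)
  expect_equal(scan_windows(calls, p65), rep(1, 65))

  # one heterozygote anywhere kills the only window (het_max = 0)
  for (pos in c(1, 33, 65)) {
    calls_het <- calls
    calls_het[pos] <- 1L
    expect_equal(scan_windows(calls_het, p65), rep(0, 65))
  }

  # up to 3 missing tolerated, 4 not
  calls_miss <- calls
  calls_miss[c(2, 30, 64)] <- NA
  expect_equal(scan_windows(calls_miss, p65), rep(1, 65))
  calls_miss[40] <- NA
  expect_equal(scan_windows(calls_miss, p65), rep(0, 65))

  # chromosomes shorter than one window yield all-zero hit rates
  expect_equal(scan_windows(rep(2L, 64), p65), rep(0, 64))
})

test_that("window scan equals brute-force enumeration on random call strings", {
  withr::local_seed(101)
  for (rep in 1:50) {
    n <- sample(30:200, 1)
    het_p <- runif(1, 0, 0.15)
    miss_p <- runif(1, 0, 0.08)
    calls <- sample(c(0L, 2L), n, replace = TRUE)
    calls[runif(n) < het_p] <- 1L
    calls[runif(n) < miss_p] <- NA
    params <- roh_params(
      window_snps = sample(5:30, 1), window_het_max = sample(0:2, 1),
      window_missing_max = sample(0:3, 1), min_snps = 5, min_kb = 0
    )
    expect_equal(scan_windows(calls, params), oracle_scan(calls, params))
  }
})

test_that("segment assembly keeps planted runs and applies gap/density/min-SNP rules", {
  # 100 homozygous SNPs spanning ~1 Mb, heterozygous flanks
  pos <- c(seq(1e5, by = 1e4, length.out = 10),
           seq(2e6, by = 1e4, length.out = 100),
           seq(4e6, by = 1e4, length.out = 10))
  calls <- c(rep(1L, 10), rep(0L, 100), rep(1L, 10))
  params <- roh_params(window_snps = 20, min_snps = 20, min_kb = 10)
  seg <- assemble_segments(scan_windows(calls, params), calls, pos, params)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_idx, 11L)
  expect_equal(seg$end_idx, 110L)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$length_bp, pos[110] - pos[11] + 1)

  # a 600 kb gap splits the run; each half of 50 SNPs < min_snps 65 -> nothing
  pos2 <- c(seq(1e6, by = 1e4, length.out = 50), seq(2.1e6, by = 1e4, length.out = 50))
  calls2 <- rep(0L, 100)
  seg2 <- assemble_segments(scan_windows(calls2, p65), calls2, pos2, p65)
  expect_equal(nrow(seg2), 0L)

  # 70 homozygous SNPs spread over 20 Mb: ~290 kb/SNP violates the density rule
  pos3 <- round(seq(1e6, 21e6, length.out = 70))
  calls3 <- rep(0L, 70)
  params3 <- roh_params(gap_kb = 1e6) # disable the gap split to isolate density
  seg3 <- assemble_segments(scan_windows(calls3, params3), calls3, pos3, params3)
  expect_equal(nrow(seg3), 0L)
})

test_that("leading and trailing missing calls are trimmed from segments", {
  calls <- c(NA, rep(0L, 70), NA, NA)
  pos <- seq(1e6, by = 1e4, length.out = 73)
  seg <- assemble_segments(scan_windows(calls, p65), calls, pos, p65)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_idx, 2L)
  expect_equal(seg$end_idx, 71L)
})

test_that("cohort ROH calling is empty for heterozygous cohorts and order-equivariant", {
  g <- make_genotypes(matrix(1L, 4, 100), bp = 1000L * seq_len(100))
  expect_equal(nrow(call_roh(g)), 0L)

  sim <- simulate_cohort(sim_config(
    n_individuals = 12, n_variants = 3000, genome_length_bp = 3e7,
    inbreeding = list(f_target = c(0, 0.2), g = 6), seed = 5
  ))
  segs <- call_roh(sim$genotypes)
  perm <- c(5, 1, 12, 3, 9, 7, 2, 11, 4, 10, 8, 6)
  segs_p <- call_roh(sim$genotypes[perm, ])
  expect_equal(
    segs[order(segs$iid, segs$chrom, segs$start_bp), ],
    segs_p[order(segs_p$iid, segs_p$chrom, segs_p$start_bp), ],
    ignore_attr = TRUE
  )
})

test_that("non-autosomal variants are excluded from ROH calling", {
  calls <- matrix(0L, 2, 140)
  g <- genotypes(
    calls,
    variants = data.frame(
      chrom = rep(c("1", "X"), each = 70), id = sprintf("s%03d", 1:140), cm = 0,
      bp = rep(1000L * seq_len(70), 2), a1 = "A", a2 = "G"
    ),
    samples = data.frame(fid = c("f1", "f2"), iid = c("i1", "i2"), sex = 1L)
  )
  expect_message(segs <- call_roh(g), "non-autosomal")
  expect_true(all(segs$chrom == "1"))
  expect_equal(nrow(segs), 2L) # one segment per individual, chromosome 1 only
})

test_that("F_ROH arithmetic follows the fixed denominator and 8.5 Mb split", {
  # no segments: all zeros
  empty <- data.frame(
    iid = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), n_snps = integer(0), length_bp = numeric(0)
  )
  f0 <- compute_froh(empty, ids = "i1")
  expect_equal(unlist(f0[, -1]), c(f_roh = 0, f_roh_long = 0, f_roh_short = 0))

  # one 27.7 Mb segment: f_roh = 0.01, all of it long
  seg <- data.frame(iid = "i1", chrom = "1", start_bp = 1, end_bp = 27.7e6,
                    n_snps = 2770L, length_bp = 27.7e6)
  f1 <- compute_froh(seg)
  expect_equal(f1$f_roh, 0.01)
  expect_equal(f1$f_roh_long, 0.01)
  expect_equal(f1$f_roh_short, 0)

  # 9 Mb + 3 Mb: split across the 8.5 Mb threshold, parts sum exactly
  seg2 <- data.frame(
    iid = "i1", chrom = c("1", "2"), start_bp = c(1, 1),
    end_bp = c(9e6, 3e6), n_snps = c(900L, 300L), length_bp = c(9e6, 3e6)
  )
  f2 <- compute_froh(seg2)
  expect_equal(f2$f_roh_long, 9e6 / 2.77e9)
  expect_equal(f2$f_roh_short, 3e6 / 2.77e9)
  expect_equal(f2$f_roh_long + f2$f_roh_short, f2$f_roh)
})

test_that("the long/short partition sums to f_roh and f_roh is monotone in segments", {
  withr::local_seed(17)
  sim <- simulate_cohort(sim_config(
    n_individuals = 30, n_variants = 4000, genome_length_bp = 4e7,
    inbreeding = list(f_target = c(0, 0.25), g = 6), seed = 23
  ))
  segs <- call_roh(sim$genotypes)
  fs <- compute_froh(segs, ids = sim$genotypes$samples$iid, denominator_bp = 4e7)
  expect_equal(fs$f_roh_long + fs$f_roh_short, fs$f_roh, tolerance = 1e-12)
  expect_true(all(fs$f_roh >= 0 & fs$f_roh <= 1))

  # adding a disjoint segment never decreases f_roh
  extra <- segs[1, ]
  extra$chrom <- "21"
  fs2 <- compute_froh(rbind(segs, extra), ids = sim$genotypes$samples$iid,
                      denominator_bp = 4e7)
  expect_true(all(fs2$f_roh >= fs$f_roh))
})

test_that("negative-length segments violate the invariant", {
  bad <- data.frame(iid = "i", chrom = "1", start_bp = 10, end_bp = 5,
                    n_snps = 65L, length_bp = -4)
  expect_error(compute_froh(bad), class = "autozyg_integrity_error")
})

test_that("f_snp is 1 for fully homozygous individuals and matches hand arithmetic", {
  withr::local_seed(41)
  calls <- sapply(runif(60, 0.2, 0.5), function(p) rbinom(40, 2, p))
  calls[1, ] <- 2L # fully homozygous individual
  calls <- calls[, colMeans(calls) / 2 > 0 & colMeans(calls) / 2 < 1]
  g <- make_genotypes(calls)
  f <- compute_fsnp(g)
  expect_equal(f$f_snp[1], 1)

  # 3-variant toy case, hand-computed from the (O - E)/(T - E) formula
  toy <- matrix(c(
    0L, 1L, 2L,
    1L, 1L, 0L,
    2L, 0L, 1L,
    0L, 0L, 2L
  ), nrow = 4, byrow = TRUE)
  gt <- make_genotypes(toy)
  n <- 4
  p <- colSums(toy) / (2 * n)
  e_hom <- 1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  o <- rowSums(toy != 1L)
  f_hand <- (o - sum(e_hom)) / (3 - sum(e_hom))
  expect_equal(compute_fsnp(gt)$f_snp, f_hand)
  # without the small-sample factor the expectation changes accordingly
  e0 <- 1 - 2 * p * (1 - p)
  expect_equal(
    compute_fsnp(gt, small_sample_correction = FALSE)$f_snp,
    (o - sum(e0)) / (3 - sum(e0))
  )
})

test_that("mean f_snp is near zero in an outbred Hardy-Weinberg cohort", {
  withr::local_seed(43)
  n <- 400
  calls <- sapply(runif(2000, 0.1, 0.5), function(p) rbinom(n, 2, p))
  calls <- calls[, colMeans(calls) / 2 > 0 & colMeans(calls) / 2 < 1]
  g <- make_genotypes(calls)
  f <- compute_fsnp(g)
  se <- sd(f$f_snp) / sqrt(n)
  expect_lt(abs(mean(f$f_snp)), 3 * se + 1e-3)
})

test_that("f_roh tracks true autozygosity closely at array density", {
  sim <- simulate_cohort(sim_config(
    n_individuals = 100, n_variants = 10000, genome_length_bp = 1e8,
    inbreeding = list(f_target = c(0, 0.15), g = 6), seed = 29
  ))
  fs <- compute_froh(call_roh(sim$genotypes),
    ids = sim$genotypes$samples$iid, denominator_bp = 1e8
  )
  expect_gte(cor(fs$f_roh, sim$truth$f), 0.9)
})

test_that("recent inbreeding inflates the variance of f_roh_long relative to distant", {
  recent <- simulate_cohort(sim_config(
    n_individuals = 120, n_variants = 8000, genome_length_bp = 2e8,
    inbreeding = list(f_target = 0.08, g = 2), seed = 31
  ))
  distant <- simulate_cohort(sim_config(
    n_individuals = 120, n_variants = 8000, genome_length_bp = 2e8,
    inbreeding = list(f_target = 0.08, g = 10), seed = 31
  ))
  f_recent <- compute_froh(call_roh(recent$genotypes),
    ids = recent$genotypes$samples$iid, denominator_bp = 2e8
  )
  f_distant <- compute_froh(call_roh(distant$genotypes),
    ids = distant$genotypes$samples$iid, denominator_bp = 2e8
  )
  expect_gt(var(f_recent$f_roh_long), var(f_distant$f_roh_long))
})
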