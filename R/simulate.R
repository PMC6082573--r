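#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-cohort
#' generator. The generator emulates the statistical structure the
#' autozygosity analysis assumes: independent sites at array-like density
#' (default 1 SNP / 10 kb), per-individual autozygous tracts whose lengths
#' are exponential with mean `100 / (2g)` cM (1 cM = 1 Mb), fully
#' recessive quantitative phenotypes driven by minor-allele homozygosity
#' at common (MAF > 0.05) or rare (MAF < 0.05) causal variants, and an
#' optional latent sociodemographic confounder that depresses autozygosity
#' and raises the trait, inducing a spurious F-trait association.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of variants on the (single, autosomal)
#'   synthetic chromosome.
#' @param genome_length_bp simulated genome length in bases; also the
#'   F_ROH denominator for synthetic data.
#' @param maf_distribution `list(kind = "uniform", low, high)` or
#'   `list(kind = "beta", a, b)`; draws are folded to at most 0.5.
#' @param inbreeding `list(f_target = c(lo, hi) or single value, g)`:
#'   per-individual target autozygous fraction (uniform between the
#'   bounds) and generations to the common ancestor setting tract scale.
#' @param causal `list(maf_class = "none"|"common"|"rare", n_causal,
#'   effect_size)`; effects are fully recessive (minor-allele homozygote
#'   indicator), negative effect sizes encode inbreeding depression.
#' @param noise_sd standard deviation of the environmental trait noise.
#' @param confounder `list(kind = "none")` or `list(kind =
#'   "sociodemographic", strength_on_f, strength_on_trait, f_max,
#'   base_p)`.
#' @param miss_rate genotype missingness rate.
#' @param seed RNG seed; mandatory, every stochastic run is reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000,
                       n_variants = 20000,
                       genome_length_bp = 2e8,
                       maf_distribution = list(kind = "uniform", low = 0.01, high = 0.5),
                       inbreeding = list(f_target = c(0, 0.1), g = 6),
                       causal = list(maf_class = "none", n_causal = 0, effect_size = 0),
                       noise_sd = 1,
                       confounder = list(kind = "none"),
                       miss_rate = 0.001,
                       seed = 1) {
  stopifnot(
    is_count(n_individuals), n_individuals >= 1,
    is_count(n_variants), n_variants >= 1,
    genome_length_bp > n_variants,
    is_count(seed)
  )
  f <- inbreeding$f_target
  if (any(f < 0) || any(f >= 1)) {
    abort_autozyg("target autozygous fraction must lie in [0, 1)", "autozyg_config_error")
  }
  if (!causal$maf_class %in% c("none", "common", "rare")) {
    abort_autozyg("causal$maf_class must be none, common or rare", "autozyg_config_error")
  }
  if (causal$maf_class != "none" && causal$n_causal > n_variants) {
    abort_autozyg("n_causal exceeds n_variants", "autozyg_config_error")
  }
  if (!confounder$kind %in% c("none", "sociodemographic")) {
    abort_autozyg("unknown confounder kind", "autozyg_config_error")
  }
  structure(
    list(
      n_individuals = n_individuals, n_variants = n_variants,
      genome_length_bp = genome_length_bp,
      maf_distribution = maf_distribution, inbreeding = inbreeding,
      causal = causal, noise_sd = noise_sd, confounder = confounder,
      miss_rate = miss_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw variant positions and allele frequencies
#'
#' Positions are uniform over the genome, forced strictly increasing;
#' minor-allele frequencies are drawn from the configured distribution and
#' folded to at most 0.5.
#'
#' @param cfg a [sim_config()] object. Consumes the current RNG stream;
#'   call [set.seed()] (or go through [simulate_cohort()]) for
#'   reproducibility.
#' @return data.frame with columns `bp`, `maf`.
#' @export
simulate_frequencies <- function(cfg) {
  m <- cfg$n_variants
  base <- sort(stats::runif(m, 0, cfg$genome_length_bp - m))
  bp <- floor(base) + seq_len(m)
  md <- cfg$maf_distribution
  raw <- switch(md$kind,
    uniform = stats::runif(m, md$low, md$high),
    beta = stats::rbeta(m, md$a, md$b),
    abort_autozyg("maf_distribution$kind must be uniform or beta", "autozyg_config_error")
  )
  maf <- pmax(pmin(raw, 1 - raw), 1e-4)
  data.frame(bp = bp, maf = maf)
}

# choose causal variant indices within the configured MAF class
pick_causal <- function(maf, causal) {
  if (causal$maf_class == "none" || causal$n_causal == 0) return(integer(0))
  pool <- switch(causal$maf_class,
    common = which(maf > 0.05),
    rare = which(maf < 0.05)
  )
  if (length(pool) < causal$n_causal) {
    abort_autozyg(
      sprintf(
        "maf_distribution yields only %d %s variants; %d causal requested",
        length(pool), causal$maf_class, causal$n_causal
      ),
      "autozyg_config_error"
    )
  }
  sort(sample(pool, causal$n_causal))
}

# place non-overlapping exponential tracts totalling >= f_target * genome
place_tracts <- function(f_target, g, genome_length_bp, max_tries = 1000) {
  if (f_target <= 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  mean_len <- 100 / (2 * g) * 1e6 # 100/(2g) cM at 1 cM per Mb
  goal <- f_target * genome_length_bp
  starts <- numeric(0)
  ends <- numeric(0)
  total <- 0
  redraws <- 0L
  while (total < goal) {
    len <- max(1, stats::rexp(1, rate = 1 / mean_len))
    # a tract longer than the free genome can never be placed: redraw
    if (len > 0.45 * genome_length_bp) {
      redraws <- redraws + 1L
      if (redraws > max_tries) {
        abort_autozyg(
          "cannot place non-overlapping tracts; reduce the target autozygous fraction or tract scale",
          "autozyg_config_error"
        )
      }
      next
    }
    tries <- 0L
    placed <- FALSE
    repeat {
      s <- stats::runif(1, 1, genome_length_bp - len)
      e <- s + len - 1
      if (!length(starts) || all(e < starts | s > ends)) {
        placed <- TRUE
        break
      }
      tries <- tries + 1L
      if (tries > 200L) break
    }
    if (!placed) {
      # this length does not fit the remaining free space: redraw it
      redraws <- redraws + 1L
      if (redraws > max_tries) {
        abort_autozyg(
          "cannot place non-overlapping tracts; reduce the target autozygous fraction or tract scale",
          "autozyg_config_error"
        )
      }
      next
    }
    starts <- c(starts, s)
    ends <- c(ends, e)
    total <- total + len
  }
  ord <- order(starts)
  data.frame(start = starts[ord], end = ends[ord])
}

#' Simulate one individual's genotypes with planted autozygous tracts
#'
#' Two haplotypes are drawn independently from the allele frequencies;
#' within each planted tract the second haplotype copies the first, so
#' every in-tract variant is homozygous by construction. Tract lengths are
#' exponential with mean `100/(2g)` Mb, placed uniformly without overlap
#' until the summed length reaches `f_target * genome_length_bp` (the last
#' tract may overshoot; the realized fraction is recorded in the truth).
#'
#' @param freqs per-variant minor allele frequencies.
#' @param positions per-variant bp positions (strictly increasing).
#' @param genome_length_bp genome length.
#' @param f_target target autozygous fraction in [0, 1).
#' @param g generations to the tract-donating common ancestor.
#' @return List with `calls` (integer vector of minor-allele counts) and
#'   `truth` (`mask` data.frame of tract intervals, realized `f`).
#' @export
simulate_individual <- function(freqs, positions, genome_length_bp, f_target, g) {
  stopifnot(length(freqs) == length(positions), f_target < 1)
  mask <- place_tracts(f_target, g, genome_length_bp)
  m <- length(freqs)
  hap1 <- as.integer(stats::runif(m) < freqs)
  hap2 <- as.integer(stats::runif(m) < freqs)
  if (nrow(mask)) {
    for (t in seq_len(nrow(mask))) {
      j <- which(positions >= mask$start[t] & positions <= mask$end[t])
      hap2[j] <- hap1[j]
    }
  }
  list(
    calls = hap1 + hap2,
    truth = list(
      mask = mask,
      f = sum(mask$end - mask$start + 1) / genome_length_bp
    )
  )
}

#' Fully recessive phenotype from causal minor-allele homozygosity
#'
#' `trait = effect_size * (number of causal variants at which the
#' individual is a minor-allele homozygote) + Normal(0, noise_sd)`. A
#' negative effect size encodes inbreeding depression through directional
#' dominance: only the homozygous recessive state moves the trait.
#'
#' @param calls genotype matrix (individuals x variants, minor-allele
#'   counts).
#' @param causal_idx column indices of the causal variants.
#' @param effect_size per-homozygote effect.
#' @param noise_sd environmental noise standard deviation.
#' @return List with `trait` (numeric vector) and `genetic` (the noiseless
#'   genetic component).
#' @export
recessive_phenotype <- function(calls, causal_idx, effect_size, noise_sd) {
  n <- nrow(calls)
  genetic <- if (length(causal_idx)) {
    effect_size * rowSums(calls[, causal_idx, drop = FALSE] == 2L, na.rm = TRUE)
  } else {
    rep(0, n)
  }
  list(trait = genetic + stats::rnorm(n, 0, noise_sd), genetic = genetic)
}

# shared covariate block for synthetic phenotype tables
simulate_covariates <- function(n) {
  data.frame(
    sex = sample(c(1L, 2L), n, replace = TRUE),
    age = round(stats::runif(n, 40, 70)),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n)
  )
}

#' Simulate a full cohort
#'
#' Draws variants, plants per-individual autozygous tracts, generates the
#' (optional) recessive phenotype and covariates, and applies genotype
#' missingness. Fully deterministic given the config (including its seed).
#'
#' @param cfg a [sim_config()] object.
#' @return A list of class `autozyg_sim`:
#'   `genotypes` (a [genotypes()] object),
#'   `phenotypes` (data.frame: iid, sex, age, age2, batch, miss_frac,
#'   pc1-pc3, trait),
#'   `truth` (list: per-individual tract `mask`s, realized `f`, `genetic`
#'   trait components, `causal_idx`, per-variant `maf`),
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_rng(cfg$seed)
  n <- cfg$n_individuals
  fr <- simulate_frequencies(cfg)
  causal_idx <- pick_causal(fr$maf, cfg$causal)
  ft <- cfg$inbreeding$f_target
  f_targets <- if (length(ft) == 2L) stats::runif(n, ft[1], ft[2]) else rep(ft, n)

  calls <- matrix(NA_integer_, n, cfg$n_variants)
  masks <- vector("list", n)
  true_f <- numeric(n)
  for (i in seq_len(n)) {
    ind <- simulate_individual(
      fr$maf, fr$bp, cfg$genome_length_bp, f_targets[i], cfg$inbreeding$g
    )
    calls[i, ] <- ind$calls
    masks[[i]] <- ind$truth$mask
    true_f[i] <- ind$truth$f
  }
  if (cfg$miss_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$miss_rate] <- NA_integer_
  }
  phe <- recessive_phenotype(calls, causal_idx, cfg$causal$effect_size, cfg$noise_sd)

  iid <- sprintf("ind%05d", seq_len(n))
  g <- genotypes(
    calls = calls,
    variants = data.frame(
      chrom = "1", id = sprintf("snp%06d", seq_len(cfg$n_variants)),
      cm = 0, bp = fr$bp, a1 = "A", a2 = "G"
    ),
    samples = data.frame(fid = iid, iid = iid, sex = 0L)
  )
  cov <- simulate_covariates(n)
  pheno <- data.frame(
    iid = iid, cov,
    age2 = cov$age^2,
    miss_frac = rowMeans(is.na(calls)),
    trait = phe$trait
  )
  names(masks) <- iid
  structure(
    list(
      genotypes = g,
      phenotypes = pheno,
      truth = list(
        mask = masks, f = stats::setNames(true_f, iid),
        genetic = phe$genetic, causal_idx = causal_idx, maf = fr$maf
      ),
      config = cfg
    ),
    class = "autozyg_sim"
  )
}

#' @export
print.autozyg_sim <- function(x, ...) {
  cat(sprintf(
    "<autozyg_sim> %d individuals x %d variants, mean true F = %.4f, causal class: %s\n",
    nrow(x$genotypes$calls), ncol(x$genotypes$calls), mean(x$truth$f),
    x$config$causal$maf_class
  ))
  invisible(x)
}

#' Simulate a confounded cohort
#'
#' The pure-confounding scenario: a latent standard-normal sociodemographic
#' score `S` both suppresses autozygosity (the target autozygous fraction
#' is `f_max * plogis(qlogis(base_p) - strength_on_f * S)`, a decreasing
#' logistic function of `S`) and raises the trait
#' (`trait = strength_on_trait * S + noise`), with no causal variant
#' anywhere. Any F-trait association in this cohort is spurious and should
#' vanish once the observed proxy of `S` (exported as the `income` column)
#' is adjusted for.
#'
#' @param cfg a [sim_config()] object whose `confounder$kind` is
#'   `"sociodemographic"`.
#' @return An `autozyg_sim` list as in [simulate_cohort()]; `phenotypes`
#'   gains an `income` column (= S) and `truth` an `s` element.
#' @export
confounded_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$confounder$kind != "sociodemographic") {
    abort_autozyg("cfg$confounder$kind must be 'sociodemographic'", "autozyg_config_error")
  }
  cf <- cfg$confounder
  f_max <- cf$f_max %||% 0.1
  base_p <- cf$base_p %||% 0.5
  seed_rng(cfg$seed)
  n <- cfg$n_individuals
  s <- stats::rnorm(n)
  f_targets <- f_max * stats::plogis(stats::qlogis(base_p) - cf$strength_on_f * s)

  fr <- simulate_frequencies(cfg)
  calls <- matrix(NA_integer_, n, cfg$n_variants)
  masks <- vector("list", n)
  true_f <- numeric(n)
  for (i in seq_len(n)) {
    ind <- simulate_individual(
      fr$maf, fr$bp, cfg$genome_length_bp, f_targets[i], cfg$inbreeding$g
    )
    calls[i, ] <- ind$calls
    masks[[i]] <- ind$truth$mask
    true_f[i] <- ind$truth$f
  }
  if (cfg$miss_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$miss_rate] <- NA_integer_
  }
  trait <- cf$strength_on_trait * s + stats::rnorm(n, 0, cfg$noise_sd)

  iid <- sprintf("ind%05d", seq_len(n))
  g <- genotypes(
    calls = calls,
    variants = data.frame(
      chrom = "1", id = sprintf("snp%06d", seq_len(cfg$n_variants)),
      cm = 0, bp = fr$bp, a1 = "A", a2 = "G"
    ),
    samples = data.frame(fid = iid, iid = iid, sex = 0L)
  )
  cov <- simulate_covariates(n)
  pheno <- data.frame(
    iid = iid, cov,
    age2 = cov$age^2,
    miss_frac = rowMeans(is.na(calls)),
    income = s,
    trait = trait
  )
  names(masks) <- iid
  structure(
    list(
      genotypes = g,
      phenotypes = pheno,
      truth = list(
        mask = masks, f = stats::setNames(true_f, iid),
        genetic = rep(0, n), causal_idx = integer(0), maf = fr$maf, s = s
      ),
      config = cfg
    ),
    class = "autozyg_sim"
  )
}

#' Simulate genotypes in correlated LD blocks
#'
#' Fixture generator for the LD-pruning stage (the main cohort simulator
#' uses independent sites): variants come in blocks sharing a latent
#' Gaussian factor with loading `sqrt(r2)`, thresholded to Hardy-Weinberg
#' genotype frequencies, so within-block genotype correlations are ~`r2`
#' and across-block correlations are ~0.
#'
#' @param n_individuals cohort size.
#' @param n_blocks number of independent blocks.
#' @param block_size variants per block.
#' @param r2 target squared correlation of each variant with the block
#'   factor (1 makes all variants in a block identical).
#' @param maf_range range of minor allele frequencies.
#' @param spacing_bp distance between adjacent variants.
#' @param seed RNG seed.
#' @return A `genotypes` object.
#' @export
simulate_ld_blocks <- function(n_individuals, n_blocks, block_size, r2,
                               maf_range = c(0.1, 0.5), spacing_bp = 10000,
                               seed = NULL) {
  seed_rng(seed)
  m <- n_blocks * block_size
  maf <- stats::runif(n_blocks, maf_range[1], maf_range[2]) # one frequency per block
  calls <- matrix(NA_integer_, n_individuals, m)
  for (b in seq_len(n_blocks)) {
    u <- stats::rnorm(n_individuals)
    p <- maf[b]
    q1 <- stats::qnorm((1 - p)^2)
    q2 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
    for (k in seq_len(block_size)) {
      x <- sqrt(r2) * u + sqrt(1 - r2) * stats::rnorm(n_individuals)
      calls[, (b - 1) * block_size + k] <- (x > q1) + (x > q2)
    }
  }
  iid <- sprintf("ind%05d", seq_len(n_individuals))
  genotypes(
    calls = calls,
    variants = data.frame(
      chrom = "1", id = sprintf("snp%06d", seq_len(m)), cm = 0,
      bp = spacing_bp * seq_len(m), a1 = "A", a2 = "G"
    ),
    samples = data.frame(fid = iid, iid = iid, sex = 0L)
  )
}
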