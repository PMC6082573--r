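test_that("range exclusions blank values trait-wise with strict bounds", {
  pheno <- data.frame(
    iid = c("a", "b", "c"),
    systolic_bp = c(120, 205, 200),
    grip_strength = c(30, 70, 71),
    height = c(180, 119, 120)
  )
  rules <- default_exclusions()[c("systolic_bp", "grip_strength", "height")]
  out <- apply_exclusions(pheno, rules)
  expect_equal(is.na(out$systolic_bp), c(FALSE, TRUE, FALSE)) # 200 exactly stays
  expect_equal(is.na(out$grip_strength), c(FALSE, FALSE, TRUE)) # 70.0 exactly stays
  expect_equal(is.na(out$height), c(FALSE, TRUE, FALSE)) # 120 exactly stays
  # exclusion is trait-wise: individual b keeps its other traits
  expect_false(is.na(out$grip_strength[2]))

  # all values within bounds: table unchanged
  ok <- data.frame(iid = "a", systolic_bp = 140)
  expect_identical(apply_exclusions(ok, rules["systolic_bp"]), ok)

  expect_error(
    apply_exclusions(pheno, list(no_such_trait = c(0, 1))),
    "unknown column", class = "autozyg_config_error"
  )
})

test_that("within-sex standardization yields mean-0 variance-1 strata", {
  v <- c(1, 2, 3, 10, 20, 30)
  sex <- c(1, 1, 1, 2, 2, 2)
  expect_equal(standardize_within_sex(v, sex), rep(c(-1, 0, 1), 2))

  withr::local_seed(8)
  vals <- rnorm(200, mean = 5, sd = 3)
  vals[sample(200, 10)] <- NA
  sx <- sample(c("m", "f"), 200, replace = TRUE)
  z <- standardize_within_sex(vals, sx)
  for (s in c("m", "f")) {
    i <- sx == s & !is.na(z)
    expect_lt(abs(mean(z[i])), 1e-12)
    expect_equal(sd(z[i]), 1)
    # oracle: explicit per-stratum mean/sd
    expect_equal(z[i], (vals[i] - mean(vals[i])) / sd(vals[i]))
  }
  expect_true(all(is.na(z[is.na(vals)])))

  expect_error(
    standardize_within_sex(c(1, 1, 2, 3), c("m", "m", "f", "f")),
    "zero variance", class = "autozyg_config_error"
  )
})

test_that("the linear fit reproduces exact and hand-solved coefficients", {
  d <- data.frame(y = 2 * c(1, 2, 3, 4), f_roh = c(1, 2, 3, 4))
  fit <- fit_linear(d, "y", "f_roh")
  expect_equal(unname(coef(fit)), 2)
  expect_lt(suppressWarnings(summary(fit))$sigma, 1e-10)

  # 6-point dataset solved by the normal equations directly
  d6 <- data.frame(
    y = c(1.2, 0.7, 2.9, 3.1, 1.8, 2.2),
    x = c(0.1, 0.0, 0.5, 0.6, 0.3, 0.4),
    z = c(1, 0, 1, 0, 1, 0)
  )
  X <- cbind(1, d6$x, d6$z)
  beta_hand <- solve(t(X) %*% X, t(X) %*% d6$y)
  fit6 <- fit_linear(d6, "y", "x", "z")
  expect_equal(unname(coef(fit6$fit)), as.numeric(beta_hand), tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  d <- data.frame(y = rnorm(30), f_roh = runif(30), dup = NA)
  d$dup <- d$f_roh * 2
  expect_error(
    fit_linear(d, "y", "f_roh", "dup"),
    "collinear", class = "autozyg_rank_error"
  )
})

test_that("the logistic fit matches the closed-form odds ratio on a 2x2 table", {
  # counts: exposed cases a=20, exposed controls b=30, unexposed c=15, d=40
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), c(20, 30, 15, 40)),
    x = rep(c(1, 1, 0, 0), c(20, 30, 15, 40))
  )
  fit <- fit_logistic(d, "y", "x")
  expect_equal(unname(coef(fit)), log(20 * 40 / (30 * 15)), tolerance = 1e-6)

  expect_error(
    fit_logistic(data.frame(y = rep(1, 20), x = rnorm(20)), "y", "x"),
    "single class", class = "autozyg_config_error"
  )
  # perfect separation is an error, not silent output
  sep <- data.frame(y = rep(c(0, 1), each = 20), x = c(rnorm(20), rnorm(20) + 50))
  expect_error(fit_logistic(sep, "y", "x"), class = "autozyg_convergence_error")
})

test_that("null logistic models are calibrated", {
  withr::local_seed(77)
  p <- replicate(50, {
    d <- data.frame(y = rbinom(400, 1, 0.4), f_roh = runif(400, 0, 0.1))
    fit_logistic(d, "y", "f_roh")$coefficients$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("attenuation reproduces simple arithmetic and signals increases", {
  expect_equal(attenuation(5, 5), 0)
  expect_equal(attenuation(4, 2), 50)
  expect_equal(attenuation(-4, -2), 50) # works on magnitudes
  expect_equal(attenuation(2, 3), -50) # adjusted estimate grew
  expect_error(attenuation(0, 1), class = "autozyg_config_error")
})

test_that("Bonferroni thresholds follow 0.05 / n_traits", {
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(19), 0.05 / 19)
  expect_lt(bonferroni_alpha(19), 0.003)
})

test_that("model sets skip sociodemographic traits in adjusted sets and flag significance", {
  withr::local_seed(55)
  n <- 300
  d <- data.frame(
    f_roh = runif(n, 0, 0.1), f_snp = rnorm(n, 0, 0.02),
    sex = sample(1:2, n, TRUE), age = runif(n, 40, 70),
    income = rnorm(n)
  )
  d$age2 <- d$age^2
  d$trait_a <- -5 * d$f_roh + rnorm(n, 0, 0.1)
  d$trait_b <- rnorm(n)
  res <- run_model_sets(
    d,
    traits = c("trait_a", "trait_b", "income"),
    predictor = "f_roh",
    minimal_covariates = c("sex", "age", "age2"),
    sociodemographic_covariates = "income",
    sociodemographic_traits = "income"
  )
  expect_s3_class(res, "roh_burden_scan")
  # income modelled in set 1 only
  expect_equal(sort(unique(res$set[res$trait == "income"])), 1)
  # set 3 reports both the f_roh and the f_snp coefficient
  s3 <- res[res$set == 3 & res$trait == "trait_a", ]
  expect_setequal(s3$predictor, c("f_roh", "f_snp"))
  # per-set Bonferroni: 3 traits in set 1, 2 traits in sets 2-3
  expect_equal(unique(res$alpha[res$set == 1]), 0.05 / 3)
  expect_equal(unique(res$alpha[res$set == 2]), 0.05 / 2)
  # the planted strong effect is significant, the null trait is not
  expect_true(all(res$significant[res$trait == "trait_a" & res$predictor == "f_roh"]))
  expect_false(any(res$significant[res$trait == "trait_b"]))
})

test_that("estimates are invariant to row order and affine covariate rescaling", {
  withr::local_seed(66)
  n <- 200
  d <- data.frame(
    y = rnorm(n), f_roh = runif(n, 0, 0.1), age = runif(n, 40, 70),
    pc1 = rnorm(n)
  )
  d$y <- d$y - 2 * d$f_roh + 0.3 * d$pc1
  f1 <- fit_linear(d, "y", "f_roh", c("age", "pc1"))
  f2 <- fit_linear(d[sample(n), ], "y", "f_roh", c("age", "pc1"))
  expect_equal(coef(f1), coef(f2))
  d2 <- d
  d2$age <- 3 * d2$age - 100
  d2$pc1 <- -0.5 * d2$pc1 + 1
  f3 <- fit_linear(d2, "y", "f_roh", c("age", "pc1"))
  expect_equal(coef(f1), coef(f3), tolerance = 1e-10)
})

test_that("sex-interaction test detects differential slopes and respects coding flips", {
  withr::local_seed(91)
  n <- 4000
  sex <- sample(0:1, n, TRUE)
  f <- runif(n, 0, 0.1)
  y <- -3 * f * sex + rnorm(n, 0, 0.1) # slope -3 in one sex, 0 in the other
  d <- data.frame(y = y, f_roh = f, sex = sex, age = runif(n, 40, 70))
  res <- sex_interaction_test(d, "y", "f_roh", c("age", "sex"))
  expect_lt(res$p, 0.002)
  expect_equal(res$beta, -3, tolerance = 0.3)

  # flipping the sex coding negates the interaction coefficient
  d2 <- d
  d2$sex <- 1 - d2$sex
  res2 <- sex_interaction_test(d2, "y", "f_roh", c("age", "sex"))
  expect_equal(res2$beta, -res$beta, tolerance = 1e-8)

  expect_error(
    sex_interaction_test(within(d, sex <- 1), "y", "f_roh", c("age", "sex")),
    "both sexes", class = "autozyg_config_error"
  )
})

test_that("sex-interaction test is calibrated under equal slopes", {
  withr::local_seed(93)
  p <- replicate(100, {
    n <- 400
    sex <- sample(0:1, n, TRUE)
    f <- runif(n, 0, 0.1)
    d <- data.frame(y = -2 * f + rnorm(n), f_roh = f, sex = sex)
    sex_interaction_test(d, "y", "f_roh", "sex")$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("the indirect-effect bootstrap point estimate is resample-free and the CI behaves", {
  withr::local_seed(12)
  n <- 400
  f <- runif(n, 0, 0.1)
  med <- 4 * f + rnorm(n, 0, 0.05) # fully mediated chain f -> med -> y
  y <- -2 * med + rnorm(n, 0, 0.1)
  d <- data.frame(y = y, f_roh = f, med = med)
  b1 <- indirect_effect_bootstrap(d, "y", "f_roh", "med", n_boot = 1000, seed = 3)
  b2 <- indirect_effect_bootstrap(d, "y", "f_roh", "med", n_boot = 2000, seed = 3)
  expect_identical(b1$estimate, b2$estimate)
  expect_true(b1$significant)
  # the indirect effect carries essentially the whole total effect
  total <- coef(fit_linear(d, "y", "f_roh"))[[1]]
  expect_equal(b1$estimate, total, tolerance = 0.15 * abs(total))

  # independent mediator: CI covers zero
  d0 <- data.frame(y = rnorm(n), f_roh = f, med = rnorm(n))
  b0 <- indirect_effect_bootstrap(d0, "y", "f_roh", "med", n_boot = 1000, seed = 4)
  expect_false(b0$significant)

  expect_error(
    indirect_effect_bootstrap(d, "y", "f_roh", "med", n_boot = 10),
    "at least 1000", class = "autozyg_config_error"
  )
})
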