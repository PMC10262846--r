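test_that("Wald ratio arithmetic and delta-method SEs", {
  p <- harmonized_set("v1", 0.5, 0.05, 0.25, 0.05)
  r <- wald_ratio(p)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(r$or, exp(0.5))
  expect_equal(r$ci_low, 0.5 - qnorm(0.975) * 0.1)

  p0 <- harmonized_set("v1", 0.5, 0.05, 0, 0.05)
  expect_equal(wald_ratio(p0)$beta, 0)
  expect_equal(wald_ratio(p0)$or, 1)
  expect_error(wald_ratio(harmonized_set("v1", 0, 0.05, 0.1, 0.05)), "zero")

  # both delta orders match independent numeric differentiation
  p2 <- harmonized_set("v1", 0.5, 0.2, 0.25, 0.05)
  expect_equal(wald_ratio(p2)$se,
               bf_numeric_delta_se(0.5, 0.2, 0.25, 0.05), tolerance = 1e-8)
  expect_equal(wald_ratio(p2, second_order = TRUE)$se,
               bf_numeric_delta_se(0.5, 0.2, 0.25, 0.05,
                                   second_order = TRUE), tolerance = 1e-8)
})

test_that("IVW reduces to the equal-weight mean and the single-pair Wald ratio", {
  h <- harmonized_set(paste0("v", 1:3), rep(1, 3), rep(0.01, 3),
                      c(0.4, 0.5, 0.6), rep(0.1, 3))
  r <- mr_ivw(h)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1 / sqrt(3), tolerance = 1e-12)

  h1 <- make_hset(5, seed = 4)
  one <- h1[3, , drop = FALSE]
  expect_equal(mr_ivw(rbind(one, one))$beta, wald_ratio(one)$beta)
  # exact identity on a single pair via the WLS formula
  wr <- wald_ratio(one)
  expect_equal(bf_ivw(one$beta_exp, one$beta_out, one$se_out)$beta, wr$beta)
  expect_equal(bf_ivw(one$beta_exp, one$beta_out, one$se_out)$se, wr$se)
})

test_that("IVW equals the closed-form WLS-through-origin oracle", {
  for (seed in 1:10) {
    h <- make_hset(sample(3:20, 1), seed = seed,
                   se_out = runif(1, 0.005, 0.05))
    o <- bf_ivw(h$beta_exp, h$beta_out, h$se_out)
    r <- mr_ivw(h)
    expect_equal(r$beta, o$beta, tolerance = 1e-10)
    expect_equal(r$se, o$se, tolerance = 1e-10)
  }
})

test_that("IVW multiplicative-random-effects SE never shrinks below fixed", {
  h <- make_hset(20, seed = 8)
  expect_gte(mr_ivw(h, "mre")$se, mr_ivw(h, "fixed")$se)
  # with Q below df the MRE floor keeps the fixed SE exactly
  hq <- harmonized_set(paste0("v", 1:3), rep(1, 3), rep(0.01, 3),
                       c(0.499, 0.5, 0.501), rep(0.1, 3))
  expect_equal(mr_ivw(hq, "mre")$se, mr_ivw(hq, "fixed")$se)
})

test_that("Egger recovers exact-line data and matches the normal equations", {
  h <- harmonized_set(paste0("v", 1:3), c(1, 2, 3), rep(0.01, 3),
                      c(0.3, 0.5, 0.7), rep(0.1, 3))
  eg <- mr_egger(h)
  expect_equal(eg$result$beta, 0.2, tolerance = 1e-10)
  expect_equal(eg$pleiotropy$intercept, 0.1, tolerance = 1e-10)
  expect_equal(cochran_q(h, "egger")$Q, 0, tolerance = 1e-10)

  h0 <- harmonized_set(paste0("v", 1:4), 1:4, rep(0.01, 4),
                       0.5 * (1:4), rep(0.1, 4))
  eg0 <- mr_egger(h0)
  expect_equal(eg0$result$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg0$pleiotropy$intercept, 0, tolerance = 1e-10)

  for (seed in 1:10) {
    set.seed(seed)
    h <- harmonized_set(paste0("v", 1:6), rnorm(6, 0.1, 0.05),
                        rep(0.01, 6), rnorm(6, 0.05, 0.05),
                        runif(6, 0.01, 0.1))
    o <- bf_egger(h$beta_exp, h$beta_out, h$se_out)
    eg <- mr_egger(h)
    expect_equal(eg$result$beta, o$slope, tolerance = 1e-8)
    expect_equal(eg$result$se, o$slope_se, tolerance = 1e-8)
    expect_equal(eg$pleiotropy$intercept, o$intercept, tolerance = 1e-8)
    expect_equal(eg$pleiotropy$se, o$int_se, tolerance = 1e-8)
  }
  expect_error(mr_egger(harmonized_set(paste0("v", 1:3), rep(0.1, 3),
                                       rep(0.01, 3), rnorm(3),
                                       rep(0.1, 3))), "degenerate")
})

test_that("weighted median follows the interpolation rule", {
  h <- harmonized_set(paste0("v", 1:3), rep(1, 3), rep(0.01, 3),
                      c(0.1, 0.5, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.5)

  # dominance: nearly all weight on one variant
  hd <- harmonized_set(paste0("v", 1:3), c(1, 1, 10), rep(0.01, 3),
                       c(0.1, 0.5, 9), c(0.1, 0.1, 0.05))
  expect_equal(mr_weighted_median(hd, n_boot = 0)$beta, 0.9,
               tolerance = 0.05)

  for (seed in 1:10) {
    set.seed(seed)
    h <- harmonized_set(paste0("v", 1:4), runif(4, 0.5, 2), rep(0.01, 4),
                        rnorm(4), runif(4, 0.05, 0.2))
    expect_equal(mr_weighted_median(h, n_boot = 0)$beta,
                 bf_weighted_median(h$beta_out / h$beta_exp,
                                    h$beta_exp^2 / h$se_out^2),
                 tolerance = 1e-10)
  }
  expect_error(mr_weighted_median(h, n_boot = 100), "seed")
})

test_that("weighted median stays inside the ratio range", {
  for (seed in 1:20) {
    set.seed(seed)
    J <- sample(3:15, 1)
    h <- harmonized_set(paste0("v", 1:J), runif(J, 0.2, 2), rep(0.01, J),
                        rnorm(J), runif(J, 0.02, 0.2))
    ratio <- h$beta_out / h$beta_exp
    b <- mr_weighted_median(h, n_boot = 0)$beta
    expect_gte(b, min(ratio)); expect_lte(b, max(ratio))
  }
})

test_that("mode estimators find the dominant cluster and match the KDE oracle", {
  h <- harmonized_set(paste0("v", 1:4), rep(1, 4), rep(0.01, 4),
                      c(0.49, 0.50, 0.51, 1.5), rep(0.1, 4))
  sm <- mr_mode(h, weighted = FALSE, n_boot = 0)$beta
  expect_gte(sm, 0.49); expect_lte(sm, 0.51)
  expect_equal(sm, bf_mode(h$beta_out, rep(1, 4), weighted = FALSE),
               tolerance = 1e-10)

  # all ratios equal: the common ratio, no error
  he <- harmonized_set(paste0("v", 1:3), rep(1, 3), rep(0.01, 3),
                       rep(0.7, 3), rep(0.1, 3))
  expect_equal(mr_mode(he, n_boot = 0)$beta, 0.7)

  # weighted dominance pulls the mode to the heavy variant
  hw <- harmonized_set(paste0("v", 1:4), c(1, 1, 1, 20), rep(0.01, 4),
                       c(0.49, 0.50, 0.51, 30), c(0.1, 0.1, 0.1, 0.05))
  expect_equal(mr_mode(hw, weighted = TRUE, n_boot = 0)$beta, 1.5,
               tolerance = 0.1)

  for (seed in 1:8) {
    set.seed(seed)
    J <- sample(4:15, 1)
    h <- harmonized_set(paste0("v", 1:J), runif(J, 0.5, 2), rep(0.01, J),
                        rnorm(J, 0.5, 0.3), runif(J, 0.05, 0.2))
    w <- h$beta_exp^2 / h$se_out^2
    ratio <- h$beta_out / h$beta_exp
    expect_equal(mr_mode(h, weighted = TRUE, n_boot = 0)$beta,
                 bf_mode(ratio, w, weighted = TRUE), tolerance = 1e-10)
    expect_equal(mr_mode(h, weighted = FALSE, n_boot = 0)$beta,
                 bf_mode(ratio, w, weighted = FALSE), tolerance = 1e-10)
  }
})

test_that("estimators are invariant to pair order and joint sign flips", {
  h <- make_hset(12, seed = 21)
  perm <- h[sample.int(12), , drop = FALSE]
  flip <- h
  flip$beta_exp[1:4] <- -flip$beta_exp[1:4]
  flip$beta_out[1:4] <- -flip$beta_out[1:4]
  for (variant in list(perm, flip)) {
    expect_equal(mr_ivw(variant)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(variant)$result$beta, mr_egger(h)$result$beta,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_median(variant, n_boot = 0)$beta,
                 mr_weighted_median(h, n_boot = 0)$beta, tolerance = 1e-12)
    expect_equal(mr_mode(variant, n_boot = 0)$beta,
                 mr_mode(h, n_boot = 0)$beta, tolerance = 1e-12)
  }
})

test_that("the five-method suite sets consistency and significance flags", {
  sim <- simulate_pair(sim_config(n_variants = 30, n_instruments = 30,
                                  theta = 0.7, seed = 31))
  h <- harmonize(sim$exposure, sim$outcome)
  fit <- mr_fit(h, seed = 31, n_boot = 100)
  core <- fit$results[fit$results$method %in%
                        c("ivw_fixed", "egger", "weighted_median",
                          "simple_mode", "weighted_mode"), ]
  expect_equal(nrow(core), 5)
  expect_true(all(core$beta > 0))
  expect_true(fit$consistent)
  expect_true(fit$significant)
  expect_true(all(core$n_snp == nrow(h)))

  # minimal 3-pair set still returns the full suite
  h3 <- make_hset(3, seed = 5)
  fit3 <- mr_fit(h3, seed = 5, n_boot = 50)
  expect_equal(sum(fit3$results$method %in%
                     c("ivw_fixed", "egger", "weighted_median",
                       "simple_mode", "weighted_mode")), 5)

  # null scenario: significance flag rarely set
  hits <- 0L
  for (s in 1:40) {
    hn <- make_hset(20, theta = 0, seed = 1000 + s)
    f <- mr_fit(hn, seed = s, n_boot = 0)
    # with n_boot = 0 the median/mode SEs are NA: judge on IVW + Egger
    ps <- f$results$pval[f$results$method %in% c("ivw_fixed", "egger")]
    if (f$consistent && all(ps < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits / 40, 0.10)
})

test_that("coef, confint, residuals and print methods expose the fit", {
  h <- make_hset(10, seed = 6)
  fit <- mr_fit(h, seed = 6, n_boot = 50)
  expect_named(coef(fit), fit$results$method)
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), fit$results$ci_low)
  expect_equal(length(residuals(fit)), 10)
  expect_output(print(fit), "ivw_fixed")
  expect_output(print(summary(fit)), "Egger intercept")
})
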