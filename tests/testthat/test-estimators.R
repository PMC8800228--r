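test_that("Wald ratios follow the ratio formula and its variance", {
  p <- as_harmonized_panel(data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    beta_x = c(0.02, 0.05, 0.03), se_x = rep(0.003, 3),
    beta_y = c(0.01, 0, -0.03), se_y = c(0.004, 0.01, 0.006)))
  w <- wald_ratio(p)
  expect_equal(w$theta, c(0.5, 0, -1))
  expect_equal(w$variance, c(0.04, 0.04, 0.04))
  p$variants$beta_x[1] <- 0
  expect_error(wald_ratio(p), "undefined ratio")
})

test_that("IVW reproduces hand-computed combinations", {
  one <- data.frame(theta = 0.7, variance = 0.09)
  est <- ivw(one)
  expect_equal(est$beta, 0.7)
  expect_equal(est$se, 0.3)

  two <- data.frame(theta = c(0.5, 1.0), variance = c(0.04, 0.04))
  est <- ivw(two, model = "fixed")
  expect_equal(est$beta, 0.75)
  expect_equal(est$se, sqrt(1 / 50), tolerance = 1e-6)
  expect_equal(est$or, exp(0.75))
  expect_true(est$ci_low < est$beta && est$beta < est$ci_high)
})

test_that("IVW point estimate is model-invariant; SEs differ as specified", {
  w <- wald_ratio(random_panel(12, theta = 0.3, seed = 4))
  fixed <- ivw(w, "fixed")
  mre <- ivw(w, "multiplicative_random")
  auto <- ivw(w, "auto")
  expect_equal(fixed$beta, mre$beta)
  expect_equal(auto$beta, mre$beta)
  expect_equal(auto$se, mre$se)   # J >= 4 -> random-effects
  q <- sum((w$theta - fixed$beta)^2 / w$variance)
  expect_equal(mre$se, fixed$se * max(1, sqrt(q / (nrow(w) - 1))))
  small <- ivw(w[1:3, ], "auto")
  expect_equal(small$se, ivw(w[1:3, ], "fixed")$se)
})

test_that("IVW of duplicated inputs keeps the point, scales fixed SE by 1/sqrt(2)", {
  w <- wald_ratio(random_panel(9, theta = -0.2, seed = 8))
  w2 <- rbind(w, w)
  expect_equal(ivw(w2, "fixed")$beta, ivw(w, "fixed")$beta)
  expect_equal(ivw(w2, "fixed")$se, ivw(w, "fixed")$se / sqrt(2))
})

test_that("estimators are invariant to variant order", {
  panel <- random_panel(15, theta = 0.4, seed = 21)
  w <- wald_ratio(panel)
  perm <- sample(nrow(w))
  panel_p <- panel
  panel_p$variants <- panel$variants[perm, ]
  expect_equal(ivw(w[perm, ])$beta, ivw(w)$beta)
  expect_equal(weighted_median(w[perm, ], 500, seed = 2)$beta,
               weighted_median(w, 500, seed = 2)$beta)
  eg1 <- mr_egger(panel)
  eg2 <- mr_egger(panel_p)
  expect_equal(eg2$beta, eg1$beta)
  expect_equal(eg2$egger_intercept, eg1$egger_intercept)
})

test_that("weighted median handles symmetric, outlying and tiny panels", {
  eq <- data.frame(theta = c(1, 2, 3), variance = rep(1, 3))
  expect_equal(weighted_median(eq, 200, seed = 1)$beta, 2)
  out <- data.frame(theta = c(1, 2, 100), variance = rep(1, 3))
  expect_equal(weighted_median(out, 200, seed = 1)$beta, 2)
  expect_error(weighted_median(eq[1:2, ], 200, seed = 1), ">= 3")
  expect_error(weighted_median(eq, 200), "seed")
})

test_that("weighted median matches the interpolation oracle on small panels", {
  # all panel sizes up to 6 over a grid of weights and a random 7-variant
  # panel: agreement with the independent approx()-based oracle to 1e-12
  for (J in 3:6) {
    for (wseed in 1:8) {
      set.seed(100 * J + wseed)
      theta <- rnorm(J)
      w <- runif(J, 0.1, 5)
      est <- weighted_median(data.frame(theta = theta, variance = 1 / w),
                             n_boot = 100, seed = 1)
      expect_equal(est$beta, bf_weighted_median(theta, w),
                   tolerance = 1e-12)
    }
  }
  set.seed(77)
  theta <- rnorm(7)
  w <- runif(7, 0.2, 3)
  expect_equal(weighted_median(data.frame(theta = theta, variance = 1 / w),
                               100, seed = 1)$beta,
               bf_weighted_median(theta, w), tolerance = 1e-12)
})

test_that("weighted median bootstrap SE is seed-reproducible and sane", {
  w <- wald_ratio(random_panel(30, theta = 0.2, seed = 12))
  a <- weighted_median(w, n_boot = 2000, seed = 99)
  b <- weighted_median(w, n_boot = 2000, seed = 99)
  expect_identical(a$se, b$se)
  # bootstrap SE should be commensurate with the IVW scale
  expect_gt(a$se, 0)
  expect_lt(a$se, 10 * ivw(w)$se)
})

test_that("MR-Egger recovers exact lines and affine relations", {
  bx <- c(0.01, 0.02, 0.03, 0.05)
  se_y <- c(0.01, 0.02, 0.015, 0.01)
  p1 <- as_harmonized_panel(data.frame(
    rsid = paste0("rs", 1:4), beta_x = bx, se_x = 0.003,
    beta_y = 0.7 * bx, se_y = se_y))
  e1 <- mr_egger(p1)
  expect_equal(e1$beta, 0.7, tolerance = 1e-10)
  expect_equal(e1$egger_intercept, 0, tolerance = 1e-10)

  p2 <- as_harmonized_panel(data.frame(
    rsid = paste0("rs", 1:4), beta_x = bx, se_x = 0.003,
    beta_y = 0.01 + 0.5 * bx, se_y = se_y))
  e2 <- mr_egger(p2)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$egger_intercept, 0.01, tolerance = 1e-10)
})

test_that("MR-Egger agrees with the transformed unweighted LS oracle", {
  for (seed in 1:6) {
    panel <- random_panel(10 + seed, theta = 0.3, seed = seed,
                          pleio = rnorm(10 + seed, 0.01, 0.005))
    est <- mr_egger(panel)
    v <- panel$variants
    o <- bf_egger(v$beta_x, v$beta_y, v$se_y)
    expect_equal(est$beta, o$slope, tolerance = 1e-10)
    expect_equal(est$egger_intercept, o$intercept, tolerance = 1e-10)
    expect_equal(est$se, o$slope_se, tolerance = 1e-8)
    expect_equal(est$egger_intercept_se, o$intercept_se, tolerance = 1e-8)
  }
  expect_error(mr_egger(random_panel(2, seed = 1)), ">= 3")
  flat <- as_harmonized_panel(data.frame(
    rsid = paste0("rs", 1:4), beta_x = 0.02, se_x = 0.003,
    beta_y = c(0.01, 0.02, 0, 0.01), se_y = 0.01))
  expect_error(mr_egger(flat), "singular")
})

test_that("odds-ratio conversion matches closed-form exponentiation", {
  z <- to_odds_ratio(0, 1)
  expect_equal(unname(z["or"]), 1)
  expect_equal(unname(z["or_low"] * z["or_high"]), 1, tolerance = 1e-12)

  a <- to_odds_ratio(-0.342, 0.086)
  expect_equal(unname(a["or"]), 0.71034, tolerance = 1e-4)
  expect_equal(unname(a["or_low"]), 0.60019, tolerance = 1e-4)
  expect_equal(unname(a["or_high"]), 0.84076, tolerance = 1e-4)

  b <- to_odds_ratio(0.610, 0.0746)
  expect_equal(unname(b["or"]), 1.8404, tolerance = 1e-4)
  expect_error(to_odds_ratio(0.1, 0))
})

test_that("mr_fit bundles methods with standard accessors", {
  panel <- random_panel(20, theta = -0.3, seed = 31)
  fit <- mr_fit(panel, seed = 7, n_boot = 300, n_sim = 300)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("ivw", "weighted_median", "mr_egger",
                            "mr_presso"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  s <- summary(fit)
  expect_equal(nrow(s$table), 4L)
  expect_equal(s$table$or, exp(s$table$beta))
  r <- residuals(fit)
  expect_length(r, 20L)
  expect_output(print(fit), "IVW")
})
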