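mcmc_small <- list(chains = 2, iter = 400, warmup = 400, adapt = 200)

test_that("fitting validates its inputs", {
  df <- data.frame(participant = "a", segment_index = 1:10, bias = rnorm(10))
  expect_error(fit_bias_model(df[0, ], "linear"), "no observations")
  expect_error(fit_bias_model(df, "linear"), "2 participants")
  df2 <- expand.grid(participant = c("a", "b"), segment_index = 1:10)
  df2$bias <- rnorm(20)
  expect_error(fit_bias_model(transform(df2, bias = c(NA, bias[-1])), "linear"),
               "finite")
  expect_error(fit_bias_model(df2, "dual_identical"), "condition")
  expect_error(fit_bias_model(df2, "additive", basis = spline_basis(8)),
               "mismatch")
  expect_error(fit_bias_model(df2, "quadratic"))
  df2$condition <- "perception"
  expect_error(fit_bias_model(df2, "dual_identical"), "both levels")
})

test_that("symmetric null data yield near-zero population effects", {
  set.seed(71)
  df <- expand.grid(participant = c("a", "b", "c"), segment_index = 1:10,
                    rep = 1:100)
  df$bias <- rnorm(nrow(df), 0, 0.2)
  fl <- suppressWarnings(
    do.call(fit_bias_model, c(list(df, "linear", seed = 1), mcmc_small))
  )
  co <- coef(fl)
  expect_lt(abs(co[["alpha"]]), 0.05)
  expect_lt(abs(co[["beta"]]), 0.05)

  fa <- suppressWarnings(
    do.call(fit_bias_model, c(list(df, "additive", seed = 2), mcmc_small))
  )
  curve_means <- fa$summary$mean[grep("^curve\\[", fa$summary$parameter)]
  expect_true(all(abs(curve_means) < 0.05))
})

test_that("the linear model recovers generating parameters at default settings", {
  set.seed(5)
  np <- 8
  a <- rnorm(np, 0.5, 0.1)
  b <- rnorm(np, -0.1, 0.05)
  df <- expand.grid(participant = sprintf("p%02d", 1:np),
                    segment_index = 1:10, rep = 1:50)
  pid <- as.integer(factor(df$participant))
  df$bias <- a[pid] + b[pid] * (df$segment_index - 1) + rnorm(nrow(df), 0, 0.2)

  fit <- fit_bias_model(df, "linear", seed = 9) # default 4 chains, 1000+1000
  s <- summary(fit)
  arow <- s[s$parameter == "alpha", ]
  brow <- s[s$parameter == "beta", ]
  expect_true(arow$ci_lo < 0.5 && 0.5 < arow$ci_hi)
  expect_true(brow$ci_lo < -0.1 && -0.1 < brow$ci_hi)
  # converged at default settings
  expect_true(all(s$rhat[is.finite(s$rhat)] <= 1.01))
  # HPDI never wider than the percentile interval on the same draws
  expect_true(all(s$hpdi_hi - s$hpdi_lo <= s$ci_hi - s$ci_lo + 1e-12))
  expect_true(all(is.finite(fit$draws)))
})

test_that("the additive model recovers a known curve and the scaling order", {
  set.seed(6)
  b <- spline_basis(10)
  w_true <- c(-0.05, -0.35, -0.1, 0.02, 0, 0)
  curve <- synthesize_curve(b, w_true)
  scales <- c(0.5, 1.0, 2.0)
  df <- expand.grid(participant = sprintf("p%d", 1:3), segment_index = 1:10,
                    rep = 1:60)
  pid <- as.integer(factor(df$participant))
  df$bias <- curve[df$segment_index] * scales[pid] + rnorm(nrow(df), 0, 0.3)

  fit <- suppressWarnings(fit_bias_model(df, "additive", basis = b, seed = 3))
  s <- summary(fit)
  post_curve <- s$mean[grep("^curve\\[", s$parameter)]
  expect_gte(cor(post_curve, curve), 0.95)
  wp <- s$mean[grep("^w_p\\[", s$parameter)]
  expect_equal(order(wp), order(scales))
  # participant scaling weights are strictly positive in every draw
  wp_draws <- fit$draws[, grep("^w_p\\[", colnames(fit$draws))]
  expect_true(all(wp_draws > 0))
})

test_that("fits are reproducible under a fixed seed and expose methods", {
  set.seed(81)
  df <- expand.grid(participant = c("a", "b"), segment_index = 1:10, rep = 1:15)
  df$bias <- -0.1 * (df$segment_index <= 3) + rnorm(nrow(df), 0, 0.4)
  f1 <- suppressWarnings(
    do.call(fit_bias_model, c(list(df, "additive", seed = 4), mcmc_small))
  )
  f2 <- suppressWarnings(
    do.call(fit_bias_model, c(list(df, "additive", seed = 4), mcmc_small))
  )
  expect_identical(f1$draws, f2$draws)

  expect_output(print(f1), "rc_fit 'additive'")
  expect_length(fitted(f1), nrow(df))
  expect_equal(residuals(f1), df$bias - fitted(f1))
  pr <- predict(f1)
  expect_equal(nrow(pr), 2 * 10)
  expect_true(all(pr$lo <= pr$estimate & pr$estimate <= pr$hi))
  pop <- predict(f1, level = "population")
  expect_equal(unique(pop$participant), "population")
  sims <- simulate(f1, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(df), 2L))
  expect_error(scaling_weight_contrast(f1), "dual-condition")
})

test_that("slow-mixing fits raise a convergence warning", {
  # widely spread participant scales put the additive sampler on its
  # multiplicative ridge; short chains cannot reach split-Rhat <= 1.01
  set.seed(3)
  b <- spline_basis(10)
  curve <- synthesize_curve(b, c(-0.05, -0.35, -0.1, 0.02, 0, 0))
  df <- expand.grid(participant = c("a", "b", "c"), segment_index = 1:10,
                    rep = 1:60)
  pid <- as.integer(factor(df$participant))
  df$bias <- curve[df$segment_index] * c(0.5, 1, 2)[pid] +
    rnorm(nrow(df), 0, 0.3)
  expect_warning(
    fit_bias_model(df, "additive", basis = b, chains = 2, iter = 150,
                   warmup = 100, adapt = 100, seed = 1),
    "split-Rhat above 1.01"
  )
})

test_that("the additive model beats the linear model on bell-shaped data", {
  set.seed(77)
  x <- 1:10
  bell <- -0.35 * exp(-(x - 5.5)^2 / 12.5)
  df <- expand.grid(participant = c("a", "b", "c"), segment_index = x,
                    rep = 1:80)
  df$bias <- bell[df$segment_index] + rnorm(nrow(df), 0, 0.5)
  fl <- suppressWarnings(
    do.call(fit_bias_model, c(list(df, "linear", seed = 7), mcmc_small))
  )
  fa <- suppressWarnings(
    do.call(fit_bias_model, c(list(df, "additive", seed = 8), mcmc_small))
  )
  cmp <- compare_models(linear = fl, additive = fa)
  expect_equal(cmp$model[1], "additive")
  lin <- cmp[cmp$model == "linear", ]
  expect_lt(lin$delta_elpd, -2 * lin$delta_se)
})

test_that("dual fits carry per-condition parameters and weight contrasts", {
  set.seed(91)
  b <- spline_basis(10)
  curve <- synthesize_curve(b, c(-0.05, -0.3, -0.1, 0, 0, 0))
  df <- expand.grid(participant = c("a", "b"), segment_index = 1:10,
                    rep = 1:120, condition = c("perception", "memory"))
  sc <- ifelse(df$condition == "perception", 1, 0.45)
  df$bias <- curve[df$segment_index] * sc + rnorm(nrow(df), 0, 0.5)

  fit <- suppressWarnings(
    do.call(fit_bias_model,
            c(list(df, "dual_identical", basis = b, seed = 5), mcmc_small))
  )
  frac <- scaling_weight_contrast(fit)
  expect_named(frac, c("a", "b"))
  expect_true(all(frac > 0.9))
  # per-condition residual scales and scaling weights are present
  expect_true(all(c("sigma[1]", "sigma[2]", "w_p[1,1]", "w_p[1,2]") %in%
                    colnames(fit$draws)))

  fc <- suppressWarnings(
    do.call(fit_bias_model,
            c(list(df, "dual_correlated", basis = b, seed = 6), mcmc_small))
  )
  expect_true("rho" %in% colnames(fc$draws))
  expect_true(all(abs(fc$draws[, "rho"]) < 1))
})
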