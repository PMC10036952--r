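test_that("drive pools evidence linearly through the kernel", {
  kappa <- default_kernel(10)
  expect_equal(drive(rep(0, 10), kappa), 0)
  expect_equal(drive(c(1, rep(0, 9)), c(1, rep(0, 9))), 1)
  # selector kernel picks out one segment
  e3 <- replace(rep(0, 10), 3, 1)
  s <- seq(-1, 0.8, by = 0.2)
  expect_equal(drive(s, e3), s[3])

  # brute-force elementwise oracle
  set.seed(4)
  for (i in 1:25) {
    kk <- rnorm(10)
    ss <- sample(seq(-1, 1, 0.1), 10, replace = TRUE)
    acc <- 0
    for (j in 1:10) acc <- acc + kk[j] * ss[j]
    expect_equal(drive(ss, kk), acc)
  }
  expect_error(drive(rep(0, 9), kappa), "same length")
})

test_that("response probabilities are lapse-mixed logistics, monotone in drive", {
  p0 <- observer_params(lapse = 0, gain_perception = 1, gain_memory = 0.5,
                        baseline_perception = 1.5, baseline_memory = 0.8)
  pr <- response_probabilities(0, p0)
  expect_equal(pr$p_prime_same, plogis(1.5))
  expect_equal(pr$p_probe_next_same, plogis(0.8))

  # logistic limits: both probabilities vanish for strongly negative drive
  lo <- response_probabilities(-50, p0)
  expect_lt(lo$p_prime_same, 1e-10)
  expect_lt(lo$p_probe_next_same, 1e-10)

  # lapse floors/ceilings the probabilities at lambda/2 and 1 - lambda/2
  pl <- observer_params(lapse = 0.1)
  expect_equal(response_probabilities(-50, pl)$p_prime_same, 0.05)
  expect_equal(response_probabilities(50, pl)$p_prime_same, 0.95)

  # finite-difference monotonicity over a grid of drives
  d <- seq(-6, 6, by = 0.25)
  pr <- response_probabilities(d, observer_params(lapse = 0.07))
  expect_true(all(diff(pr$p_prime_same) >= 0))
  expect_true(all(diff(pr$p_probe_next_same) >= 0))
})

test_that("observer parameter validation enforces ranges", {
  expect_error(observer_params(lapse = 0.3), "lapse")
  expect_error(observer_params(p_miss = -0.01), "p_miss")
  expect_error(observer_params(gain_perception = -1))
  expect_error(observer_params(kernel = c(1, NA)), "finite")
})

test_that("the default kernel peaks at segment 2 and is zero after segment 5", {
  kappa <- default_kernel(10)
  expect_length(kappa, 10)
  expect_equal(which.max(kappa), 2L)
  expect_equal(kappa[2], 0.6)
  expect_true(all(kappa[6:10] == 0))
  expect_true(all(kappa[1:5] > 0))
  expect_equal(default_kernel(20)[11:20], rep(0, 10))
})

test_that("a miss-free session alternates strictly and ends on a probe", {
  set.seed(21)
  sch <- kde_schedule("onset_only")
  sess <- simulate_session(observer_params(p_miss = 0), sch, n_primes = 100)
  expect_equal(sum(sess$trial_type == "prime"), 100)
  expect_equal(sum(sess$trial_type == "probe"), 101)
  expect_equal(sess$trial_type, rep(c("probe", "prime"), length.out = 201))
  expect_true(all(sess$report != "missing"))
  # probes carry no sequence; primes carry a full on-grid sequence
  seg <- as.matrix(sess[, sprintf("seg_%02d", 1:10)])
  expect_true(all(is.na(seg[sess$trial_type == "probe", ])))
  expect_true(all(seg[sess$trial_type == "prime", ] %in% -10:10))
})

test_that("sessions are reproducible under a fixed seed", {
  sch <- kde_schedule("onset_only")
  set.seed(33)
  s1 <- simulate_session(observer_params(), sch, n_primes = 50)
  set.seed(33)
  s2 <- simulate_session(observer_params(), sch, n_primes = 50)
  expect_identical(s1, s2)
})

test_that("zero gain and high baseline yield near-total persistence", {
  set.seed(5)
  sch <- kde_schedule("onset_only")
  pars <- observer_params(gain_perception = 0, gain_memory = 0,
                          baseline_perception = 4, baseline_memory = 4,
                          lapse = 0, p_miss = 0)
  sess <- simulate_session(pars, sch, n_primes = 2000)
  tr <- build_triplets(sess)
  prime_chg <- mean(tr$report_prime != tr$report_lead)
  mem_chg <- mean(tr$report_trail != tr$report_lead)
  # plogis(4) ~ 0.982 persistence
  expect_lt(prime_chg, 0.05)
  expect_lt(mem_chg, 0.05)
})

test_that("no prime ever follows a missing report", {
  set.seed(55)
  sch <- kde_schedule("full")
  sess <- simulate_session(observer_params(p_miss = 0.15), sch, n_primes = 300)
  expect_equal(sum(sess$trial_type == "prime"), 300)
  expect_equal(sess$trial_type[1], "probe")
  prev_missing <- c(FALSE, sess$report[-nrow(sess)] == "missing")
  expect_true(all(sess$trial_type[prev_missing] == "probe"))
  # and there are misses to make the scan meaningful
  expect_gt(sum(sess$report == "missing"), 0)
})
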