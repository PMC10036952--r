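test_that("outcome classification matches the 2x2 definition on all 8 patterns", {
  # independent enumeration: prime changed iff prime != leading, memory
  # changed iff trailing != leading
  dirs <- c("left", "right")
  for (l in dirs) for (p in dirs) for (t in dirs) {
    expected <- if (p != l && t != l) {
      "both_changed"
    } else if (p != l) {
      "prime_only"
    } else if (t != l) {
      "memory_only"
    } else {
      "no_change"
    }
    expect_equal(as.character(classify_outcome(l, p, t)), expected)
  }
  # the printed examples
  expect_equal(as.character(classify_outcome("left", "right", "right")), "both_changed")
  expect_equal(as.character(classify_outcome("left", "right", "left")), "prime_only")
  expect_equal(as.character(classify_outcome("left", "left", "right")), "memory_only")
  expect_equal(as.character(classify_outcome("left", "left", "left")), "no_change")
  expect_error(classify_outcome("left", "missing", "left"), "left.*right")
})

test_that("sign alignment follows the previous-probe convention and is an involution", {
  expect_equal(align_sign(0.5, "right"), 0.5)
  expect_equal(align_sign(0.5, "left"), -0.5)
  expect_equal(align_sign(0, "left"), 0)
  expect_equal(align_sign(0, "right"), 0)

  set.seed(9)
  x <- sample(seq(-1, 1, 0.1), 10, replace = TRUE)
  for (r in c("left", "right")) {
    expect_equal(align_sign(align_sign(x, r), r), x)
  }
  m <- unname(rbind(x, -x))
  expect_equal(align_sign(m, c("left", "right")), unname(rbind(-x, -x)))
  expect_error(align_sign(x, "missing"), "left.*or.*right")
  expect_error(align_sign(x, NA_character_))
})

test_that("triplet construction yields one triplet per fully-reported prime", {
  set.seed(13)
  sess <- simulate_session(observer_params(p_miss = 0), kde_schedule("onset_only"), 100)
  tr <- build_triplets(sess)
  expect_s3_class(tr, "kde_triplets")
  expect_equal(nrow(tr), 100)
  # aligned sequences: negated iff leading probe reported left
  i <- which(tr$report_lead == "left")[1]
  row <- sess[sess$trial_index == tr$prime_trial_index[i], sprintf("seg_%02d", 1:10)]
  expect_equal(unlist(tr[i, sprintf("seg_%02d", 1:10)], use.names = FALSE),
               -unlist(row, use.names = FALSE) / 10)
})

test_that("missing reports invalidate exactly the affected triplets", {
  sch <- kde_schedule("full", n_segments = 2)
  # probe prime probe prime probe ; second prime's report missing
  sess <- make_session(
    trial_type = c("probe", "prime", "probe", "prime", "probe"),
    report = c("right", "left", "right", "missing", "left"),
    schedule = sch
  )
  tr <- build_triplets(sess)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$prime_trial_index, 2L)

  # a missing middle probe removes the triplets on both sides of it
  sess2 <- make_session(
    trial_type = rep(c("probe", "prime"), length.out = 7),
    report = c("right", "left", "missing", "right", "right", "left", "left"),
    schedule = sch
  )
  tr2 <- build_triplets(sess2)
  expect_equal(tr2$prime_trial_index, 6L)

  # probes only -> empty result
  sess3 <- make_session(rep("probe", 4), rep("right", 4), schedule = sch)
  expect_equal(nrow(build_triplets(sess3)), 0)
})

test_that("sliding triplets reuse probes; disjoint triplets do not", {
  sch <- kde_schedule("full", n_segments = 2)
  sess <- make_session(
    trial_type = rep(c("probe", "prime"), length.out = 9),
    report = rep("right", 9),
    schedule = sch
  )
  expect_equal(nrow(build_triplets(sess, "sliding")), 4)
  expect_equal(build_triplets(sess, "disjoint")$prime_trial_index, c(2L, 6L))
})

test_that("average_sequence matches hand arithmetic and a brute-force oracle", {
  tr <- make_triplets(rbind(c(0.4, 0.1), c(-0.2, 0.3)))
  avg <- average_sequence(tr, "memory_changed")
  expect_equal(avg$mean, c(0.1, 0.2))
  expect_equal(avg$n_trials, c(2L, 2L))

  # empty selection is an explicit signal, not a silent zero
  empty <- average_sequence(tr, "prime_changed")
  expect_true(attr(empty, "empty"))
  expect_true(all(is.na(empty$mean)))
  expect_equal(empty$n_trials, c(0L, 0L))
  expect_output(print(empty), "no qualifying trials")

  # brute-force per-segment sum/count oracle on a random 50-triplet set
  set.seed(17)
  vals <- matrix(sample(seq(-1, 1, 0.1), 50 * 10, replace = TRUE), 50, 10)
  cls <- sample(c("both_changed", "prime_only", "memory_only", "no_change"),
                50, replace = TRUE)
  tr50 <- make_triplets(vals, outcome = cls)
  avg50 <- average_sequence(tr50, "prime_changed")
  sel <- cls %in% c("both_changed", "prime_only")
  oracle <- numeric(10)
  for (s in 1:10) {
    tot <- 0
    cnt <- 0
    for (i in which(sel)) {
      tot <- tot + vals[i, s]
      cnt <- cnt + 1
    }
    oracle[s] <- tot / cnt
  }
  expect_equal(avg50$mean, oracle)
  expect_equal(unique(avg50$n_trials), sum(sel))
})

test_that("individual bootstrap handles constant data, is seeded, errors when empty", {
  tr <- make_triplets(matrix(0.3, 20, 3))
  est <- bootstrap_individual(tr, "memory_changed", n_iterations = 200, seed = 1)
  expect_equal(est$ci_lo, rep(0.3, 3))
  expect_equal(est$ci_hi, rep(0.3, 3))
  expect_true(all(est$ci_lo <= est$mean & est$mean <= est$ci_hi))

  set.seed(99)
  vals <- matrix(rnorm(40 * 2), 40, 2)
  trv <- make_triplets(vals)
  e1 <- bootstrap_individual(trv, "memory_changed", n_iterations = 300, seed = 7)
  e2 <- bootstrap_individual(trv, "memory_changed", n_iterations = 300, seed = 7)
  expect_identical(e1, e2)
  expect_true(all(e1$ci_lo <= e1$mean & e1$mean <= e1$ci_hi))

  expect_error(bootstrap_individual(tr, "prime_changed"), "no qualifying")
})

test_that("group bootstrap averages participants without weighting by trial count", {
  sch <- kde_schedule("full", n_segments = 2)
  # degenerate constant participants: group mean exact, zero-width interval
  tr <- rbind(
    make_triplets(matrix(0.4, 30, 2), participant = "a", schedule = sch),
    make_triplets(matrix(-0.2, 10, 2), participant = "b", schedule = sch)
  )
  attr(tr, "schedule") <- sch
  class(tr) <- c("kde_triplets", "data.frame")
  g <- bootstrap_group(tr, "memory_changed", n_iterations = 200, seed = 3)
  expect_equal(g$mean, c(0.1, 0.1)) # (0.4 + -0.2) / 2, despite 30 vs 10 trials
  expect_equal(g$ci_lo, g$ci_hi)

  # heterogeneous participants: point estimate equals a two-pass oracle
  set.seed(31)
  vals_a <- matrix(rnorm(25 * 2, 0.2), 25, 2)
  vals_b <- matrix(rnorm(50 * 2, -0.1), 50, 2)
  trh <- rbind(
    make_triplets(vals_a, participant = "a", schedule = sch),
    make_triplets(vals_b, participant = "b", schedule = sch)
  )
  attr(trh, "schedule") <- sch
  class(trh) <- c("kde_triplets", "data.frame")
  gh <- bootstrap_group(trh, "memory_changed", n_iterations = 500, seed = 4)
  oracle <- (colMeans(vals_a) + colMeans(vals_b)) / 2
  expect_equal(gh$mean, unname(oracle))
  expect_true(all(gh$ci_lo <= gh$mean & gh$mean <= gh$ci_hi))

  solo <- make_triplets(matrix(0, 5, 2), schedule = sch)
  expect_error(bootstrap_group(solo, "memory_changed"), ">= 2 participants")
})

test_that("prime-changed and memory-changed selections pool the right classes", {
  vals <- matrix(0.1, 4, 2)
  tr <- make_triplets(vals, outcome = c("both_changed", "prime_only",
                                        "memory_only", "no_change"))
  expect_equal(unique(average_sequence(tr, "prime_changed")$n_trials), 2L)
  expect_equal(unique(average_sequence(tr, "memory_changed")$n_trials), 2L)
})
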