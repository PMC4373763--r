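test_that("welch_test matches the reference implementation on random cases", {
  set.seed(14)
  for (i in 1:20) {
    a <- stats::rnorm(sample(2:9, 1), 0, stats::runif(1, 0.5, 3))
    b <- stats::rnorm(sample(2:9, 1), stats::runif(1, -2, 2),
                      stats::runif(1, 0.5, 3))
    ours <- welch_test(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    # one-tailed p (alternative oriented by observed sign) is half of two
    expect_equal(welch_test(a, b, tails = "one")$p, ours$p / 2,
                 tolerance = 1e-12)
  }
})

test_that("welch_test edge conventions and errors", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1), tolerance = 1e-12)
  # shifted copy: large |t|, sign fixed by argument order
  shifted <- welch_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  expect_lt(shifted$t, 0)
  # zero variance, equal means -> p = 1 by convention
  expect_identical(welch_test(c(5, 5, 5), c(5, 5))$p, 1)
  # zero variance, unequal means -> p = 0
  expect_identical(welch_test(c(5, 5, 5), c(6, 6))$p, 0)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("adjust_fdr equals the brute-force BH definition and p.adjust", {
  expect_identical(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(rep(0.2, 8)), rep(0.2, 8))
  set.seed(3)
  for (i in 1:30) {
    p <- stats::runif(50)^sample(1:3, 1)
    adj <- adjust_fdr(p)
    expect_equal(adj, brute_force_bh(p), tolerance = 1e-14)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_fdr(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("fold_change follows the knockdown/control orientation", {
  expect_identical(fold_change(100, 50), 0.5)
  expect_identical(fold_change(10, 26), 2.6)
  expect_identical(fold_change(7, 7), 1)
  expect_error(fold_change(0, 1), "positive")
  expect_error(fold_change(1, -2), "positive")
})

test_that("select_differential applies the dual criterion spot by spot", {
  set.seed(42)
  n <- 30
  ctrl <- matrix(exp(stats::rnorm(n * 5, 10, 0.2)), n)
  kd <- matrix(exp(stats::rnorm(n * 5, 10, 0.2)), n)
  # spot 1: strong true effect; spot 2: exact permutation (fold exactly 1)
  kd[1, ] <- ctrl[1, ] * 3
  kd[2, ] <- ctrl[2, c(2, 3, 1, 5, 4)]
  t0 <- make_table(two_group_matrix(ctrl, kd), normalized = TRUE)
  prof <- constant_profile(t0, 1.4)
  de <- select_differential(t0, prof, alpha = 0.05)

  expect_true(de$selected[1])
  expect_identical(de$direction[1], "up")
  expect_false(de$selected[2])
  expect_equal(de$fold[2], 1, tolerance = 1e-14)
  # invariants
  expect_identical(de$selected, de$passes_fdr & de$passes_threshold)
  expect_true(all(de$p_fdr >= de$p_raw))
  expect_identical(de$direction, ifelse(de$fold > 1, "up", "down"))
  # conjunction is never less conservative than FDR alone
  expect_true(all(which(de$selected) %in% which(de$passes_fdr)))
})

test_that("select_differential rejects missing thresholds and excludes zero volumes", {
  set.seed(7)
  ctrl <- matrix(5 + stats::runif(48), 12)
  kd <- matrix(5 + stats::runif(48), 12)
  t0 <- make_table(two_group_matrix(ctrl, kd), normalized = TRUE)
  prof <- constant_profile(t0, 1.3)
  prof$data <- prof$data[-2, ] # drop spot_0002's threshold
  expect_error(select_differential(t0, prof), "spot_0002")

  kd[2, 1] <- 0
  t1 <- make_table(two_group_matrix(ctrl, kd), normalized = TRUE)
  prof1 <- constant_profile(t1, 1.3)
  expect_warning(de <- select_differential(t1, prof1), "spot_0002")
  expect_identical(nrow(de), 11L)
  expect_identical(attr(de, "excluded"), "spot_0002")
})

test_that("validation requires direction concordance and a one-tailed hit", {
  set.seed(31)
  n <- 12
  ctrl <- matrix(exp(stats::rnorm(n * 6, 10, 0.15)), n)
  kd <- ctrl * exp(stats::rnorm(n * 6, 0, 0.15))
  kd[1, ] <- ctrl[1, ] * 2.5    # true up-regulation
  kd[2, ] <- ctrl[2, ] * 2.5
  wt <- ctrl * exp(stats::rnorm(n * 6, 0, 0.05)) # reference tracks control
  wt[2, ] <- kd[2, ] * 3        # reference above knockdown: direction flips
  t0 <- make_table(two_group_matrix(ctrl, kd, wt), normalized = TRUE)
  prof <- constant_profile(t0, 1.3)
  de <- select_differential(t0, prof)
  expect_true(all(de$selected[1:2]))
  val <- validate_against_reference(de, t0)
  expect_true(val$validated[1])   # concordant with reference
  expect_false(val$validated[2])  # reversed against reference
  expect_true(all(!val$validated[!val$selected]))

  # empty selection -> nothing validated
  de_none <- de; de_none$selected <- FALSE
  expect_identical(sum(validate_against_reference(de_none, t0)$validated), 0L)

  # selected spot without reference data: warning, left unvalidated
  wt2 <- wt; wt2[1, ] <- 0
  t2 <- make_table(two_group_matrix(ctrl, kd, wt2), normalized = TRUE)
  de2 <- select_differential(t2, constant_profile(t2, 1.3))
  expect_warning(val2 <- validate_against_reference(de2, t2), "spot_0001")
  expect_false(val2$validated[1])
})

test_that("spot_power behaves like a power function", {
  # null-effect limit: power -> alpha (exact for the pooled formula)
  expect_equal(spot_power(0.3, 7, 1 + 1e-12, method = "pooled"), 0.05,
               tolerance = 1e-6)
  # the Welch test is slightly conservative at small n, so its exact size
  # sits just below alpha
  expect_lt(abs(spot_power(0.3, 7, 1 + 1e-12, method = "welch") - 0.05),
            5e-3)
  # monotone in n, fold; antitone in sd (both methods)
  for (m in c("welch", "pooled")) {
    p_n <- vapply(c(3, 5, 7, 9, 12), function(n)
      spot_power(0.35, n, 2, method = m), numeric(1))
    expect_true(all(diff(p_n) > 0))
    p_f <- vapply(c(1.2, 1.5, 2, 3), function(f)
      spot_power(0.35, 7, f, method = m), numeric(1))
    expect_true(all(diff(p_f) > 0))
    p_s <- spot_power(c(0.2, 0.35, 0.5, 0.8), 7, 2, method = m)
    expect_true(all(diff(p_s) < 0))
  }
  # fold and 1/fold give identical power
  expect_equal(spot_power(0.3, 7, 2), spot_power(0.3, 7, 0.5),
               tolerance = 1e-12)
  expect_error(spot_power(0.3, 1, 2), "n_per_group")
  expect_error(spot_power(-0.3, 7, 2), "positive")
})

test_that("sample_size_profile reports coverage fractions and recommendations", {
  s <- power_settings(folds = c(2, 1.5), n_grid = 2:12)
  # identical sds: the fraction is a 0/1 step in n
  prof <- sample_size_profile(rep(0.4, 50), s)
  expect_true(all(prof$table$fraction %in% c(0, 1)))
  for (f in c(2, 1.5)) {
    fr <- prof$table$fraction[prof$table$fold == f]
    expect_true(all(diff(fr) >= 0))
  }
  # mixed sds: monotone in n; at fixed n smaller fold covers fewer spots
  set.seed(2)
  sds <- stats::rlnorm(200, log(0.35), 0.3)
  prof2 <- sample_size_profile(sds, s, coverage_goal = 0.9)
  tab <- prof2$table
  for (f in c(2, 1.5)) {
    expect_true(all(diff(tab$fraction[tab$fold == f]) >= 0))
  }
  merged <- merge(tab[tab$fold == 2, ], tab[tab$fold == 1.5, ], by = "n")
  expect_true(all(merged$fraction.x >= merged$fraction.y))
  # recommended n is the smallest n meeting the coverage goal
  for (f in c("2", "1.5")) {
    sub <- tab[tab$fold == as.numeric(f), ]
    expected <- suppressWarnings(min(sub$n[sub$fraction >= 0.9]))
    expect_equal(unname(prof2$recommended[f]),
                 if (is.finite(expected)) as.numeric(expected) else NA_real_)
  }
  expect_error(sample_size_profile(numeric()), "empty")
})

test_that("welch p-values are uniform under the null (KS property)", {
  set.seed(1234)
  p <- vapply(1:10000, function(i) {
    welch_test(stats::rnorm(7), stats::rnorm(7))$p
  }, numeric(1L))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})
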