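test_that("Mann-Whitney exact path matches hand enumeration", {
  mw <- mann_whitney_two_sided(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_identical(mw$method, "exact")

  # identical multisets give p = 1 (ties force the approximate path)
  same <- mann_whitney_two_sided(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)

  expect_error(mann_whitney_two_sided(numeric(0), 1), "nonempty")
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free data", {
  withr::with_seed(21, {
    cases <- list()
    for (nx in 2:5) for (ny in 2:5) {
      if (nx + ny > 10) next
      x <- sample(1:100, nx)
      y <- sample(setdiff(1:100, x), ny)
      cases[[length(cases) + 1]] <- list(x = x, y = y)
    }
    for (cs in cases) {
      mine <- mann_whitney_two_sided(cs$x, cs$y)
      ref <- stats::wilcox.test(cs$x, cs$y, exact = TRUE)
      expect_equal(mine$U, unname(ref$statistic))
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("tied or large samples use the corrected normal approximation", {
  withr::with_seed(33, {
    x <- sample(1:5, 15, replace = TRUE)
    y <- sample(2:6, 18, replace = TRUE)
  })
  mine <- mann_whitney_two_sided(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_identical(mine$method, "normal_approximation")
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("U statistics of the two groups sum to nx * ny", {
  withr::with_seed(14, {
    for (rep in 1:10) {
      x <- rnorm(sample(3:8, 1))
      y <- rnorm(sample(3:8, 1))
      ux <- mann_whitney_two_sided(x, y)$U
      uy <- mann_whitney_two_sided(y, x)$U
      expect_equal(ux + uy, length(x) * length(y))
    }
  })
})

test_that("the p-value is invariant under strictly monotone transforms", {
  withr::with_seed(15, {
    x <- rexp(6); y <- rexp(7) + 0.3
  })
  p0 <- mann_whitney_two_sided(x, y)$p
  expect_equal(mann_whitney_two_sided(log(x), log(y))$p, p0)
  expect_equal(mann_whitney_two_sided(x^3, y^3)$p, p0)
})

test_that("Fisher exact p-values match the worked examples", {
  expect_equal(fisher_exact_two_sided(c(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(2, 0, 0, 2), 2,
                                             byrow = TRUE)),
               1 / 3, tolerance = 1e-12)
  p <- fisher_exact_two_sided(c(6, 0, 47, 142))
  expect_equal(p, 3.249188e-4, tolerance = 1e-6)
  expect_error(fisher_exact_two_sided(c(1, -1, 0, 0)), "nonnegative")
})

test_that("Fisher agrees with an independent enumeration for all n <= 10", {
  # independent oracle: enumerate margin-preserving tables, probabilities
  # from binomial coefficients (not dhyper)
  oracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    xs <- max(0, c1 - r2):min(r1, c1)
    pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
    stopifnot(abs(sum(pr) - 1) < 1e-12)
    pobs <- pr[xs == a]
    sum(pr[pr <= pobs * (1 + 1e-7)])
  }
  for (n in 1:10) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(fisher_exact_two_sided(c(a, b, c, d)),
                   min(1, oracle(a, b, c, d)), tolerance = 1e-12)
    }
  }
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  tabs <- list(c(3, 1, 2, 4), c(5, 0, 1, 4), c(2, 2, 2, 2), c(0, 3, 3, 0))
  for (t in tabs) {
    m <- matrix(t, 2, byrow = TRUE)
    p <- fisher_exact_two_sided(m)
    expect_equal(fisher_exact_two_sided(t(m)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(m[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(m[, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("group summaries use the mean and interpolated quartiles", {
  ages <- c(46, 49, 49, 46, 49, 51)
  s <- summarize_group(ages)
  expect_equal(s$mean, 48.33, tolerance = 0.01)
  tmb <- c(75.2, 71.7, 64.1, 28.6, 21.6, 5.8)
  expect_equal(summarize_group(tmb)$median, 46.35, tolerance = 1e-12)
  one <- summarize_group(7)
  expect_equal(unlist(one[c("mean", "median", "q1", "q3")]),
               c(mean = 7, median = 7, q1 = 7, q3 = 7))
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("cohort_report assembles the age and histology comparisons", {
  calls <- data.frame(
    sample_id = sprintf("s%02d", 1:20),
    outlier = c(rep(TRUE, 3), rep(FALSE, 17)),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(
    sample_id = calls$sample_id,
    age_years = c(45, 47, 46, round(seq(55, 70, length.out = 17))),
    histology = c(rep("endometrioid", 8), rep("serous", 12)),
    stringsAsFactors = FALSE
  )
  rep <- cohort_report(calls, ann)
  expect_identical(rep$n_pole, 3L)
  expect_identical(unname(rep$histology$table[1, ]), c(3L, 0L))
  expect_equal(rep$pole_frequency, 3 / 8)
  expect_lt(rep$age$test$p, 0.05)
  expect_equal(rep$age$pole$mean, 46)
})
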