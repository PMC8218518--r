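test_that("capture region applies the inclusive 20x rule", {
  cov <- data.frame(chrom = "chrS", pos = 1:4, depth = c(25, 19, 20, 21))
  cr <- compute_capture_region(cov)
  expect_identical(cr$size, 3L)
  expect_identical(cr$positions$pos, c(1L, 3L, 4L))

  none <- compute_capture_region(data.frame(chrom = "chrS", pos = 1:5,
                                            depth = 0L))
  expect_identical(none$size, 0L)

  expect_error(compute_capture_region(
    data.frame(chrom = "chrS", pos = 1:2, depth = c(10, -1))), "malformed")
})

test_that("sample exclusion is strict at five million positions", {
  res <- exclude_low_coverage_samples(c(A = 4999999, B = 5000000))
  expect_identical(res$excluded, "A")
  expect_identical(res$kept, "B")

  empty <- exclude_low_coverage_samples(list())
  expect_identical(empty$kept, character(0))
  expect_identical(empty$excluded, character(0))

  all_big <- exclude_low_coverage_samples(c(x = 1e7, y = 1e7, z = 1e7))
  expect_identical(all_big$excluded, character(0))
})

test_that("a six-megabase region at exactly 20x is retained", {
  n <- 6e6
  cov <- data.frame(chrom = "chrS", pos = seq_len(n), depth = 20L)
  cr <- compute_capture_region(cov, sample_id = "big")
  expect_identical(cr$size, 6000000L)
  res <- exclude_low_coverage_samples(list(cr))
  expect_identical(res$kept, "big")
})

test_that("eSNV thresholds are strict per the stated rules", {
  keepers <- variant_row(quality_score = 0.5, depth = 30,
                         population_af = 0.001)
  expect_identical(nrow(filter_esnvs(keepers)$kept), 1L)

  # depth exactly 10 fails the strict 'greater than 10'
  d10 <- filter_esnvs(variant_row(depth = 10))
  expect_identical(nrow(d10$kept), 0L)
  expect_identical(unname(d10$removed_by_rule["low_depth"]), 1L)
  expect_identical(nrow(filter_esnvs(variant_row(depth = 11))$kept), 1L)

  # quality exactly 0.1 fails; just above passes
  expect_identical(nrow(filter_esnvs(variant_row(quality_score = 0.1))$kept), 0L)
  expect_identical(nrow(filter_esnvs(variant_row(quality_score = 0.1001))$kept), 1L)

  # population AF exactly 0.02 fails the strict 'less than 2%'; NA is kept
  expect_identical(nrow(filter_esnvs(variant_row(population_af = 0.02))$kept), 0L)
  expect_identical(nrow(filter_esnvs(variant_row(population_af = 0.0199))$kept), 1L)
  expect_identical(nrow(filter_esnvs(variant_row(population_af = NA))$kept), 1L)
})

test_that("removal is attributed to the first failing rule, and counts partition", {
  pon <- data.frame(chrom = "chrS", pos = 100L, ref = "C", alt = "T")
  v <- rbind(
    variant_row(quality_score = 0.05, depth = 5, population_af = 0.5), # q first
    variant_row(depth = 3, population_af = 0.5),                       # depth
    variant_row(population_af = 0.3),                                  # af
    variant_row(),                                                     # pon
    variant_row(pos = 101L)                                            # kept
  )
  fr <- filter_esnvs(v, pon)
  expect_identical(unname(fr$removed_by_rule),
                   c(1L, 1L, 1L, 1L))
  expect_identical(nrow(fr$kept), 1L)
  expect_identical(nrow(fr$kept) + sum(fr$removed_by_rule), fr$n_input)
})

test_that("filter agrees with a brute-force per-record oracle", {
  withr::with_seed(42, {
    n <- 50
    pon <- data.frame(chrom = "chrS", pos = c(5L, 10L), ref = c("C", "C"),
                      alt = c("T", "T"))
    v <- data.frame(
      sample_id = "s1", chrom = "chrS",
      pos = sample(1:20, n, replace = TRUE), ref = "C", alt = "T",
      quality_score = round(runif(n, 0, 0.3), 3),
      depth = sample(5:15, n, replace = TRUE),
      population_af = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.05), 4)),
      stringsAsFactors = FALSE
    )
    fr <- filter_esnvs(v, pon)
    oracle <- filter_oracle(v, pon)
    expect_identical(nrow(fr$kept), sum(oracle == "kept"))
    for (rule in names(fr$removed_by_rule)) {
      expect_identical(unname(fr$removed_by_rule[rule]),
                       sum(oracle == rule))
    }
  })
})

test_that("tightening any threshold never increases the kept count", {
  withr::with_seed(8, {
    n <- 80
    v <- data.frame(
      sample_id = "s1", chrom = "chrS", pos = seq_len(n), ref = "C",
      alt = "T", quality_score = runif(n), depth = sample(1:40, n, TRUE),
      population_af = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.05)),
      stringsAsFactors = FALSE
    )
    base_kept <- nrow(filter_esnvs(v)$kept)
    for (q in c(0.2, 0.5)) {
      expect_lte(nrow(filter_esnvs(v, q_min = q)$kept), base_kept)
    }
    for (d in c(15, 25)) {
      expect_lte(nrow(filter_esnvs(v, depth_min = d)$kept), base_kept)
    }
    for (a in c(0.01, 0.005)) {
      expect_lte(nrow(filter_esnvs(v, af_max = a)$kept), base_kept)
    }
  })
})

test_that("TMB arithmetic is exact and guards against empty regions", {
  expect_identical(compute_tmb(50, 1e7), 5)
  expect_identical(compute_tmb(0, 5e6), 0)
  expect_identical(compute_tmb(575, 1e8), 5.75)
  expect_error(compute_tmb(10, 0), "undefined")
})

test_that("panel of normals requires recurrence in two distinct normals", {
  nv <- data.frame(
    normal_id = c("N1", "N2", "N1", "N1", "N3"),
    chrom = "chrS", pos = c(7L, 7L, 9L, 9L, 11L),
    ref = "C", alt = "T", stringsAsFactors = FALSE
  )
  pon <- build_panel_of_normals(nv)
  # pos 7 seen in N1+N2 (recurrent); pos 9 twice in N1 only; pos 11 once
  expect_identical(pon$pos, 7L)
  expect_identical(nrow(build_panel_of_normals(nv[0, ])), 0L)
})
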