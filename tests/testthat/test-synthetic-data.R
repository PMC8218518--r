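test_that("generate_reference is deterministic and hits its GC target", {
  a <- generate_reference(10000, 0.5, seed = 1)
  b <- generate_reference(10000, 0.5, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_reference(10000, 0.5, seed = 2)))

  r <- generate_reference(2e5, 0.41, seed = 7)
  gc <- sum(strsplit(r[[1]], "")[[1]] %in% c("G", "C")) / 2e5
  expect_gte(gc, 0.39)
  expect_lte(gc, 0.43)

  hi <- generate_reference(10000, 0.99, seed = 1)
  gc_hi <- sum(strsplit(hi[[1]], "")[[1]] %in% c("G", "C")) / 10000
  expect_gte(gc_hi, 0.96)
})

test_that("generate_reference rejects invalid configurations", {
  expect_error(generate_reference(5000, 0.5, seed = 1), "configuration")
  expect_error(generate_reference(20000, 0, seed = 1), "configuration")
  expect_error(generate_reference(20000, 1.2, seed = 1), "configuration")
})

test_that("clean variant channels round-trip through the reference", {
  sc <- small_cohort()
  cv <- sc$cohort$clean_variants
  ctx <- substring(sc$reference[[1]], cv$pos - 1L, cv$pos + 1L)
  recomputed <- channel_index(ctx, cv$ref, cv$alt)
  expect_false(anyNA(recomputed))
  expect_identical(channel_labels()[recomputed + 1L], cv$channel)
})

test_that("clean counts and manifest TMB are conserved exactly", {
  sc <- small_cohort()
  co <- sc$cohort
  counts <- table(factor(co$clean_variants$sample_id,
                         levels = names(co$capture_bases)))
  expect_identical(as.integer(counts),
                   as.integer(sc$config$mutations_per_sample[names(co$capture_bases)]))
  man <- co$manifest
  expect_equal(man$true_tmb_per_signature,
               sweep(man$true_counts_per_signature, 2, man$capture_bases,
                     "/") * 1e6)
  expect_identical(colSums(man$true_counts_per_signature),
                   stats::setNames(as.numeric(counts),
                                   names(co$capture_bases)))
})

test_that("a zero-mutation sample yields a valid empty profile column", {
  catalog <- synthetic_cosmic_catalog()
  ref <- tiny_reference()
  W <- matrix(c(1, 1), ncol = 1,
              dimnames = list(c("a", "b"), "COSMIC_10"))
  cfg <- simulation_config(
    n_samples = 2, reference_length = 2e4, gc_content = 0.5,
    mixture_weights = W, mutations_per_sample = c(a = 0L, b = 50L),
    capture_fraction = c(a = 1, b = 1), seed = 3
  )
  co <- simulate_cohort(cfg, catalog, ref)
  m <- build_profiles(co$clean_variants, ref, sample_ids = c("a", "b"))
  expect_true(all(m[, "a"] == 0))
  expect_identical(sum(m[, "b"]), 50L)
  # the empty sample still writes a syntactically valid VCF
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  va <- read_vcf(file.path(dir, "vcf", "a.vcf"))
  expect_identical(nrow(va), 0L)
})

test_that("identical config and seed reproduce bit-identical VCFs", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc1 <- small_cohort()
  sc2 <- small_cohort()
  write_cohort(sc1$cohort, dir1)
  write_cohort(sc2$cohort, dir2)
  for (f in list.files(file.path(dir1, "vcf"))) {
    expect_identical(readLines(file.path(dir1, "vcf", f)),
                     readLines(file.path(dir2, "vcf", f)))
  }
})

test_that("inject_filter_failures plants exactly what is asked", {
  ref <- tiny_reference()
  base <- variant_row(pos = 1000L,
                      ref = substring(ref[[1]], 1000, 1000), alt = NA)
  base$alt <- setdiff(c("A", "C", "G", "T"), base$ref)[1]
  inj <- inject_filter_failures(base, list(low_depth = 5), reference = ref,
                                seed = 4)
  expect_identical(nrow(inj$variants), 6L)
  expect_identical(sum(inj$labels$failure_class == "low_depth"), 5L)
  added <- inj$variants[-1, ]
  expect_true(all(added$depth <= 10))
  expect_true(all(added$quality_score > 0.1))

  # empty map is the identity
  inj0 <- inject_filter_failures(base, list(), reference = ref, seed = 4)
  expect_identical(inj0$variants, base)

  expect_error(
    inject_filter_failures(base, list(bogus = 1), reference = ref),
    "unknown failure class")
})

test_that("planted failures are removed by the filter, clean records kept", {
  ref <- tiny_reference()
  clean <- do.call(rbind, lapply(1:10, function(i) {
    p <- 500L + 7L * i
    r <- substring(ref[[1]], p, p)
    variant_row(pos = p, ref = r, alt = setdiff(c("A", "C", "G", "T"), r)[1])
  }))
  inj <- inject_filter_failures(clean,
                                list(low_quality = 3, common_population = 2),
                                reference = ref, seed = 9)
  fr <- filter_esnvs(inj$variants)
  expect_identical(nrow(fr$kept), 10L)
  expect_identical(sum(fr$removed_by_rule), 5L)
  expect_identical(unname(fr$removed_by_rule["low_quality"]), 3L)
  expect_identical(unname(fr$removed_by_rule["common_population"]), 2L)
})

test_that("hotspot spiking adds passing records and records ground truth", {
  ref <- tiny_reference()
  hot <- make_hotspot_table(ref, seed = 5)
  expect_identical(hot$ref, substring(ref[[1]], hot$pos, hot$pos))
  v0 <- empty_variants_frame <- variant_row()[0, ]
  sp <- spike_hotspots(v0, hot, c(P4 = "P286R"), reference = ref)
  expect_identical(nrow(sp), 1L)
  hits <- check_hotspots(filter_esnvs(sp)$kept, hot)
  expect_identical(nrow(hits$P4), 1L)
  expect_identical(hits$P4$protein_change, "P286R")

  # empty sample set is the identity
  sp0 <- spike_hotspots(v0, hot, character(0), reference = ref)
  expect_identical(nrow(sp0), 0L)

  # two hotspots into one sample -> two hits
  sp2 <- spike_hotspots(v0, hot, c(X = "V411L", X = "A456P"),
                        reference = ref)
  hits2 <- check_hotspots(filter_esnvs(sp2)$kept, hot)
  expect_identical(nrow(hits2$X), 2L)

  # mismatching reference base is a data error
  bad <- hot
  bad$ref <- ifelse(bad$ref == "C", "G", "C")
  expect_error(spike_hotspots(v0, bad, c(P4 = "P286R"), reference = ref),
               "ref mismatch")
})

test_that("panel of normals sites are recurrent among the normals", {
  ref <- tiny_reference()
  withr::with_seed(2, {
    pon <- simulate_panel_of_normals(ref, n_sites = 8, n_normals = 6)
    expect_identical(nrow(pon$sites), 8L)
    rebuilt <- build_panel_of_normals(pon$normal_variants)
    key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt))
    expect_identical(key(rebuilt), key(pon$sites))
  })
})
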