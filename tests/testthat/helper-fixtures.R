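# Shared fixtures, built in code at test time.

tiny_reference <- function(length = 20000, gc = 0.5, seed = 101) {
  generate_reference(length, gc, seed)
}

# 4-sample cohort on a 200 kb reference: three pure-signature samples and
# one mixed sample, with planted filter failures and one hotspot spike.
small_cohort <- function(seed = 11, mutations = c(A = 1000, B = 1000,
                                                  C = 1000, D = 500)) {
  catalog <- synthetic_cosmic_catalog()
  ref <- generate_reference(2e5, 0.41, seed = 7)
  W <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1,
                0.2, 0.3, 0.5),
              nrow = 4, byrow = TRUE,
              dimnames = list(names(mutations),
                              c("COSMIC_1", "COSMIC_5", "COSMIC_10")))
  cfg <- simulation_config(
    n_samples = 4, reference_length = 2e5, gc_content = 0.41,
    mixture_weights = W, mutations_per_sample = mutations,
    capture_fraction = c(A = 0.9, B = 0.9, C = 0.9, D = 0.9),
    pon_artifact_count = 5,
    filter_failure_counts = list(low_quality = 3, common_population = 2),
    hotspot_samples = c(C = "P286R"), seed = seed
  )
  list(cohort = simulate_cohort(cfg, catalog, ref), config = cfg,
       catalog = catalog, reference = ref)
}

# Hand-built variant rows for filter tests.
variant_row <- function(sample_id = "s1", chrom = "chrS", pos = 100L,
                        ref = "C", alt = "T", quality_score = 0.5,
                        depth = 30L, population_af = NA_real_) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, quality_score = quality_score, depth = depth,
             population_af = population_af, stringsAsFactors = FALSE)
}

# Independent per-record filter oracle: evaluates each rule directly.
filter_oracle <- function(v, pon = NULL, q_min = 0.1, depth_min = 10,
                          af_max = 0.02) {
  pon_key <- if (is.null(pon)) character(0) else
    paste(pon$chrom, pon$pos, pon$ref, pon$alt)
  verdict <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    verdict[i] <- if (!(v$quality_score[i] > q_min)) "low_quality"
    else if (!(v$depth[i] > depth_min)) "low_depth"
    else if (!is.na(v$population_af[i]) &&
             !(v$population_af[i] < af_max)) "common_population"
    else if (paste(v$chrom[i], v$pos[i], v$ref[i], v$alt[i]) %in% pon_key)
      "pon_recurrent"
    else "kept"
  }
  verdict
}

# Dirichlet-ish mixture count matrix drawn straight from signatures, for
# factorization tests that do not need the genomic placement machinery.
mixture_counts <- function(truth, n_samples, n_mutations, seed,
                           alpha = 1) {
  withr::with_seed(seed, {
    K <- ncol(truth)
    Wt <- matrix(stats::rgamma(n_samples * K, shape = alpha), ncol = K)
    Wt <- Wt / rowSums(Wt)
    V <- vapply(seq_len(n_samples), function(i) {
      stats::rmultinom(1, n_mutations, truth %*% Wt[i, ])[, 1]
    }, numeric(96))
    rownames(V) <- rownames(truth)
    colnames(V) <- sprintf("m%03d", seq_len(n_samples))
    list(V = V, weights = Wt)
  })
}
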