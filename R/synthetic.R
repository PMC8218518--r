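#' Generate a random reference sequence
#'
#' @param length Number of bases (>= 10,000).
#' @param gc_content Target GC fraction in (0, 1); bases are drawn i.i.d.
#'   with P(G) = P(C) = gc/2.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param name Sequence (chromosome) name.
#' @param path Optional FASTA path to write.
#' @return Named character vector of length 1 (the sequence).
#' @export
generate_reference <- function(length, gc_content, seed, name = "chrS",
                               path = NULL) {
  if (length < 10000) stop("configuration error: reference length must be >= 10,000")
  if (gc_content <= 0 || gc_content >= 1) {
    stop("configuration error: gc_content must lie in (0, 1)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  seq <- paste(sample(.BASES, length, replace = TRUE, prob = p),
               collapse = "")
  out <- stats::setNames(seq, name)
  if (!is.null(path)) write_reference_fasta(out, path)
  out
}

#' Simulation configuration for a synthetic eSNV cohort
#'
#' @param n_samples Number of tumor samples.
#' @param reference_length Reference length in bases.
#' @param gc_content Reference GC fraction.
#' @param mixture_weights N x K matrix (rows = samples, columns = catalog
#'   signature names, rows summing to 1).
#' @param mutations_per_sample Named integer vector of clean variant counts.
#' @param capture_fraction Named numeric vector in (0, 1]: fraction of the
#'   reference covered at >= 20x per sample (the capture region is the
#'   prefix of that many bases).
#' @param n_normals Number of synthetic normals behind the panel of normals.
#' @param pon_artifact_count Number of recurrent artifact sites.
#' @param filter_failure_counts Named list/vector: failure class -> count of
#'   planted failing variants (cohort-wide, assigned to random samples).
#' @param hotspot_samples Named character vector: sample id -> hotspot
#'   protein label to spike.
#' @param seed Integer seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples, reference_length, gc_content,
                              mixture_weights, mutations_per_sample,
                              capture_fraction, n_normals = 10,
                              pon_artifact_count = 0,
                              filter_failure_counts = list(),
                              hotspot_samples = character(0), seed = 1) {
  stopifnot(reference_length >= 10000, n_samples >= 1)
  mixture_weights <- as.matrix(mixture_weights)
  if (nrow(mixture_weights) != n_samples) {
    stop("configuration error: mixture_weights needs one row per sample")
  }
  if (any(abs(rowSums(mixture_weights) - 1) > 1e-9)) {
    stop("configuration error: mixture_weights rows must sum to 1")
  }
  if (any(mixture_weights < 0) || any(mutations_per_sample < 0)) {
    stop("configuration error: negative weights or counts")
  }
  if (length(mutations_per_sample) != n_samples ||
      length(capture_fraction) != n_samples) {
    stop("configuration error: per-sample vectors must have length n_samples")
  }
  bad <- setdiff(names(filter_failure_counts), .FILTER_RULES)
  if (length(bad)) {
    stop("configuration error: unknown failure class ", bad[1])
  }
  structure(list(
    n_samples = n_samples, reference_length = reference_length,
    gc_content = gc_content, mixture_weights = mixture_weights,
    mutations_per_sample = mutations_per_sample,
    capture_fraction = capture_fraction, n_normals = n_normals,
    pon_artifact_count = pon_artifact_count,
    filter_failure_counts = filter_failure_counts,
    hotspot_samples = hotspot_samples, seed = seed
  ), class = "simulation_config")
}

#' Default synthetic study conditions
#'
#' A 195-sample cohort mirroring the structure of an unselected ovarian
#' cancer RNA-seq cohort: 189 background samples whose non-POLE burden is
#' drawn uniformly between 0.2 and 2 mut/Mb from a mix of aging (COSMIC_1),
#' flat (COSMIC_5) and smoking-like (COSMIC_4) signatures, plus a genuine
#' low POLE-signature component drawn uniformly between 0 and 2.5 mut/Mb
#' (non-POLE tumors and normal tissue show a small but real signature-10
#' attribution, and the boxplot fence must sit between the background
#' maximum and the smallest true POLE case); and six hypermutated samples
#' P1-P6 whose POLE-signature burden is planted at 75.2, 71.7, 64.1, 28.6,
#' 21.6 and 5.8 mut/Mb (90% COSMIC_10-like, 10% aging), each spiked with
#' one POLE hotspot analog (A456P, S297F, V411L, P286R, P286R, V411L
#' respectively). Per-sample capture fractions are uniform in \[0.5, 1\] of
#' a 30 Mb reference, i.e. 15-30 Mb capture.
#'
#' @param seed Integer seed.
#' @param n_background Number of background samples (default 189).
#' @param reference_length Reference length (default 3e7).
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(seed = 1, n_background = 189,
                                      reference_length = 3e7) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pole_tmb <- c(P1 = 75.2, P2 = 71.7, P3 = 64.1, P4 = 28.6, P5 = 21.6,
                P6 = 5.8)
  pole_hotspot <- c(P1 = "A456P", P2 = "S297F", P3 = "V411L", P4 = "P286R",
                    P5 = "P286R", P6 = "V411L")
  bg_ids <- sprintf("S%03d", seq_len(n_background))
  ids <- c(bg_ids, names(pole_tmb))
  n <- length(ids)
  sig_names <- c("COSMIC_1", "COSMIC_4", "COSMIC_5", "COSMIC_10")
  W <- matrix(0, nrow = n, ncol = 4, dimnames = list(ids, sig_names))
  capture_fraction <- stats::setNames(stats::runif(n, 0.5, 1), ids)
  capture_bases <- floor(capture_fraction * reference_length)
  g <- matrix(stats::rgamma(n_background * 3, shape = c(2, 1, 1)),
              ncol = 3, byrow = TRUE)
  bg_other_tmb <- stats::runif(n_background, 0.2, 2)
  bg_pole_tmb <- stats::runif(n_background, 0, 2.5)
  bg_total <- bg_other_tmb + bg_pole_tmb
  W[bg_ids, 1:3] <- (g / rowSums(g)) * (bg_other_tmb / bg_total)
  W[bg_ids, "COSMIC_10"] <- bg_pole_tmb / bg_total
  W[names(pole_tmb), "COSMIC_10"] <- 0.9
  W[names(pole_tmb), "COSMIC_1"] <- 0.1
  total_tmb <- stats::setNames(c(bg_total, pole_tmb / 0.9), ids)
  mutations <- stats::setNames(
    pmax(1L, as.integer(round(total_tmb * capture_bases / 1e6))), ids)
  simulation_config(
    n_samples = n, reference_length = reference_length, gc_content = 0.41,
    mixture_weights = W, mutations_per_sample = mutations,
    capture_fraction = capture_fraction, n_normals = 10,
    pon_artifact_count = 25,
    filter_failure_counts = list(low_quality = 40, low_depth = 40,
                                 common_population = 30, pon_recurrent = 30),
    hotspot_samples = pole_hotspot, seed = seed
  )
}

# Integer base codes A=0 C=1 G=2 T=3 for a sequence string.
base_codes <- function(seq) {
  lut <- integer(128); lut[] <- NA_integer_
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(seq)]
}

# Positions 2..(L-1) of each genomic trinucleotide code (0..63), ascending.
index_trinucleotides <- function(seq) {
  b <- base_codes(seq)
  L <- length(b)
  if (L < 3) stop("reference too short to host trinucleotide contexts")
  tcode <- 16L * b[1:(L - 2)] + 4L * b[2:(L - 1)] + b[3:L]
  pos <- seq.int(2L, L - 1L)
  ok <- !is.na(tcode)
  split(pos[ok], factor(tcode[ok], levels = 0:63))
}

# For channel ch (0..95): the genomic trinucleotide codes that can host it.
# Forward code has a pyrimidine center; reverse code is its complement.
channel_tricodes <- function(ch) {
  block <- ch %/% 16L; rest <- ch %% 16L
  f5 <- rest %/% 4L; f3 <- rest %% 4L
  center <- if (block < 3L) 1L else 3L # C or T
  fwd <- 16L * f5 + 4L * center + f3
  rev <- 16L * (3L - f3) + 4L * (3L - center) + (3L - f5)
  alt_pyr <- c(0L, 2L, 3L, 0L, 1L, 2L)[block + 1L] # alt base code, pyr strand
  list(fwd = fwd, rev = rev, center = center, alt_pyr = alt_pyr)
}

clean_annotations <- function(n) {
  data.frame(
    quality_score = round(stats::runif(n, 0.2, 1), 4),
    depth = 11L + stats::rpois(n, 40),
    population_af = ifelse(stats::runif(n) < 0.3,
                           round(stats::runif(n, 0, 0.019), 6),
                           NA_real_)
  )
}

#' Simulate a cohort of expressed-SNV call sets from known signatures
#'
#' For every sample, each clean variant's channel is drawn from the sample's
#' signature mixture and placed (uniformly, without replacement within the
#' sample) at a capture-region position whose trinucleotide context matches
#' the drawn channel after pyrimidine-strand collapse. Clean variants carry
#' annotations that pass all downstream filters. Panel-of-normals artifacts,
#' planted filter failures and hotspot spikes are then layered on per the
#' configuration, and everything is recorded in a ground-truth manifest.
#'
#' @param config A [simulation_config()].
#' @param catalog Signature catalog containing every column named in
#'   `config$mixture_weights`.
#' @param reference Named character vector (single sequence), e.g. from
#'   [generate_reference()].
#' @param out_dir Optional directory: writes one VCF per sample, the
#'   reference FASTA, hotspot table, panel of normals TSV and manifest JSON.
#' @param write_coverage_files Also write dense per-base coverage TSVs
#'   (intended for small references; default FALSE).
#' @return List of class `synthetic_cohort`: `variants` (all records),
#'   `clean_variants`, `capture_bases` (named), `panel_of_normals`,
#'   `normal_variants`, `hotspot_table`, `manifest`, `reference`.
#' @export
simulate_cohort <- function(config, catalog, reference, out_dir = NULL,
                            write_coverage_files = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  validate_catalog(catalog)
  sig_names <- colnames(config$mixture_weights)
  missing_sig <- setdiff(sig_names, colnames(catalog))
  if (length(missing_sig)) {
    stop("catalog lacks signature ", missing_sig[1])
  }
  if (length(reference) != 1) stop("expected a single reference sequence")
  chrom <- names(reference)
  L <- nchar(reference[[1]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  by_tricode <- index_trinucleotides(reference[[1]])
  tric <- lapply(0:95, channel_tricodes)
  ids <- rownames(config$mixture_weights)
  capture_bases <- stats::setNames(
    pmin(floor(config$capture_fraction * L), L), ids)
  K <- length(sig_names)
  sig_counts <- matrix(0L, nrow = K, ncol = length(ids),
                       dimnames = list(sig_names, ids))
  all_var <- vector("list", length(ids))

  for (si in seq_along(ids)) {
    id <- ids[si]
    n_mut <- config$mutations_per_sample[[id]]
    cap <- capture_bases[[id]]
    if (n_mut == 0) {
      all_var[[si]] <- data.frame(empty_variants(),
                                  channel = character(0),
                                  stringsAsFactors = FALSE)
      next
    }
    sig_of <- sample.int(K, n_mut, replace = TRUE,
                         prob = config$mixture_weights[id, ])
    sig_counts[, si] <- tabulate(sig_of, nbins = K)
    ch_of <- integer(n_mut)
    for (k in seq_len(K)) {
      idx <- which(sig_of == k)
      if (length(idx)) {
        ch_of[idx] <- sample.int(96, length(idx), replace = TRUE,
                                 prob = catalog[, sig_names[k]]) - 1L
      }
    }
    used <- integer(0)
    pos <- integer(n_mut); ref <- character(n_mut); alt <- character(n_mut)
    for (ch in sort(unique(ch_of))) {
      idx <- which(ch_of == ch)
      tc <- tric[[ch + 1L]]
      fwd <- by_tricode[[tc$fwd + 1L]]
      rev <- by_tricode[[tc$rev + 1L]]
      fwd <- fwd[seq_len(findInterval(cap, fwd))]
      # (positions are ascending, so this truncates to the capture prefix)
      rev <- rev[seq_len(findInterval(cap - 1L, rev))]
      cand <- c(fwd, rev)
      n_fwd <- length(fwd)
      if (length(cand) - length(used) < length(idx)) {
        stop("simulation error: cannot place channel ",
             channel_labels()[ch + 1L], " (context absent from reference)")
      }
      pick <- sample.int(length(cand), length(idx))
      while (any(cand[pick] %in% used) || anyDuplicated(cand[pick])) {
        bad <- cand[pick] %in% used | duplicated(cand[pick])
        pick[bad] <- sample.int(length(cand), sum(bad))
      }
      chosen <- cand[pick]
      used <- c(used, chosen)
      is_fwd <- pick <= n_fwd
      pyr_ref <- .BASES[tc$center + 1L]
      pyr_alt <- .BASES[tc$alt_pyr + 1L]
      pos[idx] <- chosen
      ref[idx] <- ifelse(is_fwd, pyr_ref, .COMP[[pyr_ref]])
      alt[idx] <- ifelse(is_fwd, pyr_alt, .COMP[[pyr_alt]])
    }
    ann <- clean_annotations(n_mut)
    all_var[[si]] <- data.frame(
      sample_id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
      quality_score = ann$quality_score, depth = ann$depth,
      population_af = ann$population_af,
      channel = channel_labels()[ch_of + 1L], stringsAsFactors = FALSE
    )
  }
  clean <- do.call(rbind, all_var)
  rownames(clean) <- NULL

  pon <- simulate_panel_of_normals(reference, config$pon_artifact_count,
                                   config$n_normals,
                                   max_pos = min(capture_bases))
  inj <- inject_filter_failures(clean[, setdiff(names(clean), "channel")],
                                config$filter_failure_counts,
                                panel_of_normals = pon$sites,
                                reference = reference, sample_ids = ids,
                                max_pos = min(capture_bases))
  hot_tab <- make_hotspot_table(reference, max_pos = min(capture_bases))
  spiked <- spike_hotspots(inj$variants, hot_tab, config$hotspot_samples,
                           reference = reference)

  true_tmb <- sweep(sig_counts, 2, capture_bases, "/") * 1e6
  manifest <- list(
    true_signatures = catalog[, sig_names, drop = FALSE],
    true_weights = t(config$mixture_weights),
    true_counts_per_signature = sig_counts,
    true_tmb_per_signature = true_tmb,
    capture_bases = capture_bases,
    mutations_per_sample = config$mutations_per_sample,
    spiked_hotspots = attr(spiked, "spiked"),
    planted_failures = inj$labels,
    seed = config$seed
  )
  cohort <- structure(list(
    variants = spiked, clean_variants = clean,
    capture_bases = capture_bases, panel_of_normals = pon$sites,
    normal_variants = pon$normal_variants, hotspot_table = hot_tab,
    manifest = manifest, reference = reference
  ), class = "synthetic_cohort")
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir, write_coverage_files = write_coverage_files)
  }
  cohort
}

#' Write a synthetic cohort to disk
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param write_coverage_files Write dense per-base coverage TSVs too.
#' @export
write_cohort <- function(cohort, out_dir, write_coverage_files = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "vcf"), showWarnings = FALSE)
  write_reference_fasta(cohort$reference,
                        file.path(out_dir, "reference.fa"))
  chrom <- names(cohort$reference)
  for (id in names(cohort$capture_bases)) {
    v <- cohort$variants[cohort$variants$sample_id == id, , drop = FALSE]
    write_vcf(v, file.path(out_dir, "vcf", paste0(id, ".vcf")),
              sample_id = id)
  }
  if (write_coverage_files) {
    dir.create(file.path(out_dir, "coverage"), showWarnings = FALSE)
    for (id in names(cohort$capture_bases)) {
      n <- cohort$capture_bases[[id]]
      cov <- data.frame(chrom = chrom, pos = seq_len(n), depth = 20L)
      write_coverage(cov, file.path(out_dir, "coverage",
                                    paste0(id, ".coverage.tsv")))
    }
  }
  utils::write.table(
    data.frame(sample_id = names(cohort$capture_bases),
               capture_bases = unname(cohort$capture_bases)),
    file.path(out_dir, "capture_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$panel_of_normals,
                     file.path(out_dir, "panel_of_normals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_hotspots(cohort$hotspot_table, file.path(out_dir, "hotspots.tsv"))
  man <- cohort$manifest
  jsonlite::write_json(
    list(capture_bases = as.list(man$capture_bases),
         mutations_per_sample = as.list(man$mutations_per_sample),
         true_weights = man$true_weights,
         true_counts_per_signature = man$true_counts_per_signature,
         true_tmb_per_signature = man$true_tmb_per_signature,
         spiked_hotspots = man$spiked_hotspots,
         planted_failures = man$planted_failures,
         seed = man$seed),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a panel of recurrent normal-tissue artifacts
#'
#' Each artifact site is assigned to at least two of `n_normals` synthetic
#' normals, the minimal definition of a recurrent site.
#'
#' @param reference Named character vector (single sequence).
#' @param n_sites Number of artifact sites.
#' @param n_normals Number of synthetic normals.
#' @param max_pos Largest position usable (keep sites inside every
#'   sample's capture region).
#' @return List: `sites` (chrom/pos/ref/alt), `normal_variants`
#'   (normal_id/chrom/pos/ref/alt).
#' @export
simulate_panel_of_normals <- function(reference, n_sites, n_normals,
                                      max_pos = NULL) {
  chrom <- names(reference)
  L <- nchar(reference[[1]])
  if (is.null(max_pos)) max_pos <- L - 1L
  if (n_sites == 0) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
    nv <- data.frame(normal_id = character(0), chrom = character(0),
                     pos = integer(0), ref = character(0),
                     alt = character(0))
    return(list(sites = sites, normal_variants = nv))
  }
  pos <- sample(seq.int(2L, max_pos), n_sites)
  ref <- substring(reference[[1]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), character(1),
                USE.NAMES = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  nv <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    k <- sample(2:max(2, min(n_normals, 5)), 1)
    data.frame(normal_id = paste0("N", sample.int(n_normals, k)),
               chrom = chrom, pos = pos[i], ref = ref[i], alt = alt[i],
               stringsAsFactors = FALSE)
  }))
  rownames(nv) <- NULL
  list(sites = sites, normal_variants = nv)
}

#' Plant variants that each fail exactly one eSNV filter
#'
#' Adds the requested number of variants per failure class, each failing
#' only its own class's filter: `low_quality` (quality score <= 0.1),
#' `low_depth` (depth <= 10), `common_population` (population AF >= 2%),
#' `pon_recurrent` (site present in the panel of normals). Added records
#' are assigned to random samples.
#'
#' @param variants Existing variant data frame.
#' @param failure_counts Named list/vector: class -> count. Empty map
#'   returns the input unchanged.
#' @param panel_of_normals Required when `pon_recurrent` is requested.
#' @param reference Named character vector for reference-consistent bases.
#' @param seed Optional seed (defaults to continuing the current RNG
#'   stream, as inside [simulate_cohort()]).
#' @param sample_ids Samples to assign failures to.
#' @param max_pos Largest usable position.
#' @return List: `variants` (augmented), `labels` (data frame sample_id /
#'   chrom / pos / ref / alt / failure_class).
#' @export
inject_filter_failures <- function(variants, failure_counts,
                                   panel_of_normals = NULL, reference,
                                   seed = NULL,
                                   sample_ids = unique(variants$sample_id),
                                   max_pos = NULL) {
  bad <- setdiff(names(failure_counts), .FILTER_RULES)
  if (length(bad)) stop("configuration error: unknown failure class ", bad[1])
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  labels <- data.frame(sample_id = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), failure_class = character(0),
                       stringsAsFactors = FALSE)
  total <- sum(unlist(failure_counts))
  if (total == 0) {
    return(list(variants = variants, labels = labels))
  }
  chrom <- names(reference)
  L <- nchar(reference[[1]])
  if (is.null(max_pos)) max_pos <- L - 1L
  add <- list()
  for (cls in names(failure_counts)) {
    n <- failure_counts[[cls]]
    if (n == 0) next
    if (cls == "pon_recurrent") {
      if (is.null(panel_of_normals) || nrow(panel_of_normals) == 0) {
        stop("configuration error: pon_recurrent failures need a panel of normals")
      }
      rows <- panel_of_normals[
        sample.int(nrow(panel_of_normals), n, replace = TRUE), ,
        drop = FALSE]
      pos <- rows$pos; ref <- rows$ref; alt <- rows$alt
    } else {
      pos <- sample(seq.int(2L, max_pos), n)
      ref <- substring(reference[[1]], pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1),
                    character(1), USE.NAMES = FALSE)
    }
    ann <- clean_annotations(n)
    if (cls == "low_quality") ann$quality_score <- round(stats::runif(n, 0, 0.0999), 4)
    if (cls == "low_depth") ann$depth <- sample(0:10, n, replace = TRUE)
    if (cls == "common_population") {
      ann$population_af <- round(stats::runif(n, 0.021, 0.5), 6)
    }
    add[[cls]] <- data.frame(
      sample_id = sample(sample_ids, n, replace = TRUE), chrom = chrom,
      pos = pos, ref = ref, alt = alt,
      quality_score = ann$quality_score, depth = ann$depth,
      population_af = ann$population_af, failure_class = cls,
      stringsAsFactors = FALSE
    )
  }
  added <- do.call(rbind, add)
  rownames(added) <- NULL
  labels <- added[, c("sample_id", "chrom", "pos", "ref", "alt",
                      "failure_class")]
  out <- rbind(variants, added[, names(variants), drop = FALSE])
  rownames(out) <- NULL
  list(variants = out, labels = labels)
}

#' Build a synthetic POLE hotspot table on a simulated reference
#'
#' Picks one locus per hotspot label at a TpCpT context with a C>A change
#' (or TpCpG with C>T), the substitution classes characteristic of POLE
#' exonuclease deficiency, so spiked hotspot variants are consistent with
#' the POLE-like signature.
#'
#' @param reference Named character vector (single sequence).
#' @param labels Protein-change labels (default the four canonical POLE
#'   exonuclease hotspots).
#' @param max_pos Largest usable position.
#' @param seed Optional seed (defaults to the current RNG stream).
#' @return Data frame `gene`, `protein_change`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @export
make_hotspot_table <- function(reference,
                               labels = c("P286R", "S297F", "V411L", "A456P"),
                               max_pos = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  chrom <- names(reference)
  L <- nchar(reference[[1]])
  if (is.null(max_pos)) max_pos <- L - 1L
  hits <- gregexpr("TCT", substr(reference[[1]], 1, max_pos + 1L))[[1]]
  hits2 <- gregexpr("TCG", substr(reference[[1]], 1, max_pos + 1L))[[1]]
  cand <- sort(c(hits[hits > 0] + 1L, hits2[hits2 > 0] + 1L))
  cand <- cand[cand >= 2 & cand <= max_pos]
  if (length(cand) < length(labels)) {
    stop("reference too short to host hotspot contexts")
  }
  pos <- sort(sample(cand, length(labels)))
  ref <- substring(reference[[1]], pos, pos)
  ctx3 <- substring(reference[[1]], pos + 1L, pos + 1L)
  alt <- ifelse(ctx3 == "T", "A", "T") # TCT -> TAT, TCG -> TTG analogs
  data.frame(gene = "POLE", protein_change = labels, chrom = chrom,
             pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Spike filter-passing hotspot variants into named samples
#'
#' @param variants Variant data frame.
#' @param hotspot_table Data frame from [make_hotspot_table()] or
#'   [read_hotspots()].
#' @param sample_ids Samples to spike. A named character vector maps sample
#'   id -> protein label; an unnamed vector assigns hotspots cyclically.
#'   Empty input returns `variants` unchanged.
#' @param reference Optional reference to verify hotspot ref bases against.
#' @return Augmented variant data frame; attribute `spiked` lists the added
#'   records (sample_id, gene, protein_change, chrom, pos, ref, alt).
#' @export
spike_hotspots <- function(variants, hotspot_table, sample_ids,
                           reference = NULL) {
  empty <- data.frame(sample_id = character(0), gene = character(0),
                      protein_change = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  if (length(sample_ids) == 0) {
    attr(variants, "spiked") <- empty
    return(variants)
  }
  if (!is.null(reference)) {
    at <- substring(reference[[1]], hotspot_table$pos, hotspot_table$pos)
    if (any(at != hotspot_table$ref)) {
      i <- which(at != hotspot_table$ref)[1]
      stop(sprintf("data error: hotspot %s ref mismatch at %s:%d",
                   hotspot_table$protein_change[i], hotspot_table$chrom[i],
                   hotspot_table$pos[i]))
    }
  }
  if (is.null(names(sample_ids))) {
    lab <- hotspot_table$protein_change[
      ((seq_along(sample_ids) - 1L) %% nrow(hotspot_table)) + 1L]
    sample_ids <- stats::setNames(lab, sample_ids)
  }
  rows <- match(sample_ids, hotspot_table$protein_change)
  if (any(is.na(rows))) {
    stop("data error: unknown hotspot label ",
         sample_ids[which(is.na(rows))[1]])
  }
  h <- hotspot_table[rows, , drop = FALSE]
  added <- data.frame(
    sample_id = names(sample_ids), chrom = h$chrom, pos = h$pos,
    ref = h$ref, alt = h$alt, quality_score = 0.95, depth = 60L,
    population_af = NA_real_, stringsAsFactors = FALSE
  )
  out <- rbind(variants, added[, names(variants), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "spiked") <- data.frame(
    sample_id = names(sample_ids), gene = h$gene,
    protein_change = h$protein_change, chrom = h$chrom, pos = h$pos,
    ref = h$ref, alt = h$alt, stringsAsFactors = FALSE
  )
  out
}
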