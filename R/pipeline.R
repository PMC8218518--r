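#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage parameter with its default. Unknown arguments are
#' rejected, so configs stay reproducible.
#'
#' @param seed Integer seed driving simulation and factorization.
#' @param simulation A [simulation_config()] (default:
#'   [default_simulation_config()] at `seed`).
#' @param q_min,depth_min,af_max eSNV filter thresholds.
#' @param min_depth Coverage depth defining the capture region.
#' @param min_capture Minimum capture size in bases for sample retention.
#' @param rank,n_restarts,max_iter,tol NMF parameters.
#' @param min_similarity Minimum cosine to accept a POLE-signature match.
#' @param threshold Optional fixed outlier threshold (mut/Mb); `NULL` uses
#'   the Tukey fence.
#' @param catalog_seed Seed for the synthetic reference catalog.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, simulation = NULL, q_min = 0.10,
                       depth_min = 10, af_max = 0.02, min_depth = 20,
                       min_capture = 5e6, rank = 4, n_restarts = 30,
                       max_iter = 2000, tol = 1e-6, min_similarity = 0.8,
                       threshold = NULL, catalog_seed = 2021) {
  if (is.null(simulation)) simulation <- default_simulation_config(seed)
  stopifnot(q_min >= 0, q_min <= 1, depth_min >= 0, af_max > 0, af_max <= 1,
            min_depth >= 0, min_capture >= 0, rank >= 1, n_restarts >= 1,
            max_iter >= 1, tol > 0, min_similarity >= 0, min_similarity <= 1)
  structure(list(seed = seed, simulation = simulation, q_min = q_min,
                 depth_min = depth_min, af_max = af_max,
                 min_depth = min_depth, min_capture = min_capture,
                 rank = rank, n_restarts = n_restarts, max_iter = max_iter,
                 tol = tol, min_similarity = min_similarity,
                 threshold = threshold, catalog_seed = catalog_seed),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; a `simulation` block, if
#' present, overrides the scalar fields of the default simulation config
#' (`n_samples` via `n_background`, `reference_length`, `seed`). Unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_keys <- y$simulation
  y$simulation <- NULL
  known <- setdiff(names(formals(run_config)), "simulation")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("configuration error: unknown config key ", bad[1])
  cfg <- do.call(run_config, y)
  if (!is.null(sim_keys)) {
    ok <- c("seed", "n_background", "reference_length")
    bad <- setdiff(names(sim_keys), ok)
    if (length(bad)) {
      stop("configuration error: unknown simulation key ", bad[1])
    }
    sim_keys$seed <- sim_keys$seed %||% cfg$seed
    cfg$simulation <- do.call(default_simulation_config, sim_keys)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort POLE detection pipeline
#'
#' simulate -> filter -> profile -> extract -> match -> call -> stats, with
#' a fixed seed end to end. Re-running with the same config reproduces
#' identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, stage outputs
#'   (calls TSV, profiles TSV, W/H TSVs, similarity TSV, provenance JSON)
#'   are written there.
#' @param annotations Optional sample annotation data frame for
#'   [cohort_report()]; when `NULL`, a synthetic annotation table is built
#'   giving POLE-planted samples endometrioid histology and younger ages.
#' @param verbose Log per-stage counts with `message()`.
#' @return List of class `polesig_run`: `cohort`, `filter_reports`
#'   (per-sample removed counts), `kept_samples`, `profiles`, `fit`,
#'   `match`, `pole`, `calls`, `report`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         annotations = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  catalog <- synthetic_cosmic_catalog(seed = config$catalog_seed)
  reference <- generate_reference(config$simulation$reference_length,
                                  config$simulation$gc_content,
                                  seed = config$seed)
  say("simulating %d samples", config$simulation$n_samples)
  cohort <- simulate_cohort(config$simulation, catalog, reference)

  keep <- exclude_low_coverage_samples(cohort$capture_bases,
                                       min_positions = config$min_capture)
  say("capture filter kept %d / %d samples", length(keep$kept),
      length(cohort$capture_bases))
  variants <- cohort$variants[cohort$variants$sample_id %in% keep$kept, ,
                              drop = FALSE]
  fr <- filter_esnvs(variants, cohort$panel_of_normals,
                     q_min = config$q_min, depth_min = config$depth_min,
                     af_max = config$af_max)
  say("eSNV filter kept %d / %d variants", nrow(fr$kept), fr$n_input)

  profiles <- build_profiles(fr$kept, reference, sample_ids = keep$kept)
  fit <- nmf_factorize(profiles, rank = config$rank,
                       n_restarts = config$n_restarts,
                       max_iter = config$max_iter, tol = config$tol,
                       seed = config$seed)
  recon <- reconstruction_similarity(profiles, fit$W, fit$H)
  say("NMF objective %.3f, median reconstruction cosine %.3f",
      fit$objective, stats::median(recon[colSums(profiles) > 0]))
  # Sparse columns cannot be reconstructed well by any rank, so the
  # rank-adequacy warning only looks at well-populated samples.
  dense <- colSums(profiles) >= 30
  if (any(dense) && stats::median(recon[dense]) < 0.8) {
    warning("low reconstruction similarity; the chosen rank may be too small")
  }

  match <- match_to_catalog(fit$W, catalog)
  pole <- identify_pole_signature(match,
                                  min_similarity = config$min_similarity)
  calls <- call_samples(fit$H, cohort$capture_bases, pole, fr$kept,
                        cohort$hotspot_table, threshold = config$threshold)
  say("POLE-signature similarity %.3f; %d outliers called",
      pole$similarity, sum(calls$outlier))

  if (is.null(annotations)) {
    annotations <- synthetic_annotations(cohort, seed = config$seed)
  }
  report <- cohort_report(calls, annotations)

  run <- structure(list(
    cohort = cohort, filter_report = fr, kept_samples = keep$kept,
    profiles = profiles, fit = fit, reconstruction = recon, match = match,
    pole = pole, calls = calls, annotations = annotations, report = report,
    config = config
  ), class = "polesig_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Synthetic clinical annotations: planted POLE samples are endometrioid
# with early onset; background samples follow the cohort's histology mix.
synthetic_annotations <- function(cohort, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 7L)
  ids <- names(cohort$capture_bases)
  planted <- unique(cohort$manifest$spiked_hotspots$sample_id)
  hist_pool <- c("serous", "endometrioid", "clear cell", "undifferentiated",
                 "mucinous", "other")
  hist_prob <- c(114, 47, 14, 8, 3, 3) # endometrioid quota minus planted
  histology <- sample(hist_pool, length(ids), replace = TRUE,
                      prob = hist_prob)
  age <- round(stats::rnorm(length(ids), 62, 12))
  names(histology) <- names(age) <- ids
  histology[planted] <- "endometrioid"
  age[planted] <- round(stats::rnorm(length(planted), 48, 2))
  data.frame(sample_id = ids, age_years = as.numeric(age),
             histology = unname(histology), stringsAsFactors = FALSE)
}

#' Write pipeline outputs and provenance
#'
#' @param run A `polesig_run`.
#' @param out_dir Output directory.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_profiles(run$profiles, file.path(out_dir, "profiles.tsv"))
  write_profiles(run$fit$W, file.path(out_dir, "signatures.tsv"))
  utils::write.table(
    data.frame(signature = rownames(run$fit$H), run$fit$H,
               check.names = FALSE),
    file.path(out_dir, "contributions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(signature = rownames(run$match$similarity),
               run$match$similarity, check.names = FALSE),
    file.path(out_dir, "catalog_similarity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(
    package = "polesig",
    version = as.character(utils::packageVersion("polesig")),
    seed = run$config$seed,
    parameters = run$config[setdiff(names(run$config), "simulation")],
    n_samples = run$config$simulation$n_samples,
    n_kept_samples = length(run$kept_samples),
    n_variants_in = run$filter_report$n_input,
    n_variants_kept = nrow(run$filter_report$kept),
    removed_by_rule = as.list(run$filter_report$removed_by_rule),
    nmf_objective = run$fit$objective,
    pole_similarity = run$pole$similarity,
    n_outliers = sum(run$calls$outlier)
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
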