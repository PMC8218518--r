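#' Per-sample, per-signature tumor mutational burden
#'
#' Converts an NMF contribution matrix (mutation counts) into mut/Mb using
#' each sample's capture-region size.
#'
#' @param H K x N contribution matrix on the count scale.
#' @param capture_bases Named numeric vector of capture sizes (bases) for
#'   every column of `H`.
#' @return K x N matrix of mut/Mb.
#' @export
signature_tmb <- function(H, capture_bases) {
  ids <- colnames(H)
  if (is.null(ids)) stop("H must have sample column names")
  missing <- setdiff(ids, names(capture_bases))
  if (length(missing)) {
    stop("missing capture size for sample ", missing[1])
  }
  cb <- capture_bases[ids]
  if (any(cb <= 0)) stop("capture sizes must be positive")
  sweep(H, 2, cb, "/") * 1e6
}

#' Identify the extracted signature corresponding to the POLE process
#'
#' Picks the extracted signature with the highest cosine similarity to the
#' catalog's POLE signature (COSMIC signature 10), provided that similarity
#' reaches `min_similarity`; otherwise reports that no POLE-like signature
#' was extracted (the pipeline then makes zero calls).
#'
#' @param match_result A `signature_match` from [match_to_catalog()],
#'   computed against a catalog containing `pole_name`.
#' @param min_similarity Minimum similarity to accept (default 0.8).
#' @param pole_name Catalog column for the POLE signature
#'   (default `"COSMIC_10"`).
#' @return List: `found` (logical), `index`, `name`, `similarity`. Ties go
#'   to the lower index (a message notes the tie).
#' @export
identify_pole_signature <- function(match_result, min_similarity = 0.8,
                                    pole_name = "COSMIC_10") {
  sim <- match_result$similarity
  if (!(pole_name %in% colnames(sim))) {
    stop("configuration error: catalog lacks ", pole_name)
  }
  s <- sim[, pole_name]
  best <- max(s)
  if (best < min_similarity) {
    return(list(found = FALSE, index = NA_integer_, name = NA_character_,
                similarity = best))
  }
  idx <- which(s == best)
  if (length(idx) > 1) {
    message("tie for best POLE-signature match; keeping the lower index")
  }
  idx <- idx[1]
  list(found = TRUE, index = unname(idx), name = rownames(sim)[idx],
       similarity = unname(best))
}

#' Tukey-fence outlier calling on per-sample burdens
#'
#' The threshold is the boxplot upper whisker `Q3 + 1.5 * IQR`, with
#' quartiles computed by linear interpolation; samples strictly above it
#' are flagged. Hypermutation is one-sided, so only the upper fence
#' triggers calls; the lower fence is reported for information.
#'
#' @param values Named numeric vector of per-sample mut/Mb (n >= 4).
#' @param threshold Optional fixed override (e.g. 5 mut/Mb); when given,
#'   the fence is not computed from the data.
#' @return List: `threshold`, `outlier` (named logical), `lower_fence`,
#'   `q1`, `q3`.
#' @export
#' @examples
#' call_outliers(c(a = 1, b = 2, c = 3, d = 4, e = 100))
call_outliers <- function(values, threshold = NULL) {
  if (length(values) < 4) {
    stop("insufficient data: outlier calling needs at least 4 samples")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  upper <- if (is.null(threshold)) q[2] + 1.5 * iqr else threshold
  list(threshold = upper, outlier = values > upper,
       lower_fence = q[1] - 1.5 * iqr, q1 = q[1], q3 = q[2])
}

#' Report POLE hotspot hits among filter-passing variants
#'
#' Exact (chrom, pos, ref, alt) matches against the hotspot table,
#' reported per sample.
#'
#' @param variants Filter-passing variant data frame.
#' @param hotspots Hotspot table (`gene`, `protein_change`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param sample_ids Samples to report on (defaults to those present).
#' @return Named list: per sample, a data frame of hits
#'   (protein_change, chrom, pos, ref, alt); empty data frames when none.
#' @export
check_hotspots <- function(variants, hotspots,
                           sample_ids = unique(variants$sample_id)) {
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  hkey <- paste(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt)
  m <- match(key, hkey)
  hit <- !is.na(m)
  out <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
  for (id in sample_ids) {
    i <- hit & variants$sample_id == id
    df <- data.frame(
      protein_change = hotspots$protein_change[m[i]],
      chrom = variants$chrom[i], pos = variants$pos[i],
      ref = variants$ref[i], alt = variants$alt[i],
      stringsAsFactors = FALSE
    )
    out[[id]] <- unique(df)
  }
  out
}

#' Assemble per-sample POLE calls
#'
#' Combines POLE-signature TMB attribution, Tukey-fence outlier calling and
#' hotspot confirmation into one call table.
#'
#' @param H Contribution matrix from [nmf_factorize()].
#' @param capture_bases Named capture sizes.
#' @param pole Result of [identify_pole_signature()].
#' @param variants Filter-passing variants (for hotspot confirmation).
#' @param hotspots Hotspot table.
#' @param threshold Optional fixed mut/Mb threshold overriding the fence.
#' @return Data frame of class `pole_calls`: `sample_id`, `pole_signature`,
#'   `pole_tmb`, `threshold`, `outlier`, `n_hotspots`, `hotspot_labels`;
#'   attribute `hotspot_hits` holds the per-sample hit tables.
#' @export
call_samples <- function(H, capture_bases, pole, variants, hotspots,
                         threshold = NULL) {
  ids <- colnames(H)
  if (!isTRUE(pole$found)) {
    out <- data.frame(sample_id = ids, pole_signature = NA_character_,
                      pole_tmb = NA_real_, threshold = NA_real_,
                      outlier = FALSE, n_hotspots = 0L,
                      hotspot_labels = "", stringsAsFactors = FALSE)
    attr(out, "hotspot_hits") <- check_hotspots(variants, hotspots, ids)
    class(out) <- c("pole_calls", class(out))
    return(out)
  }
  tmb <- signature_tmb(H, capture_bases)[pole$index, ]
  oc <- call_outliers(tmb, threshold = threshold)
  hits <- check_hotspots(variants, hotspots, ids)
  out <- data.frame(
    sample_id = ids, pole_signature = pole$name, pole_tmb = unname(tmb),
    threshold = oc$threshold, outlier = unname(oc$outlier),
    n_hotspots = vapply(hits[ids], nrow, integer(1)),
    hotspot_labels = vapply(hits[ids], function(h) {
      paste(h$protein_change, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "hotspot_hits") <- hits
  class(out) <- c("pole_calls", class(out))
  out
}
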