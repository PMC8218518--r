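#' Compute a sample's capture region from per-base coverage
#'
#' The capture region is the set of positions sequenced at or above
#' `min_depth` (20x by default); its size in bases is the denominator of
#' tumor mutational burden.
#'
#' @param coverage Data frame with columns `chrom`, `pos`, `depth` (one row
#'   per covered base), e.g. from [read_coverage()].
#' @param min_depth Minimum depth for a position to count (default 20,
#'   inclusive).
#' @param sample_id Optional sample label carried in the result.
#' @return Object of class `capture_region`: list with `sample_id`,
#'   `positions` (data frame chrom/pos) and `size` (integer bases).
#' @export
compute_capture_region <- function(coverage, min_depth = 20,
                                   sample_id = NA_character_) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(coverage)))
  depth <- coverage$depth
  if (any(is.na(depth)) || any(depth < 0)) {
    stop("malformed coverage: depths must be nonnegative numbers")
  }
  keep <- depth >= min_depth
  ch <- coverage$chrom[keep]
  po <- coverage$pos[keep]
  # duplicated() on the integer positions alone is much faster and is
  # correct whenever there is a single chromosome (the common case here)
  dup <- if (length(unique(ch)) <= 1L) duplicated(po) else
    duplicated(paste(ch, po))
  pos <- data.frame(chrom = ch[!dup], pos = po[!dup],
                    stringsAsFactors = FALSE)
  capture_region(sample_id, size = nrow(pos), positions = pos)
}

#' Construct a capture region directly from its size
#'
#' Used when the position set is implicit (e.g. a contiguous block in a
#' simulation) and only the base count matters for TMB.
#'
#' @param sample_id Sample label.
#' @param size Number of bases with sufficient coverage.
#' @param positions Optional data frame chrom/pos backing `size`.
#' @export
capture_region <- function(sample_id, size, positions = NULL) {
  size <- as.integer(size)
  stopifnot(length(size) == 1, size >= 0)
  if (!is.null(positions) && nrow(positions) != size) {
    stop("capture region size must equal the number of positions")
  }
  structure(list(sample_id = sample_id, positions = positions, size = size),
            class = "capture_region")
}

#' Exclude samples with too small a capture region
#'
#' Samples whose capture region holds fewer than `min_positions` bases
#' (default five million at 20x) are excluded from the analysis.
#'
#' @param regions List of `capture_region` objects (one per sample) or a
#'   named numeric vector of capture sizes.
#' @param min_positions Minimum capture size in bases (default 5e6);
#'   exclusion is strict: a sample is dropped iff `size < min_positions`.
#' @return List with character vectors `kept` and `excluded`.
#' @export
exclude_low_coverage_samples <- function(regions, min_positions = 5e6) {
  if (is.list(regions) && length(regions) &&
      inherits(regions[[1]], "capture_region")) {
    sizes <- vapply(regions, `[[`, numeric(1), "size")
    names(sizes) <- vapply(regions, function(r) as.character(r$sample_id),
                           character(1))
  } else {
    sizes <- unlist(regions)
    sizes <- if (is.null(sizes)) numeric(0) else sizes
  }
  if (!length(sizes)) {
    return(list(kept = character(0), excluded = character(0)))
  }
  if (is.null(names(sizes))) stop("capture sizes must be named by sample")
  keep <- sizes >= min_positions
  list(kept = names(sizes)[keep], excluded = names(sizes)[!keep])
}

.FILTER_RULES <- c("low_quality", "low_depth", "common_population",
                   "pon_recurrent")

#' Filter expressed SNVs by quality, depth, population AF and panel of normals
#'
#' A variant is kept iff its quality score exceeds `q_min` (strict), its
#' read depth exceeds `depth_min` (strict), its population allele frequency
#' is either unobserved or below `af_max` (strict), and its site/allele is
#' absent from the panel of normals. Removed variants are attributed to the
#' first failing rule, in the order quality, depth, population AF, panel of
#' normals.
#'
#' @param variants Data frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `quality_score`, `depth`, `population_af` (`NA` allowed =
#'   not observed in the population reference).
#' @param panel_of_normals Data frame of recurrent artifact sites with
#'   columns `chrom`, `pos`, `ref`, `alt`, or `NULL`.
#' @param q_min Quality-score threshold (default 0.10).
#' @param depth_min Read-depth threshold (default 10).
#' @param af_max Population allele-frequency ceiling (default 0.02).
#' @return Object of class `filter_report`: `kept` (data frame),
#'   `removed_by_rule` (named integer vector over the four rules),
#'   `n_input`.
#' @export
filter_esnvs <- function(variants, panel_of_normals = NULL,
                         q_min = 0.10, depth_min = 10, af_max = 0.02) {
  stopifnot(q_min >= 0, q_min <= 1, depth_min >= 0, af_max >= 0, af_max <= 1)
  n <- nrow(variants)
  removed <- stats::setNames(integer(length(.FILTER_RULES)), .FILTER_RULES)
  if (n == 0) {
    return(structure(list(kept = variants, removed_by_rule = removed,
                          n_input = 0L), class = "filter_report"))
  }
  fail_q <- !(variants$quality_score > q_min)
  fail_d <- !(variants$depth > depth_min)
  af <- variants$population_af
  fail_af <- !is.na(af) & !(af < af_max)
  in_pon <- rep(FALSE, n)
  if (!is.null(panel_of_normals) && nrow(panel_of_normals) > 0) {
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    pon_key <- paste(panel_of_normals$chrom, panel_of_normals$pos,
                     panel_of_normals$ref, panel_of_normals$alt)
    in_pon <- key %in% pon_key
  }
  rule <- rep(NA_character_, n)
  rule[in_pon] <- "pon_recurrent"
  rule[fail_af] <- "common_population"
  rule[fail_d] <- "low_depth"
  rule[fail_q] <- "low_quality"
  drop <- !is.na(rule)
  tab <- table(factor(rule[drop], levels = .FILTER_RULES))
  removed[] <- as.integer(tab)
  structure(list(kept = variants[!drop, , drop = FALSE],
                 removed_by_rule = removed, n_input = n),
            class = "filter_report")
}

#' Tumor mutational burden in mutations per megabase
#'
#' @param n_variants Number of filter-passing expressed variants.
#' @param capture_bases Capture-region size in bases (> 0).
#' @return `n_variants / capture_bases * 1e6`.
#' @export
#' @examples
#' compute_tmb(50, 1e7) # 5
compute_tmb <- function(n_variants, capture_bases) {
  if (any(capture_bases <= 0)) {
    stop("TMB undefined for capture size 0 (sample should have been excluded)")
  }
  n_variants / capture_bases * 1e6
}

#' Build a panel of normals from per-normal variant calls
#'
#' A site/allele is a recurrent artifact when it appears in at least
#' `min_recurrence` distinct normals (default 2, the minimal reading of
#' "recurrent").
#'
#' @param normal_variants Data frame with columns `normal_id`, `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param min_recurrence Minimum number of distinct normals (default 2).
#' @return Data frame `chrom`, `pos`, `ref`, `alt` of recurrent sites.
#' @export
build_panel_of_normals <- function(normal_variants, min_recurrence = 2) {
  if (nrow(normal_variants) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  u <- unique(normal_variants[, c("normal_id", "chrom", "pos", "ref", "alt")])
  key <- paste(u$chrom, u$pos, u$ref, u$alt, sep = "\r")
  tab <- table(key)
  rec <- names(tab)[tab >= min_recurrence]
  out <- unique(u[key %in% rec, c("chrom", "pos", "ref", "alt")])
  rownames(out) <- NULL
  out
}
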