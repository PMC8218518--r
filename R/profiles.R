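#' Build the 96 x N mutational profile matrix from filtered variants
#'
#' Each variant is assigned to one of the 96 substitution-in-trinucleotide-
#' context channels by looking up its flanking bases in the reference and
#' collapsing to the pyrimidine strand. Variants at the first or last base of
#' a sequence (no flank) or with non-ACGT context are skipped and tallied,
#' never guessed.
#'
#' @param variants Data frame with columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param reference Named character vector of sequences (names = chromosome
#'   names), a `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param sample_ids Optional character vector fixing the column set and
#'   order; defaults to the samples present in `variants`. Samples with no
#'   variants get all-zero columns.
#' @return Integer matrix 96 x N with `rownames = channel_labels()` and
#'   `colnames = sample_ids`; attribute `skipped` holds the per-sample count
#'   of ambiguous-context variants.
#' @export
build_profiles <- function(variants, reference, sample_ids = NULL) {
  reference <- as_reference(reference)
  if (is.null(sample_ids)) {
    sample_ids <- unique(as.character(variants$sample_id))
  }
  labels <- channel_labels()
  counts <- matrix(0L, nrow = 96, ncol = length(sample_ids),
                   dimnames = list(labels, sample_ids))
  skipped <- stats::setNames(integer(length(sample_ids)), sample_ids)
  if (nrow(variants) == 0) {
    attr(counts, "skipped") <- skipped
    return(counts)
  }
  chrom <- as.character(variants$chrom)
  bad_chrom <- !(chrom %in% names(reference))
  if (any(bad_chrom)) {
    stop("variant on unknown sequence: ", chrom[which(bad_chrom)[1]])
  }
  pos <- as.integer(variants$pos)
  seqlen <- nchar(reference)[chrom]
  edge <- pos <= 1L | pos >= seqlen
  ctx <- rep(NA_character_, length(pos))
  ctx[!edge] <- substr_by_chrom(reference, chrom[!edge], pos[!edge])
  ref_at <- ifelse(edge,
                   substr_by_chrom(reference, chrom, pos, width = 1L),
                   substr(ctx, 2, 2))
  mismatch <- ref_at != as.character(variants$ref)
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop(sprintf(
      "reference mismatch for %s %s:%d (VCF ref %s, reference has %s)",
      variants$sample_id[i], chrom[i], pos[i], variants$ref[i], ref_at[i]))
  }
  idx <- channel_index(ctx, as.character(variants$ref),
                       as.character(variants$alt))
  skip <- is.na(idx)
  sid <- factor(as.character(variants$sample_id), levels = sample_ids)
  if (any(skip)) {
    tab <- table(sid[skip])
    skipped[names(tab)] <- skipped[names(tab)] + as.integer(tab)
  }
  if (any(!skip)) {
    tab <- table(factor(idx[!skip], levels = 0:95), sid[!skip])
    counts <- counts + matrix(as.integer(tab), nrow = 96,
                              dimnames = dimnames(counts))
  }
  attr(counts, "skipped") <- skipped
  counts
}

#' Convert counts to per-sample proportions
#'
#' @param counts 96 x N count matrix.
#' @return Matrix of column-normalized proportions; all-zero columns stay 0.
#' @export
profile_proportions <- function(counts) {
  cs <- colSums(counts)
  cs[cs == 0] <- 1
  sweep(counts, 2, cs, "/")
}

# Coerce a FASTA path / DNAStringSet / named character to named character.
as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    return(stats::setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    nm <- sub("\\s.*$", "", names(ss))
    return(stats::setNames(as.character(ss), nm))
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  stop("reference must be a named character vector, DNAStringSet or FASTA path")
}

substr_by_chrom <- function(reference, chrom, pos, width = 3L) {
  off <- if (width == 3L) 1L else 0L
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    out[i] <- substring(reference[[cn]], pos[i] - off, pos[i] - off + width - 1L)
  }
  out
}

#' Write / read a profile matrix as TSV
#'
#' First column `channel` carries the 96 labels; remaining columns are
#' samples.
#'
#' @param counts 96 x N matrix.
#' @param path Output TSV path.
#' @export
write_profiles <- function(counts, path) {
  df <- data.frame(channel = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  if (!identical(rownames(m), channel_labels())) {
    stop("profile TSV channels are not in the standard order")
  }
  m
}
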