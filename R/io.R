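#' Write a reference sequence to FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path FASTA path.
#' @export
read_reference_fasta <- function(path) {
  as_reference(path)
}

#' Write variant records as a VCF v4.2 file
#'
#' Annotations are encoded as INFO keys `QS` (variant quality score in
#' `[0,1]`), `DP` (read depth) and `AF1KG` (population allele frequency;
#' omitted when unobserved).
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `quality_score`, `depth`, `population_af`.
#' @param path Output path.
#' @param sample_id Label recorded in the header.
#' @export
write_vcf <- function(variants, path, sample_id = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polesig",
    sprintf("##polesig_sample=%s", sample_id),
    "##INFO=<ID=QS,Number=1,Type=Float,Description=\"Variant quality score\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF1KG,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(variants) > 0) {
    v <- variants[order(variants$chrom, variants$pos, variants$alt), ,
                  drop = FALSE]
    info <- sprintf("QS=%.4f;DP=%d", v$quality_score, as.integer(v$depth))
    has_af <- !is.na(v$population_af)
    info[has_af] <- sprintf("%s;AF1KG=%.6f", info[has_af],
                            v$population_af[has_af])
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                    v$chrom, as.integer(v$pos), v$ref, v$alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into the package's variant data frame
#'
#' Parses INFO annotations (key names configurable) and splits multi-allelic
#' rows into biallelic records. Non-SNV alleles (length != 1 or non-ACGT)
#' are dropped.
#'
#' @param path VCF path.
#' @param sample_id Sample label to attach; defaults to the
#'   `##polesig_sample` header when present, else the file name.
#' @param qs_key,dp_key,af_key INFO key names for quality score, depth and
#'   population allele frequency.
#' @return Data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `quality_score`, `depth`, `population_af`.
#' @export
read_vcf <- function(path, sample_id = NULL, qs_key = "QS", dp_key = "DP",
                     af_key = "AF1KG") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(sample_id)) {
    meta <- grep("^##polesig_sample=", vcf@meta, value = TRUE)
    sample_id <- if (length(meta)) sub("^##polesig_sample=", "", meta[1]) else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0) {
    return(empty_variants())
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  qs <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, qs_key)))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, dp_key)))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, af_key)))
  out <- data.frame(
    sample_id = sample_id, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, quality_score = qs, depth = dp,
    population_af = af, stringsAsFactors = FALSE
  )
  # Split multi-allelic rows into one record per alternate allele.
  multi <- grepl(",", out$alt, fixed = TRUE)
  if (any(multi)) {
    alts <- strsplit(out$alt, ",", fixed = TRUE)
    out <- out[rep(seq_len(nrow(out)), lengths(alts)), , drop = FALSE]
    out$alt <- unlist(alts)
  }
  snv <- nchar(out$ref) == 1 & nchar(out$alt) == 1 &
    out$ref %in% .BASES & out$alt %in% .BASES
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_variants <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             quality_score = numeric(0), depth = integer(0),
             population_af = numeric(0), stringsAsFactors = FALSE)
}

#' Write / read per-base coverage as a 3-column TSV
#'
#' Columns `chrom`, `pos` (1-based), `depth`, dense over covered positions.
#'
#' @param coverage Data frame chrom/pos/depth.
#' @param path TSV path.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage[, c("chrom", "pos", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  cov <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "integer"))
  names(cov) <- c("chrom", "pos", "depth")
  bad <- which(is.na(cov$pos) | is.na(cov$depth) | cov$depth < 0)
  if (length(bad)) {
    stop(sprintf("malformed coverage row at line %d of %s", bad[1] + 1L, path))
  }
  cov
}

#' Read / write a hotspot table TSV
#'
#' Columns: `gene`, `protein_change`, `chrom`, `pos`, `ref`, `alt`.
#'
#' @param hotspots Hotspot data frame.
#' @param path TSV path.
#' @export
write_hotspots <- function(hotspots, path) {
  utils::write.table(hotspots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hotspots
#' @export
read_hotspots <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
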