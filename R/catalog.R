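#' Synthetic COSMIC-v2-like reference signature catalog
#'
#' Builds a deterministic 96 x 30 catalog standing in for the COSMIC v2
#' signature matrix, which cannot be redistributed here. It is synthetic:
#' only the columns that matter for POLE detection are modeled on the
#' published signature shapes, the rest are sparse random distributions.
#'
#' * `COSMIC_10` (POLE exonuclease deficiency): dominated by T\[C>A\]T and
#'   T\[C>T\]G, with minor mass on the remaining C>A / C>T channels.
#' * `COSMIC_1` (aging): C>T at NpCpG contexts.
#' * `COSMIC_5` (flat, clock-like): near-uniform.
#' * All other columns: Dirichlet-like sparse draws, fixed by `seed`.
#'
#' @param n_signatures Number of catalog columns (default 30).
#' @param seed Seed fixing the random columns (default 2021).
#' @return 96 x `n_signatures` matrix, columns summing to 1, rownames
#'   `channel_labels()`, colnames `COSMIC_1` ... .
#' @export
synthetic_cosmic_catalog <- function(n_signatures = 30, seed = 2021) {
  stopifnot(n_signatures >= 1)
  labels <- channel_labels()
  cat <- matrix(0, nrow = 96, ncol = n_signatures,
                dimnames = list(labels,
                                paste0("COSMIC_", seq_len(n_signatures))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (j in seq_len(n_signatures)) {
    g <- stats::rgamma(96, shape = 0.08)
    cat[, j] <- g / sum(g)
  }
  # Aging: C>T at CpG (x[C>T]G channels).
  if (n_signatures >= 1) {
    v <- rep(0.002, 96)
    v[labels %in% paste0(.BASES, "[C>T]G")] <- c(0.22, 0.18, 0.14, 0.20)
    cat[, 1] <- v / sum(v)
  }
  # Flat clock-like signature.
  if (n_signatures >= 5) {
    v <- 1 + 0.3 * sin(seq_len(96) / 7)
    cat[, 5] <- v / sum(v)
  }
  # POLE: sharp T[C>A]T and T[C>T]G peaks.
  if (n_signatures >= 10) {
    v <- rep(0.0008, 96)
    v[labels == "T[C>A]T"] <- 0.42
    v[labels == "T[C>T]G"] <- 0.26
    v[labels == "T[C>A]G"] <- 0.04
    v[labels == "C[C>A]T"] <- 0.03
    v[labels == "T[T>G]T"] <- 0.05
    cat[, 10] <- v / sum(v)
  }
  cat
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read / write a signature catalog TSV
#'
#' Format: header row of signature names; first column `channel` with the 96
#' labels in standard order.
#'
#' @param catalog 96 x M matrix with column names.
#' @param path TSV path.
#' @export
write_catalog <- function(catalog, path) {
  write_profiles(catalog, path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  m <- read_profiles(path)
  validate_catalog(m)
  m
}

validate_catalog <- function(catalog) {
  stopifnot(is.matrix(catalog), nrow(catalog) == 96, ncol(catalog) >= 1)
  if (!identical(rownames(catalog), channel_labels())) {
    stop("catalog channel labels are misaligned with the standard order")
  }
  cs <- colSums(catalog)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("catalog columns must sum to 1 (tolerance 1e-6)")
  }
  if (any(catalog < 0)) stop("catalog entries must be nonnegative")
  invisible(catalog)
}
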