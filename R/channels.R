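.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 substitution-in-context channel labels
#'
#' Channels follow the standard catalog row order: substitution blocks
#' C>A, C>G, C>T, T>A, T>C, T>G; within each block the 5' flanking base
#' varies first (A, C, G, T), then the 3' flanking base (A, C, G, T).
#' Labels look like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' channel_labels()[c(1, 36, 96)]
channel_labels <- function() {
  out <- character(96)
  i <- 1L
  for (s in .SUBS) {
    for (f5 in .BASES) {
      for (f3 in .BASES) {
        out[i] <- paste0(f5, "[", s, "]", f3)
        i <- i + 1L
      }
    }
  }
  out
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Map a substitution in its trinucleotide context to a channel index
#'
#' Purine-reference substitutions are reverse-complemented first so that
#' every substitution is expressed on the pyrimidine strand
#' (pyrimidine-strand collapse); the resulting 6 substitution classes x 16
#' contexts give the 96 channels of [channel_labels()].
#'
#' @param context 3-base string centered on the reference base.
#' @param ref Reference base (the middle base of `context`).
#' @param alt Alternate base, different from `ref`.
#' @return 0-based integer channel index in `[0, 95]`, or `NA_integer_` when
#'   the context is ambiguous (wrong length or non-ACGT characters); callers
#'   treat `NA` as a skip signal.
#' @export
#' @examples
#' channel_index("ACA", "C", "A") # 0  -> "A[C>A]A"
#' channel_index("AGT", "G", "A") # 35 -> "A[C>T]T" via strand collapse
channel_index <- function(context, ref, alt) {
  n <- length(context)
  stopifnot(length(ref) == n, length(alt) == n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(context) & nchar(context) == 3L &
    !grepl("[^ACGT]", context) & ref %in% .BASES & alt %in% .BASES &
    ref != alt
  if (!any(ok)) return(out)
  ctx <- context[ok]
  r <- ref[ok]
  a <- alt[ok]
  if (any(substr(ctx, 2, 2) != r)) {
    stop("context middle base must equal `ref`")
  }
  purine <- r %in% c("A", "G")
  if (any(purine)) {
    ctx[purine] <- revcomp(ctx[purine])
    r[purine] <- unname(.COMP[r[purine]])
    a[purine] <- unname(.COMP[a[purine]])
  }
  block <- match(paste0(r, ">", a), .SUBS) - 1L
  f5 <- match(substr(ctx, 1, 1), .BASES) - 1L
  f3 <- match(substr(ctx, 3, 3), .BASES) - 1L
  out[ok] <- 16L * block + 4L * f5 + f3
  out
}
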