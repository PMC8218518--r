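#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The U statistic comes from rank sums with midranks for ties. The p-value
#' is exact by enumeration of all labelings when the pooled sample size is
#' at most `exact_max` and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact_max Pooled-size cutoff for the exact path (default 12).
#' @return List: `U` (for `x`), `p` in (0, 1], `method` ("exact" or
#'   "normal_approximation").
#' @export
#' @examples
#' mann_whitney_two_sided(c(1, 2), c(3, 4)) # U = 0, p = 1/3
mann_whitney_two_sided <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be nonempty")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- nx * ny / 2
  if (n <= exact_max && !ties) {
    # Enumerate all C(n, nx) assignments of ranks to group x.
    combs <- utils::combn(n, nx)
    ranks <- seq_len(n)
    Us <- colSums(matrix(ranks[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- z - sign(z) * 0.5 # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "normal_approximation"
  }
  list(U = U, p = max(p, .Machine$double.xmin), method = method)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins; the two-sided p-value sums the probabilities of all
#' tables whose point probability does not exceed that of the observed
#' table (with a `1 + 1e-7` relative slack, the minimum-likelihood rule).
#'
#' @param t 2x2 matrix or length-4 vector `(a, b, c, d)` of nonnegative
#'   counts, read row-wise.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/3
fisher_exact_two_sided <- function(t) {
  t <- as.vector(t(as.matrix(t)))
  if (length(t) != 4 || any(t < 0) || any(t != round(t))) {
    stop("need a 2x2 table of nonnegative integer counts")
  }
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  n <- a + b + c + d
  if (n < 1) stop("table total must be >= 1")
  m1 <- a + b       # row-1 margin
  k <- a + c        # column-1 margin
  lo <- max(0, k - (c + d))
  hi <- min(k, m1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m1, c + d, k)
  pobs <- stats::dhyper(a, m1, c + d, k)
  p <- sum(probs[probs <= pobs * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Mean, median and quartiles of a group
#'
#' Median and quartiles use linear interpolation (quantile type 7).
#'
#' @param values Nonempty numeric vector.
#' @return List: `mean`, `median`, `q1`, `q3`, `n`.
#' @export
#' @examples
#' summarize_group(c(46, 49, 49, 46, 49, 51))$mean # 48.33
summarize_group <- function(values) {
  if (length(values) == 0) stop("empty group")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(mean = mean(values), median = q[2], q1 = q[1], q3 = q[3],
       n = length(values))
}

#' Cohort-level comparison of POLE and non-POLE samples
#'
#' Given the call table and a sample annotation table, compares age at
#' onset between POLE-called and other samples (two-sided Mann-Whitney)
#' and tests association between POLE status and histology (two-sided
#' Fisher exact on POLE x endometrioid-vs-other).
#'
#' @param calls `pole_calls` data frame from [call_samples()].
#' @param annotations Data frame: `sample_id`, `age_years`, `histology`
#'   (plus free columns such as stage/grade).
#' @param histology_of_interest Histology level contrasted against the rest
#'   (default `"endometrioid"`, case-insensitive).
#' @return List: `age` (group summaries + test), `histology` (2x2 table +
#'   p), `n_pole`, `pole_frequency` (fraction of POLE calls among samples
#'   of the histology of interest).
#' @export
cohort_report <- function(calls, annotations,
                          histology_of_interest = "endometrioid") {
  ann <- merge(calls, annotations, by = "sample_id")
  pole <- ann$outlier
  hist_hit <- tolower(ann$histology) == tolower(histology_of_interest)
  age <- NULL
  if ("age_years" %in% names(ann) && any(pole) && any(!pole)) {
    age <- list(
      pole = summarize_group(ann$age_years[pole]),
      other = summarize_group(ann$age_years[!pole]),
      test = mann_whitney_two_sided(ann$age_years[pole],
                                    ann$age_years[!pole])
    )
  }
  tab <- matrix(c(sum(pole & hist_hit), sum(pole & !hist_hit),
                  sum(!pole & hist_hit), sum(!pole & !hist_hit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("POLE", "non-POLE"),
                                c(histology_of_interest, "other")))
  list(age = age,
       histology = list(table = tab, p = fisher_exact_two_sided(tab)),
       n_pole = sum(pole),
       pole_frequency = if (any(hist_hit)) {
         sum(pole & hist_hit) / sum(hist_hit)
       } else NA_real_)
}
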