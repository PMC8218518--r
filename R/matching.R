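#' Cosine similarity between two nonnegative profile vectors
#'
#' `a . b / (||a|| ||b||)`; for nonnegative inputs the value lies in
#' `[0, 1]` (1 = identical shape, 0 = disjoint support).
#'
#' @param a,b Numeric vectors of equal length, nonnegative, each with at
#'   least one nonzero entry.
#' @return Scalar similarity in `[0, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0)) # 1/sqrt(2)
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("cosine similarity requires nonnegative vectors")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  min(1, sum(a * b) / (na * nb))
}

# Column-wise cosine similarity matrix, zero columns allowed (give 0 rows).
cosine_matrix <- function(A, B) {
  an <- sqrt(colSums(A^2)); bn <- sqrt(colSums(B^2))
  m <- crossprod(A, B)
  denom <- outer(an, bn)
  out <- ifelse(denom > 0, m / denom, 0)
  out <- pmin(out, 1)
  dimnames(out) <- list(colnames(A), colnames(B))
  out
}

#' Match extracted signatures to a reference catalog
#'
#' Computes the full K x M cosine-similarity matrix between extracted
#' signature columns and catalog columns, and reports each extracted
#' signature's best catalog match (ties broken by catalog order).
#'
#' @param W 96 x K matrix of extracted signatures (columns).
#' @param catalog 96 x M reference catalog, channel order aligned with `W`.
#' @return List of class `signature_match`: `similarity` (K x M),
#'   `best_match` (data frame: signature, match, similarity),
#'   `catalog_order` (names permuted by [cluster_catalog()] when M >= 2).
#' @export
match_to_catalog <- function(W, catalog) {
  validate_catalog(catalog)
  if (!is.null(rownames(W)) &&
      !identical(rownames(W), rownames(catalog))) {
    stop("channel labels of W and catalog are misaligned")
  }
  if (nrow(W) != 96) stop("W must have 96 rows")
  sim <- cosine_matrix(W, catalog)
  if (is.null(colnames(W))) {
    colnames(W) <- paste0("signature_", seq_len(ncol(W)))
  }
  rownames(sim) <- colnames(W)
  colnames(sim) <- colnames(catalog)
  best <- apply(sim, 1, which.max)
  bm <- data.frame(
    signature = colnames(W),
    match = colnames(catalog)[best],
    similarity = sim[cbind(seq_len(nrow(sim)), best)],
    stringsAsFactors = FALSE
  )
  ord <- if (ncol(catalog) >= 2) cluster_catalog(catalog)$order_names
         else colnames(catalog)
  structure(list(similarity = sim, best_match = bm, catalog_order = ord),
            class = "signature_match")
}

#' Order a catalog by average-linkage clustering of cosine distances
#'
#' Agglomerative clustering with average linkage on the distance
#' `1 - cosine similarity`, as used to group reference signatures in
#' similarity heatmaps.
#'
#' @param catalog 96 x M matrix (M >= 2 for a real tree; M < 2 returns a
#'   trivial ordering).
#' @return List: `hclust` (the merge tree, `NULL` when trivial), `order`
#'   (integer leaf order), `order_names`, `heights`.
#' @export
cluster_catalog <- function(catalog) {
  M <- ncol(catalog)
  if (M < 2) {
    return(list(hclust = NULL, order = seq_len(M),
                order_names = colnames(catalog), heights = numeric(0)))
  }
  d <- stats::as.dist(1 - cosine_matrix(catalog, catalog))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order,
       order_names = colnames(catalog)[hc$order], heights = hc$height)
}
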