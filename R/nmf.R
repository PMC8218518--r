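#' De novo signature extraction by KL-divergence NMF
#'
#' Factorizes a 96 x N nonnegative count matrix `V ~ W H` by minimizing the
#' generalized Kullback-Leibler divergence
#' `D(V || WH) = sum(V log(V / WH) - V + WH)` with Lee-Seung multiplicative
#' updates. Several random restarts are run and the factorization with the
#' lowest final divergence is kept (ties go to the lowest restart index).
#' On return `W` columns are normalized to sum to 1, with the scale absorbed
#' into `H`, so `H` stays on the mutation-count scale.
#'
#' All-zero sample columns carry no information for the factorization; they
#' are dropped before fitting and reported in `dropped_samples`, and their
#' contributions are zero by definition.
#'
#' @param V 96 x N nonnegative matrix (counts), at least one nonzero column.
#' @param rank Number of signatures K (default 4).
#' @param n_restarts Random restarts (default 30).
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative objective decrease below which a restart stops.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @return Object of class `nmf_fit`: `W` (96 x K, columns sum to 1), `H`
#'   (K x N, counts; zero columns reinserted for dropped samples),
#'   `objective` (final divergence), `objective_trace` (per-iteration
#'   divergence of the winning restart), `best_restart_seed`,
#'   `dropped_samples`.
#' @export
nmf_factorize <- function(V, rank = 4, n_restarts = 30, max_iter = 2000,
                          tol = 1e-6, seed = 1) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  if (all(V == 0)) stop("degenerate input: V is all zero")
  if (rank < 1) stop("rank must be >= 1")
  keep <- colSums(V) > 0
  dropped <- colnames(V)[!keep]
  Vf <- V[, keep, drop = FALSE]
  if (rank > min(nrow(Vf), ncol(Vf))) {
    stop("rank exceeds matrix dimensions after dropping zero columns")
  }
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- kl_nmf_once(Vf, rank, max_iter, tol, seed + r - 1L, eps)
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$best_restart_seed <- seed + r - 1L
    }
  }
  W <- best$W
  H <- best$H
  s <- colSums(W)
  W <- sweep(W, 2, s, "/")
  H <- H * s
  rownames(W) <- rownames(V)
  colnames(W) <- paste0("signature_", seq_len(rank))
  rownames(H) <- colnames(W)
  Hfull <- matrix(0, nrow = rank, ncol = ncol(V),
                  dimnames = list(rownames(H), colnames(V)))
  Hfull[, keep] <- H
  structure(list(W = W, H = Hfull, objective = best$objective,
                 objective_trace = best$trace,
                 best_restart_seed = best$best_restart_seed,
                 dropped_samples = dropped),
            class = "nmf_fit")
}

# One restart of Lee-Seung multiplicative updates for generalized KL.
kl_nmf_once <- function(V, K, max_iter, tol, seed, eps) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * K), n, K)
  H <- matrix(stats::runif(K * m), K, m)
  # Scale the initialization to the data magnitude.
  sc <- sqrt(mean(V) / max(mean(W %*% H), eps))
  W <- W * sc; H <- H * sc
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    R <- V / (WH + eps)
    H <- H * (crossprod(W, R)) / (colSums(W) + eps)
    WH <- W %*% H
    R <- V / (WH + eps)
    W <- W * (R %*% t(H)) / matrix(rowSums(H) + eps, n, K, byrow = TRUE)
    obj <- kl_divergence(V, W %*% H, eps)
    trace <- c(trace, obj)
    if (is.finite(prev) && (prev - obj) < tol * max(abs(prev), eps)) {
      break
    }
    prev <- obj
  }
  list(W = W, H = H, objective = trace[length(trace)], trace = trace)
}

kl_divergence <- function(V, WH, eps = 1e-12) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / (WH[pos] + eps))) - sum(V) + sum(WH)
}

#' Per-sample cosine similarity between data and reconstruction
#'
#' @param V 96 x N count matrix.
#' @param W,H Factor matrices as returned by [nmf_factorize()].
#' @return Numeric vector of per-sample cosines in `[0, 1]`; all-zero data
#'   columns get 0 with attribute `zero_columns` naming them.
#' @export
reconstruction_similarity <- function(V, W, H) {
  stopifnot(ncol(W) == nrow(H), nrow(V) == nrow(W), ncol(V) == ncol(H))
  WH <- W %*% H
  vn <- sqrt(colSums(V^2)); rn <- sqrt(colSums(WH^2))
  num <- colSums(V * WH)
  denom <- vn * rn
  out <- ifelse(denom > 0, pmin(1, num / denom), 0)
  names(out) <- colnames(V)
  zero <- colnames(V)[vn == 0]
  if (length(zero)) attr(out, "zero_columns") <- zero
  out
}

#' Match extracted signatures to known ones by optimal assignment
#'
#' Exhaustive assignment over permutations (K <= 8) maximizing total cosine
#' similarity, so recovery statements are permutation-invariant.
#'
#' @param W Extracted 96 x K matrix.
#' @param truth Known 96 x K matrix.
#' @return Data frame: `extracted`, `truth`, `cosine`, one row per pair.
#' @export
assign_signatures <- function(W, truth) {
  K <- ncol(W)
  stopifnot(ncol(truth) == K, K <= 8)
  sim <- cosine_matrix(W, truth)
  perms <- permutations_of(K)
  scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(K), p)]),
                   numeric(1))
  p <- perms[[which.max(scores)]]
  data.frame(
    extracted = if (is.null(colnames(W))) seq_len(K) else colnames(W),
    truth = if (is.null(colnames(truth))) p else colnames(truth)[p],
    cosine = sim[cbind(seq_len(K), p)],
    stringsAsFactors = FALSE
  )
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", 0)
  for (p in sub) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}
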