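#' Log-transform raw read counts
#'
#' Elementwise natural log of `count + 1`, so zero counts map to exactly 0
#' and the transform is defined for sparse targets.
#'
#' @param counts non-negative numeric matrix (targets x samples).
#' @return Matrix of the same shape.
#' @export
log_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (any(!is.finite(counts))) stop("counts must be finite")
  log1p(counts)
}

#' Median-center log depths per sample
#'
#' Subtracts, for every sample, the median of its log depths over all
#' targets. This absorbs library-size differences (a global scaling of a
#' sample's counts shifts all its log depths by a constant) and is what
#' makes single-sample prediction possible. The result is returned in the
#' samples x targets orientation used by all downstream linear algebra.
#'
#' @param P log-depth matrix, targets x samples (output of
#'   [log_transform()]).
#' @return p x n matrix: one row per sample, median-centered.
#' @export
median_center <- function(P) {
  P <- as.matrix(P)
  med <- apply(P, 2L, stats::median)
  t(P) - med
}

#' Fit the SVD normalization basis
#'
#' Per partition, takes the SVD of the centered p x n_q submatrix and keeps
#' the smallest number `k` of right singular vectors whose cumulative
#' squared-singular-value fraction reaches the variance threshold `v`
#' (k >= 1 whenever the partition is usable). These directions capture
#' correlated depth structure -- batch effects and common CNVs in the
#' background set -- and are later projected out of both training and query
#' samples.
#'
#' @param X centered matrix, samples x targets (output of
#'   [median_center()]); at least 2 samples.
#' @param v variance-explained threshold in (0, 1]; default 0.90.
#' @param partitions a [partition_targets()] assignment; default one
#'   partition.
#' @param method `"exact"` ([base::svd()]) or `"randomized"` (Halko-style
#'   sketched SVD; seeded).
#' @param seed integer seed for the randomized sketch.
#' @param oversample,power_iter randomized-SVD tuning parameters.
#' @return An object of class `normalization_basis`: per-partition list of
#'   `V` (k x n_q orthonormal rows), `k`, `singular_values`, plus the
#'   partition assignment and `v`.
#' @export
fit_basis <- function(X, v = 0.90, partitions = NULL,
                      method = c("exact", "randomized"), seed = NULL,
                      oversample = 10L, power_iter = 4L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- nrow(X); n <- ncol(X)
  if (p < 2L) stop("at least 2 background samples are required to fit a basis")
  if (!(v > 0 && v <= 1)) stop("v must be in (0, 1]")
  if (is.null(partitions)) partitions <- partition_targets(n, n)
  if (length(partitions$partition_of) != n)
    stop("partition assignment covers ", length(partitions$partition_of),
         " targets but X has ", n, " columns")

  per_part <- vector("list", partitions$num_partitions)
  for (q in seq_len(partitions$num_partitions)) {
    idx <- which(partitions$partition_of == q - 1L)
    Xq <- X[, idx, drop = FALSE]
    if (length(idx) < 2L) {
      warning("partition ", q - 1L, " has fewer than 2 targets; ",
              "projection is skipped for it")
      per_part[[q]] <- list(V = matrix(0, 0L, length(idx)), k = 0L,
                            singular_values = numeric(0), targets = idx)
      next
    }
    sv <- if (method == "exact") svd(Xq) else
      randomized_svd(Xq, seed = seed, oversample = oversample,
                     power_iter = power_iter)
    d2 <- sv$d^2
    if (sum(d2) <= 0) {           # constant submatrix: nothing to remove
      per_part[[q]] <- list(V = matrix(0, 0L, length(idx)), k = 0L,
                            singular_values = sv$d, targets = idx)
      next
    }
    frac <- cumsum(d2) / sum(d2)
    k <- which(frac >= v - 1e-12)[1L]
    if (is.na(k)) k <- length(sv$d)
    k <- max(1L, k)
    per_part[[q]] <- list(V = t(sv$v[, seq_len(k), drop = FALSE]),
                          k = as.integer(k),
                          singular_values = sv$d,
                          targets = idx)
  }
  structure(list(partitions = partitions, v = v, method = method,
                 per_partition = per_part, n_targets = n),
            class = "normalization_basis")
}

# Randomized range-finder SVD (Gaussian sketch + subspace power iterations).
# For a wide p x n matrix with small p the sketch width is capped at
# min(p, n), so the decomposition is effectively exact.
randomized_svd <- function(A, seed = NULL, oversample = 10L, power_iter = 4L) {
  p <- nrow(A); n <- ncol(A)
  r <- min(p, n)
  l <- min(n, r + oversample)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  Omega <- matrix(stats::rnorm(n * l), n, l)
  Y <- A %*% Omega                      # p x l
  for (i in seq_len(power_iter)) Y <- A %*% crossprod(A, Y)
  Q <- qr.Q(qr(Y))                      # p x min(p, l)
  B <- crossprod(Q, A)                  # small x n
  sv <- svd(B)
  list(d = sv$d, u = Q %*% sv$u, v = sv$v)
}

#' Project the retained singular directions out of a matrix
#'
#' Per partition q, computes `T_q = X_q - X_q V' V` with the stored
#' orthonormal rows `V`, then reassembles columns into original target
#' order. Partitions fitted with `k = 0` (degenerate) pass through
#' unchanged.
#'
#' @param X samples x targets matrix (any number of rows, including 1).
#' @param basis a fitted `normalization_basis`.
#' @return Matrix of the same shape as `X`.
#' @export
project_out <- function(X, basis) {
  stopifnot(inherits(basis, "normalization_basis"))
  X <- as.matrix(X)
  if (ncol(X) != basis$n_targets)
    stop("X has ", ncol(X), " targets but basis was fitted on ",
         basis$n_targets)
  out <- X
  for (pp in basis$per_partition) {
    if (pp$k == 0L) next
    Xq <- X[, pp$targets, drop = FALSE]
    out[, pp$targets] <- Xq - (Xq %*% t(pp$V)) %*% pp$V
  }
  out
}

#' Full depth normalization transform
#'
#' The composite transform `f`: log counts, median-center each sample, and
#' remove the training-time singular directions. Works for a single query
#' sample (p = 1) -- the basis is never refit from the query.
#'
#' @param counts targets x samples non-negative matrix.
#' @param basis fitted `normalization_basis` over the same targets.
#' @return samples x targets matrix of normalized log-depth residuals.
#' @export
transform_f <- function(counts, basis) {
  counts <- as.matrix(counts)
  if (nrow(counts) != basis$n_targets)
    stop("counts cover ", nrow(counts), " targets but basis was fitted on ",
         basis$n_targets)
  project_out(median_center(log_transform(counts)), basis)
}
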