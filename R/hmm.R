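#' Build the two-parameter copy-number transition model
#'
#' Five copy-number states with a banded transition matrix in which `alpha`
#' is the probability of stepping away from the diploid state (toward more
#' extreme copy numbers) and `beta` the probability of stepping back toward
#' it:
#' \preformatted{
#'      [ 1-b   b    0    0    0  ]
#'      [  a  1-a-b  b    0    0  ]
#'  M = [  0    a  1-2a   a    0  ]
#'      [  0    0    b  1-a-b  a  ]
#'      [  0    0    0    b   1-b ]
#' }
#' Smaller values favour fewer, larger CNV calls. The initial state vector
#' is `pi = (0.01, 0.01, 0.96, 0.01, 0.01)`.
#'
#' @param alpha,beta transition parameters, default 0.0025 each.
#' @param pi optional initial state vector (length 5, sums to 1).
#' @return Object of class `hmm_spec` with elements `M`, `pi`, `alpha`,
#'   `beta`.
#' @export
build_transition_matrix <- function(alpha = 0.0025, beta = 0.0025,
                                    pi = c(0.01, 0.01, 0.96, 0.01, 0.01)) {
  stopifnot(alpha >= 0, beta >= 0)
  if (1 - alpha - beta < 0 || 1 - 2 * alpha < 0)
    stop("alpha/beta combination yields a negative transition probability")
  M <- matrix(c(
    1 - beta,  beta,            0,        0,               0,
    alpha,     1 - alpha - beta, beta,    0,               0,
    0,         alpha,           1 - 2 * alpha, alpha,      0,
    0,         0,               beta,     1 - alpha - beta, alpha,
    0,         0,               0,        beta,            1 - beta),
    nrow = 5L, byrow = TRUE)
  stopifnot(length(pi) == 5L, abs(sum(pi) - 1) < 1e-9)
  structure(list(M = M, pi = pi, alpha = alpha, beta = beta),
            class = "hmm_spec")
}

# Log emission density matrix: n x K, entry (t, i) = log N(x_t; mu[t,i],
# sqrt(vars[t,i])). Evaluated in log space so |z| of 40+ stays finite.
log_emission_matrix <- function(x, means, vars) {
  n <- length(x)
  if (any(!is.finite(x)))
    stop("non-finite observation at target ", which(!is.finite(x))[1L])
  stopifnot(nrow(means) == n, all(vars > 0))
  -0.5 * log(2 * pi * vars) - (x - means)^2 / (2 * vars)
}

#' Forward-backward posterior state probabilities
#'
#' Exact marginal posteriors of a homogeneous HMM with heterogeneous
#' per-target Gaussian emissions, computed with per-step scaling so chains
#' of 10^5+ targets with extreme z-scores stay numerically stable.
#'
#' @param x numeric observations, one per target (a row of
#'   [transform_f()] output restricted to one chromosome).
#' @param spec an [build_transition_matrix()] object.
#' @param means,vars n x K emission parameter matrices for these targets.
#' @return list of class `hmm_posterior`: `posterior` (n x K, rows sum to
#'   1), `loglik` (total log-likelihood), `scale` (per-step log scaling
#'   factors).
#' @export
forward_backward <- function(x, spec, means, vars) {
  stopifnot(inherits(spec, "hmm_spec"))
  n <- length(x)
  K <- length(spec$pi)
  logb <- log_emission_matrix(x, means, vars)
  # scale emission rows so exp() cannot underflow; absorbed into loglik
  row_max <- apply(logb, 1L, max)
  b <- exp(logb - row_max)

  M <- spec$M
  fwd <- matrix(0, n, K)
  scale <- numeric(n)
  f <- spec$pi * b[1L, ]
  scale[1L] <- sum(f)
  fwd[1L, ] <- f / scale[1L]
  if (n > 1L) for (t in 2:n) {
    f <- drop(fwd[t - 1L, ] %*% M) * b[t, ]
    scale[t] <- sum(f)
    fwd[t, ] <- f / scale[t]
  }

  bwd <- matrix(0, n, K)
  bwd[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    g <- drop(M %*% (b[t + 1L, ] * bwd[t + 1L, ]))
    bwd[t, ] <- g / scale[t + 1L]
  }

  post <- fwd * bwd
  post <- post / rowSums(post)
  structure(list(posterior = post,
                 loglik = sum(log(scale)) + sum(row_max),
                 scale = log(scale) + row_max),
            class = "hmm_posterior")
}

#' Pointwise maximum a posteriori decoding
#'
#' Picks, at every target independently, the state of maximum marginal
#' posterior probability. PMAP maximizes the expected number of correctly
#' assigned targets (unlike Viterbi, which maximizes joint path
#' probability) but may emit transition-inadmissible adjacencies; these are
#' counted in the `n_inadmissible` attribute, never silently repaired.
#'
#' @param posterior an `hmm_posterior` or a bare n x K posterior matrix.
#' @param diploid_idx 1-based index of the diploid state (ties break toward
#'   it, then toward the lower state index).
#' @param M optional transition matrix used only to count inadmissible
#'   adjacencies (entries with probability 0).
#' @return Integer vector of 1-based state indices with attribute
#'   `n_inadmissible`.
#' @export
pmap_decode <- function(posterior, diploid_idx = 3L, M = NULL) {
  post <- if (inherits(posterior, "hmm_posterior")) posterior$posterior
          else as.matrix(posterior)
  path <- apply(post, 1L, function(row) {
    cand <- which(row == max(row))
    if (diploid_idx %in% cand) diploid_idx else min(cand)
  })
  n_bad <- 0L
  if (!is.null(M) && length(path) > 1L) {
    n_bad <- sum(M[cbind(path[-length(path)], path[-1L])] == 0)
  }
  structure(as.integer(path), n_inadmissible = n_bad)
}

#' Viterbi decoding (joint most probable path)
#'
#' Provided for comparison and diagnostics; CNV calling uses
#' [pmap_decode()]. Ties break toward the diploid state, then the lower
#' index.
#'
#' @inheritParams forward_backward
#' @param diploid_idx 1-based diploid state index for tie-breaking.
#' @return Integer vector of 1-based state indices.
#' @export
viterbi_decode <- function(x, spec, means, vars, diploid_idx = 3L) {
  stopifnot(inherits(spec, "hmm_spec"))
  n <- length(x)
  K <- length(spec$pi)
  logb <- log_emission_matrix(x, means, vars)
  logM <- log(spec$M)

  pick_max <- function(v) {
    cand <- which(v >= max(v))
    if (diploid_idx %in% cand) diploid_idx else min(cand)
  }

  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1L, ] <- log(spec$pi) + logb[1L, ]
  if (n > 1L) for (t in 2:n) {
    for (j in seq_len(K)) {
      v <- delta[t - 1L, ] + logM[, j]
      psi[t, j] <- pick_max(v)
      delta[t, j] <- v[psi[t, j]] + logb[t, j]
    }
  }
  path <- integer(n)
  path[n] <- pick_max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}
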