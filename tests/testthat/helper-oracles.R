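# Independent oracles and small fixture builders shared across test files.

# Exact HMM quantities by enumerating all K^n state paths.
enumerate_hmm <- function(x, spec, means, vars) {
  n <- length(x)
  K <- length(spec$pi)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logb <- matrix(stats::dnorm(x, means, sqrt(vars), log = TRUE), n, K)

  logp <- log(spec$pi)[paths[, 1L]] + logb[cbind(1L, paths[, 1L])]
  if (n > 1L) for (t in 2:n) {
    logp <- logp + log(spec$M)[cbind(paths[, t - 1L], paths[, t])] +
      logb[cbind(t, paths[, t])]
  }
  total <- max(logp) + log(sum(exp(logp - max(logp))))
  w <- exp(logp - total)
  post <- matrix(0, n, K)
  for (t in seq_len(n)) for (k in seq_len(K))
    post[t, k] <- sum(w[paths[, t] == k])
  list(posterior = post, loglik = total, paths = paths, logp = logp, w = w)
}

# Viterbi by enumeration (no tie handling; use with generic random inputs).
enumerate_viterbi <- function(x, spec, means, vars) {
  e <- enumerate_hmm(x, spec, means, vars)
  e$paths[which.max(e$logp), ]
}

random_hmm_instance <- function(n, seed) {
  set.seed(seed)
  spec <- build_transition_matrix(stats::runif(1, 0.01, 0.3),
                                  stats::runif(1, 0.01, 0.3))
  K <- 5L
  means <- matrix(stats::rnorm(n * K, sd = 2), n, K)
  vars <- matrix(stats::runif(n * K, 0.2, 2), n, K)
  x <- stats::rnorm(n, sd = 2)
  list(x = x, spec = spec, means = means, vars = vars)
}

# Small multi-chromosome depth fixture with lognormal-biased NB counts.
small_depth_fixture <- function(n = 30L, p = 6L, seed = 42L,
                                mean_depth = 400) {
  set.seed(seed)
  chrom <- rep(c("chr1", "chr2"), c(ceiling(n / 2), floor(n / 2)))
  start <- unlist(lapply(rle(chrom)$lengths, function(m) (0:(m - 1)) * 500))
  targets <- data.frame(chrom = chrom, start = start, end = start + 200)
  bias <- stats::rlnorm(n, sdlog = 0.3)
  counts <- matrix(stats::rnbinom(n * p, size = 200, mu = mean_depth * bias),
                   n, p)
  depth_matrix(targets, counts, paste0("s", seq_len(p)))
}

# Numeric-integration oracle for the Gaussian KL divergence.
kl_numeric <- function(mu1, sd1, mu2, sd2) {
  stats::integrate(function(z) {
    f <- stats::dnorm(z, mu1, sd1)
    ifelse(f == 0, 0,
           f * (stats::dnorm(z, mu1, sd1, log = TRUE) -
                stats::dnorm(z, mu2, sd2, log = TRUE)))
  }, mu1 - 12 * sd1, mu1 + 12 * sd1, rel.tol = 1e-10)$value
}
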