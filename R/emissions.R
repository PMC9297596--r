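#' Default copy-number state coefficients
#'
#' Five states described by their expected multiplicative effect on raw
#' read depth: homozygous deletion (residual mapping noise keeps the
#' coefficient slightly above zero), heterozygous deletion, diploid,
#' heterozygous duplication, and homozygous duplication/amplification.
#'
#' @return data.frame with columns `label` and `coef`
#'   (`c(0.01, 0.5, 1.0, 1.5, 2.0)`).
#' @export
default_states <- function() {
  data.frame(label = c("HOM_DEL", "HET_DEL", "DIPLOID", "HET_DUP", "HOM_DUP"),
             coef = c(0.01, 0.5, 1.0, 1.5, 2.0),
             stringsAsFactors = FALSE)
}

validate_states <- function(states) {
  stopifnot(is.data.frame(states),
            all(c("label", "coef") %in% names(states)))
  if (any(diff(states$coef) <= 0))
    stop("state coefficients must be strictly increasing")
  if (sum(states$coef == 1) != 1L)
    stop("exactly one state (the diploid) must have coefficient 1")
  states
}

diploid_index <- function(states) which(states$coef == 1)

#' Estimate per-target, per-state Gaussian emission parameters
#'
#' For each target t and copy state i, the raw background depths at t are
#' multiplied by the state coefficient `s_i` (a pseudo-CNV spiked into
#' every training sample at once), the full normalization `f` is re-applied
#' with the stored basis (never refit), and the sample mean and sample
#' variance (n-1 denominator) of the transformed values at t across
#' samples become the emission parameters for (t, i).
#'
#' The `"incremental"` method exploits the fact that rescaling one target
#' perturbs the centered matrix by a rank-two update (the target's own
#' column plus each sample's median shift), so the transformed column can
#' be written in closed form from the training-time residuals; it is
#' algebraically identical to the `"reference"` full recomputation (used as
#' the oracle in tests) but runs in O(n p) per state instead of O(n^2 p).
#'
#' @param depths a [depth_matrix] of background samples (p >= 2).
#' @param basis fitted `normalization_basis` over the same targets.
#' @param states state table as from [default_states()].
#' @param method `"incremental"` (default) or `"reference"`.
#' @param var_floor lower bound applied to variances (default 1e-6) so
#'   degenerate targets keep a proper Gaussian.
#' @return list of class `emission_model` with `means` and `variances`
#'   (n x n_states matrices, columns named by state label), `states`, and
#'   `n_train`.
#' @export
estimate_emissions <- function(depths, basis, states = default_states(),
                               method = c("incremental", "reference"),
                               var_floor = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(depths, "depth_matrix"))
  states <- validate_states(states)
  D <- depths$counts
  n <- nrow(D); p <- ncol(D)
  if (p < 2L) stop("emission estimation requires at least 2 background samples")

  est <- if (method == "reference")
    emissions_reference(D, basis, states$coef)
  else
    emissions_incremental(D, basis, states$coef)

  est$variances <- pmax(est$variances, var_floor)
  colnames(est$means) <- colnames(est$variances) <- states$label

  # higher copy number should mean higher normalized depth at every target
  mono <- apply(est$means, 1L, function(m) all(diff(m) >= 0))
  if (any(!mono))
    warning(sum(!mono), " target(s) have non-monotone emission means ",
            "across states")

  structure(list(means = est$means, variances = est$variances,
                 states = states, n_train = p),
            class = "emission_model")
}

# Reference semantics: rebuild the scaled depth matrix and re-run the whole
# transform for every (target, state) pair. O(n^2 p |s|); tests only.
emissions_reference <- function(D, basis, s) {
  n <- nrow(D); p <- ncol(D)
  means <- matrix(NA_real_, n, length(s))
  vars <- matrix(NA_real_, n, length(s))
  for (i in seq_along(s)) {
    for (t in seq_len(n)) {
      Dh <- D
      Dh[t, ] <- Dh[t, ] * s[i]
      Th <- transform_f(Dh, basis)
      means[t, i] <- mean(Th[, t])
      vars[t, i] <- stats::var(Th[, t])
    }
  }
  list(means = means, variances = vars)
}

# Closed-form path. With X the centered training matrix (samples x
# targets), scaling target t by s_i changes column t by
# delta_s = ln(s_i d_ts + 1) - ln(d_ts + 1) and shifts every entry of
# sample s by the induced median change -dm_s:
#   X_hat = X + delta e_t' - dm 1'
# Applying the projector (I - V'V) per partition and reading off column t:
#   T_hat[, t] = T[, t] + delta (1 - G_tt) - dm (1 - colsum_t(G)),
# with G = V'V, so only diag(G) and colSums(G) are needed.
emissions_incremental <- function(D, basis, s) {
  n <- nrow(D); p <- ncol(D)
  P <- log_transform(D)                 # n x p
  X <- median_center(P)                 # p x n
  T0 <- project_out(X, basis)           # p x n

  g_diag <- numeric(n); g_csum <- numeric(n)
  for (pp in basis$per_partition) {
    if (pp$k == 0L) next
    g_diag[pp$targets] <- colSums(pp$V^2)
    g_csum[pp$targets] <- drop(crossprod(pp$V, rowSums(pp$V)))
  }
  a <- 1 - g_diag                       # own-column retention
  b <- 1 - g_csum                       # median-shift retention

  # per-sample sorted columns for O(1) replace-one medians
  med0 <- apply(P, 2L, stats::median)
  sort_info <- lapply(seq_len(p), function(sm) {
    ord <- order(P[, sm])
    pos <- integer(n); pos[ord] <- seq_len(n)
    list(a_sorted = P[ord, sm], pos = pos)
  })

  means <- matrix(NA_real_, n, length(s))
  vars <- matrix(NA_real_, n, length(s))
  Tn <- t(T0)                           # n x p
  for (i in seq_along(s)) {
    if (s[i] == 1) {
      means[, i] <- rowMeans(Tn)
      vars[, i] <- rowSums((Tn - rowMeans(Tn))^2) / (p - 1)
      next
    }
    Ph <- log1p(s[i] * D)               # n x p, new values at each target
    delta <- Ph - P
    dm <- vapply(seq_len(p), function(sm)
      median_replace_one(sort_info[[sm]]$a_sorted, sort_info[[sm]]$pos,
                         Ph[, sm]) - med0[sm],
      numeric(n))                       # n x p
    Vh <- Tn + delta * a - dm * b       # n x p transformed column-t values
    mu <- rowMeans(Vh)
    means[, i] <- mu
    vars[, i] <- rowSums((Vh - mu)^2) / (p - 1)
  }
  list(means = means, variances = vars)
}

# Medians after replacing one element: given the sorted values `a_sorted`
# of a length-n vector and `pos[t]` = sorted position of element t, return
# for every t the median of the vector with element t replaced by w[t].
# Exactly matches stats::median (mean of the two middle order statistics
# for even n).
median_replace_one <- function(a_sorted, pos, w) {
  n <- length(a_sorted)
  cnt <- findInterval(w, a_sorted)            # elements <= w
  q <- cnt - (pos <= cnt) + 1L                # insertion slot after removal

  pick <- function(j) {
    # value at sorted position j after removing pos and inserting w at q
    idx <- ifelse(j < q, j + (j >= pos), j - 1L + (j - 1L >= pos))
    idx <- pmin(pmax(idx, 1L), n)
    ifelse(j == q, w, a_sorted[idx])
  }
  if (n %% 2L == 1L) pick((n + 1L) %/% 2L)
  else (pick(n %/% 2L) + pick(n %/% 2L + 1L)) / 2
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' Closed form `KL(N(mu1, s1^2) || N(mu2, s2^2)) =
#' ln(s2/s1) + (s1^2 + (mu1 - mu2)^2) / (2 s2^2) - 1/2`.
#'
#' @param mu1,sd1 parameters of the first (reference) distribution.
#' @param mu2,sd2 parameters of the second distribution.
#' @return Non-negative divergence (vectorized).
#' @export
gaussian_kl <- function(mu1, sd1, mu2, sd2) {
  stopifnot(all(sd1 > 0), all(sd2 > 0))
  log(sd2 / sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 * sd2^2) - 0.5
}

#' Per-target copy-number resolution
#'
#' The KL divergence from the heterozygous-deletion emission distribution
#' to the diploid one, a proxy for a target's power to resolve copy number:
#' overlapping distributions (low KL) mean overlapping posteriors and poor
#' calling accuracy. Values below roughly 10 flag poorly resolved targets.
#'
#' @param model a fitted `cnv_model` (see [train_model()]).
#' @param which_targets optional integer subset; default all.
#' @return Numeric vector of divergences.
#' @export
target_resolution <- function(model, which_targets = NULL) {
  stopifnot(inherits(model, "cnv_model"))
  st <- model$emissions$states
  del <- which(st$coef == 0.5)
  dip <- diploid_index(st)
  if (length(del) != 1L)
    stop("model has no heterozygous-deletion state (coefficient 0.5)")
  idx <- if (is.null(which_targets)) seq_len(nrow(model$emissions$means))
         else which_targets
  gaussian_kl(model$emissions$means[idx, del],
              sqrt(model$emissions$variances[idx, del]),
              model$emissions$means[idx, dip],
              sqrt(model$emissions$variances[idx, dip]))
}

#' Write per-target resolution to a BED file
#'
#' One row per target: chrom, start, end, KL divergence (6 decimals), and a
#' `LOW`/`PASS` flag against the threshold.
#'
#' @param model a fitted `cnv_model`.
#' @param path output path.
#' @param kl_threshold flag targets with resolution below this (default 10).
#' @export
resolution_bed <- function(model, path, kl_threshold = 10) {
  res <- target_resolution(model)
  tg <- model$targets
  rows <- paste(tg$chrom, tg$start, tg$end, sprintf("%.6f", res),
                ifelse(res < kl_threshold, "LOW", "PASS"), sep = "\t")
  writeLines(c("#chrom\tstart\tend\tkl_divergence\tflag", rows), path)
  invisible(path)
}
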