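#' Simulation configuration for synthetic capture panels
#'
#' Describes the generative model used to emulate multi-sample
#' hybridization-capture read counts: per-target capture-efficiency bias
#' (log-normal), per-sample library-size factors (log-normal), latent batch
#' factors creating correlated across-target structure, and negative
#' binomial counting noise. The defaults describe a desk-scale panel --
#' 2,000 targets on 4 chromosomes, 40 background samples, ~450 reads per
#' target (150x read depth) -- large enough to exercise the SVD
#' normalization meaningfully in minutes.
#'
#' @param n_targets,n_samples panel dimensions.
#' @param mean_depth expected read COUNT at an average target. The default
#'   450 corresponds to a mean read depth of 150x when counts are the
#'   number of reads overlapping a ~200 bp target with ~100 bp reads
#'   (count ~ depth * (L_target + L_read) / L_read), the counting scheme
#'   used with capture panels.
#' @param target_bias_sd sd of log capture efficiency (default 0.5; real
#'   probes vary severalfold).
#' @param library_sd sd of log library-size factor (default 0.2).
#' @param nb_dispersion negative binomial size parameter for residual
#'   counting noise (default 1000, i.e. near-Poisson: systematic
#'   overdispersion is carried by the explicit bias and batch terms, the
#'   residual is close to counting noise). `Inf` gives exact Poisson.
#' @param n_batch_factors number of latent rank-1 batch factors (default 2).
#' @param batch_sd sd of per-target factor loadings on the log scale
#'   (default 0.04, i.e. a few percent run-to-run depth shifts as seen in a
#'   single-lab, single-instrument series; per-sample activations are
#'   standard normal).
#' @param n_chromosomes number of chromosomes the targets are spread over.
#' @param target_length,target_gap geometry of the synthetic targets (bp).
#' @param seed integer seed; fully determines the output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_targets = 2000L, n_samples = 40L, mean_depth = 450,
                       target_bias_sd = 0.5, library_sd = 0.2,
                       nb_dispersion = 1000, n_batch_factors = 2L,
                       batch_sd = 0.04, n_chromosomes = 4L,
                       target_length = 200L, target_gap = 800L,
                       seed = 1L) {
  stopifnot(n_targets >= 1L, n_samples >= 1L, mean_depth > 0,
            n_chromosomes >= 1L, n_chromosomes <= n_targets)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic capture panel (target-level parameters)
#'
#' Draws the per-target quantities that are fixed properties of a panel --
#' coordinates, capture-efficiency bias, batch-factor loadings -- so that
#' background and query samples can be generated from the same panel.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_panel` with `targets`, `bias`, `loadings`
#'   (n x f), and the config.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_targets
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chromosomes + 1L)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chrom)
  within <- sequence(per_chrom) - 1L
  start <- within * (config$target_length + config$target_gap)
  targets <- data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(start + config$target_length),
                        stringsAsFactors = FALSE)
  bias <- stats::rlnorm(n, meanlog = -config$target_bias_sd^2 / 2,
                        sdlog = config$target_bias_sd)
  loadings <- matrix(stats::rnorm(n * config$n_batch_factors,
                                  sd = config$batch_sd),
                     n, config$n_batch_factors)
  structure(list(targets = targets, bias = bias, loadings = loadings,
                 config = config),
            class = "sim_panel")
}

#' Simulate read-count samples from a panel
#'
#' Per sample s and target t the expected count is
#' `mean_depth * L_s * b_t * exp(sum_f g_sf w_tf)` with library factor
#' `L_s` (log-normal, mean 1), capture bias `b_t`, loadings `w` and
#' standard-normal batch activations `g`; counts are negative binomial
#' around that mean (Poisson when `nb_dispersion = Inf`).
#'
#' @param panel a [simulate_panel()] object.
#' @param n_samples number of samples to draw.
#' @param seed seed for the sample-level draws.
#' @param prefix sample name prefix.
#' @return A [depth_matrix].
#' @export
simulate_depths <- function(panel, n_samples, seed, prefix = "sample") {
  stopifnot(inherits(panel, "sim_panel"))
  cfg <- panel$config
  set.seed(seed)
  n <- cfg$n_targets
  L <- stats::rlnorm(n_samples, meanlog = -cfg$library_sd^2 / 2,
                     sdlog = cfg$library_sd)
  g <- matrix(stats::rnorm(n_samples * cfg$n_batch_factors),
              n_samples, cfg$n_batch_factors)
  mu <- cfg$mean_depth * (panel$bias %o% L) *
    exp(panel$loadings %*% t(g))                    # n x p
  counts <- if (is.infinite(cfg$nb_dispersion))
    matrix(stats::rpois(n * n_samples, mu), n, n_samples)
  else
    matrix(stats::rnbinom(n * n_samples, size = cfg$nb_dispersion, mu = mu),
           n, n_samples)
  depth_matrix(panel$targets, counts,
               sprintf("%s_%03d", prefix, seq_len(n_samples)))
}

#' Simulate a background depth matrix
#'
#' Convenience wrapper: builds the panel and draws `config$n_samples`
#' background samples, all from `config$seed`. The panel is attached as
#' attribute `"panel"` so further (query) samples can be drawn from the
#' same target biases and batch loadings.
#'
#' @param config a [sim_config()].
#' @return A [depth_matrix] with attribute `panel`.
#' @export
simulate_background <- function(config) {
  panel <- simulate_panel(config)
  d <- simulate_depths(panel, config$n_samples, seed = config$seed + 10000L)
  attr(d, "panel") <- panel
  d
}

#' Build a truth set of CNVs to spike in
#'
#' Places the requested number of CNVs of each span uniformly at random
#' over (sample, chromosome) slots, at most one CNV per sample per
#' chromosome, so truth records never overlap within a sample.
#'
#' @param targets target data.frame of the depth matrix being spiked.
#' @param sample_names samples eligible to receive CNVs.
#' @param sizes data.frame with columns `span` (targets covered) and
#'   `count`, e.g. `data.frame(span = c(1, 3, 10), count = c(100, 30, 10))`.
#' @param coefficient depth multiplier for every CNV (0.5 = heterozygous
#'   deletion, 1.5 = heterozygous duplication).
#' @param seed integer seed.
#' @return data.frame of class `truth_set`: `sample`, `chrom`, `start`,
#'   `end`, `first_target`, `last_target`, `coef`, `span`.
#' @export
make_truth_set <- function(targets, sample_names, sizes, coefficient,
                           seed = 1L) {
  stopifnot(is.data.frame(sizes), all(c("span", "count") %in% names(sizes)),
            length(coefficient) == 1L, coefficient >= 0)
  set.seed(seed)
  chroms <- unique(targets$chrom)
  slots <- expand.grid(sample = sample_names, chrom = chroms,
                       stringsAsFactors = FALSE)
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  total <- sum(sizes$count)
  if (total > nrow(slots))
    stop("requested ", total, " CNVs but only ", nrow(slots),
         " (sample, chromosome) slots are available")

  spans <- rep(sizes$span, sizes$count)
  spans <- spans[sample.int(length(spans))]
  out <- vector("list", length(spans))
  for (i in seq_along(spans)) {
    sl <- slots[i, ]
    idx <- which(targets$chrom == sl$chrom)
    if (length(idx) < spans[i])
      stop("chromosome ", sl$chrom, " has only ", length(idx),
           " targets; cannot place a span-", spans[i], " CNV")
    first <- idx[sample.int(length(idx) - spans[i] + 1L, 1L)]
    last <- first + spans[i] - 1L
    out[[i]] <- data.frame(sample = sl$sample, chrom = sl$chrom,
                           start = targets$start[first],
                           end = targets$end[last],
                           first_target = first, last_target = last,
                           coef = coefficient, span = spans[i],
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(sample = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         first_target = integer(0), last_target = integer(0),
                         coef = numeric(0), span = integer(0),
                         stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("truth_set", "data.frame")
  res
}

#' Spike CNVs into a depth matrix
#'
#' Multiplies the counts of the affected targets in the affected sample by
#' the truth coefficient and rounds to the nearest integer (halves away
#' from zero). All other entries are untouched.
#'
#' @param depths a [depth_matrix].
#' @param truth one truth record or a whole [make_truth_set()] data.frame.
#' @return The modified [depth_matrix].
#' @export
spike_cnv <- function(depths, truth) {
  stopifnot(inherits(depths, "depth_matrix"))
  counts <- depths$counts
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    idx <- tr$first_target:tr$last_target
    if (length(unique(depths$targets$chrom[idx])) != 1L)
      stop("truth record ", i, " crosses a chromosome boundary")
    col <- match(tr$sample, colnames(counts))
    if (is.na(col)) stop("truth sample not in depth matrix: ", tr$sample)
    scaled <- counts[idx, col] * tr$coef
    counts[idx, col] <- sign(scaled) * floor(abs(scaled) + 0.5)
  }
  depths$counts <- counts
  depths
}
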