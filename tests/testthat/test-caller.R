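make_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_targets = 400, n_samples = 20, n_chromosomes = 2,
                        seed = 501)
      bg <- simulate_background(cfg)
      cache <<- list(bg = bg, model = train_model(bg, j = 200, seed = 501))
    }
    cache
  }
})

test_that("training yields the contracted shapes deterministically", {
  fx <- make_trained()
  model <- fx$model
  expect_s3_class(model, "cnv_model")
  expect_equal(dim(model$emissions$means), c(400L, 5L))
  expect_equal(dim(model$emissions$variances), c(400L, 5L))
  expect_equal(nrow(model$targets), 400L)

  model2 <- train_model(fx$bg, j = 200, seed = 501)
  expect_identical(serialize(model, NULL), serialize(model2, NULL))

  # rank selection is monotone in v within every partition
  k_lo <- vapply(train_model(fx$bg, v = 0.5, j = 200)$basis$per_partition,
                 `[[`, integer(1), "k")
  k_hi <- vapply(train_model(fx$bg, v = 0.99, j = 200)$basis$per_partition,
                 `[[`, integer(1), "k")
  expect_true(all(k_hi >= k_lo))
})

test_that("segment joining follows state runs and chromosome boundaries", {
  tg <- data.frame(chrom = rep(c("chr1", "chr2"), each = 4),
                   start = rep((0:3) * 1000, 2),
                   end = rep((0:3) * 1000 + 200, 2))
  post <- matrix(0.01, 8, 5); post[cbind(1:8, c(3, 2, 2, 3, 3, 3, 3, 3))] <- 0.9

  calls <- segment_calls(c(3, 2, 2, 3, 3, 3, 3, 3), post, tg, sample = "q")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$state, "HET_DEL")
  expect_equal(calls$n_targets, 2L)
  expect_equal(c(calls$start, calls$end), c(1000, 2200))
  expect_equal(calls$quality, 0.9)

  # all-diploid path: nothing to emit
  expect_equal(nrow(segment_calls(rep(3L, 8), post, tg)), 0L)

  # identical state across a chromosome boundary stays two calls
  calls <- segment_calls(c(3, 3, 3, 2, 2, 3, 3, 3), post, tg, sample = "q")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$chrom, c("chr1", "chr2"))
})

test_that("spiked deletions and duplications are recovered symmetrically", {
  fx <- make_trained()
  bg <- fx$bg
  idx <- 51:60
  for (case in list(list(coef = 0.5, state = "HET_DEL"),
                    list(coef = 1.5, state = "HET_DUP"))) {
    counts <- bg$counts[, 4, drop = FALSE]
    counts[idx, 1] <- round(counts[idx, 1] * case$coef)
    q <- depth_matrix(bg$targets, counts, "query")
    calls <- call_cnvs(q, fx$model)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$state, case$state)
    expect_equal(calls$first_target, 51L)
    expect_equal(calls$last_target, 60L)
    expect_gte(calls$quality, 0.95)
  }

  # the same sample unspiked yields (near) zero calls
  q0 <- depth_matrix(bg$targets, bg$counts[, 4, drop = FALSE], "query")
  expect_lte(nrow(call_cnvs(q0, fx$model)), 1L)
})

test_that("quality filtering is monotone and validation errors are raised", {
  fx <- make_trained()
  counts <- fx$bg$counts[, 2, drop = FALSE]
  counts[11:13, 1] <- round(counts[11:13, 1] * 0.5)
  q <- depth_matrix(fx$bg$targets, counts, "query")

  strict <- call_cnvs(q, fx$model, quality_threshold = 0.95)
  loose <- call_cnvs(q, fx$model, quality_threshold = 0)
  key <- function(x) paste(x$chrom, x$start, x$end, x$state)
  expect_true(all(key(strict) %in% key(loose)))

  two <- depth_matrix(fx$bg$targets, fx$bg$counts[, 1:2], c("a", "b"))
  expect_error(call_cnvs(two, fx$model), "single-sample")

  shifted <- fx$bg$targets
  shifted$start[1] <- shifted$start[1] + 7
  shifted$end[1] <- shifted$end[1] + 7
  qbad <- depth_matrix(shifted, counts, "query")
  expect_error(call_cnvs(qbad, fx$model), "1 query target")
})

test_that("predict method, call output files and determinism line up", {
  fx <- make_trained()
  counts <- fx$bg$counts[, 7, drop = FALSE]
  counts[101:110, 1] <- round(counts[101:110, 1] * 0.5)
  counts[301:310, 1] <- round(counts[301:310, 1] * 1.5)
  q <- depth_matrix(fx$bg$targets, counts, "q7")

  calls <- predict(fx$model, q, quality_threshold = 0.9)
  expect_gte(nrow(calls), 2L)

  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_calls_bed(calls, f1)
  write_calls_bed(predict(fx$model, q, quality_threshold = 0.9), f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical reruns

  back <- read_calls_bed(f1)
  expect_equal(nrow(back), nrow(calls))
  ord <- order(calls$chrom, calls$start)
  expect_equal(back$start, calls$start[ord])
  expect_equal(back$state, calls$state[ord])
  expect_equal(back$quality, round(calls$quality[ord], 4))
  # rows are genome-sorted within each chromosome
  for (ch in unique(back$chrom))
    expect_false(is.unsorted(back$start[back$chrom == ch]))

  # empty call set: header-only file
  write_calls_bed(calls[0, ], f1)
  expect_equal(readLines(f1), "#chrom\tstart\tend\tstate\tquality\tn_targets\tsample")
})

test_that("smaller transition parameters do not fragment calls", {
  fx <- make_trained()
  fragmented <- 0L
  for (sm in c(1, 3, 5, 8, 10)) {
    counts <- fx$bg$counts[, sm, drop = FALSE]
    counts[21:40, 1] <- round(counts[21:40, 1] * 0.5)
    q <- depth_matrix(fx$bg$targets, counts, "q")
    n_default <- nrow(call_cnvs(q, fx$model, quality_threshold = 0))
    n_small <- nrow(call_cnvs(q, fx$model, alpha = 2.5e-5, beta = 2.5e-5,
                              quality_threshold = 0))
    if (n_small > n_default) fragmented <- fragmented + 1L
  }
  expect_lt(fragmented, 3L)   # holds for the majority of samples
})
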