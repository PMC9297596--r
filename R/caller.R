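#' Join a decoded state path into CNV calls
#'
#' Maximal runs of identical non-diploid state within one chromosome become
#' single calls. Call coordinates span the first target's start to the last
#' target's end; quality is the mean (or minimum) posterior probability of
#' the assigned state over the segment's targets.
#'
#' @param path integer state path (1-based indices into the state table).
#' @param posterior n x K posterior matrix aligned with `path`.
#' @param targets target data.frame (`chrom`, `start`, `end`) aligned with
#'   `path`.
#' @param states state table (label/coef).
#' @param sample sample name recorded on each call.
#' @param quality `"mean"` (default) or `"min"` posterior aggregation.
#' @return data.frame of calls: `chrom`, `start`, `end`, `state`, `coef`,
#'   `quality`, `n_targets`, `first_target`, `last_target`, `sample`.
#' @export
segment_calls <- function(path, posterior, targets, states = default_states(),
                          sample = "sample", quality = c("mean", "min")) {
  quality <- match.arg(quality)
  stopifnot(length(path) == nrow(targets), length(path) == nrow(posterior))
  dip <- diploid_index(states)

  runs <- rle(paste(targets$chrom, path, sep = "\r"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  out <- list()
  for (r in seq_along(runs$lengths)) {
    st <- path[starts[r]]
    if (st == dip) next
    idx <- starts[r]:ends[r]
    q <- if (quality == "mean") mean(posterior[idx, st])
         else min(posterior[idx, st])
    out[[length(out) + 1L]] <- data.frame(
      chrom = targets$chrom[starts[r]],
      start = targets$start[starts[r]],
      end = targets$end[ends[r]],
      state = states$label[st],
      coef = states$coef[st],
      quality = q,
      n_targets = length(idx),
      first_target = starts[r],
      last_target = ends[r],
      sample = sample,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_calls())
  do.call(rbind, out)
}

empty_calls <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             state = character(0), coef = numeric(0), quality = numeric(0),
             n_targets = integer(0), first_target = integer(0),
             last_target = integer(0), sample = character(0),
             stringsAsFactors = FALSE)
}

#' Call CNVs in a single query sample
#'
#' The prediction phase: the query depths are normalized with the stored
#' training basis (`transform_f`), the five-state HMM is run chromosome by
#' chromosome (the chain restarts with a fresh initial vector at every
#' chromosome boundary), the posterior is decoded pointwise (PMAP), runs of
#' identical non-diploid state are joined, and calls below the quality
#' threshold are dropped.
#'
#' @param query a [depth_matrix] with exactly one sample, over exactly the
#'   model's targets (same coordinates, same order after sorting).
#' @param model a trained `cnv_model` (from [train_model()] or
#'   [load_model()]).
#' @param alpha,beta transition parameters (default 0.0025); smaller values
#'   favour fewer, larger CNVs.
#' @param quality_threshold drop calls with quality below this (default
#'   0.95). Use 0 to keep everything.
#' @param quality posterior aggregation rule, `"mean"` or `"min"`.
#' @return data.frame of calls as in [segment_calls()], sorted by
#'   (chromosome, start), with attribute `n_inadmissible` counting
#'   PMAP adjacencies of zero transition probability.
#' @export
call_cnvs <- function(query, model, alpha = 0.0025, beta = 0.0025,
                      quality_threshold = 0.95,
                      quality = c("mean", "min")) {
  quality <- match.arg(quality)
  stopifnot(inherits(query, "depth_matrix"), inherits(model, "cnv_model"))
  if (ncol(query$counts) != 1L)
    stop("prediction is single-sample by design; got ",
         ncol(query$counts), " samples")
  check_targets_match(query$targets, model$targets)

  x <- drop(transform_f(query$counts, model$basis))
  spec <- build_transition_matrix(alpha, beta)
  states <- model$emissions$states
  dip <- diploid_index(states)
  sample_name <- colnames(query$counts)[1L]

  calls <- list()
  n_bad <- 0L
  for (chrom in unique(model$targets$chrom)) {
    idx <- which(model$targets$chrom == chrom)
    fb <- forward_backward(x[idx], spec,
                           model$emissions$means[idx, , drop = FALSE],
                           model$emissions$variances[idx, , drop = FALSE])
    path <- pmap_decode(fb, diploid_idx = dip, M = spec$M)
    n_bad <- n_bad + attr(path, "n_inadmissible")
    seg <- segment_calls(path, fb$posterior,
                         model$targets[idx, , drop = FALSE],
                         states, sample = sample_name, quality = quality)
    if (nrow(seg)) {
      seg$first_target <- seg$first_target + idx[1L] - 1L
      seg$last_target <- seg$last_target + idx[1L] - 1L
      calls[[length(calls) + 1L]] <- seg
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  out <- out[out$quality >= quality_threshold, , drop = FALSE]
  ord <- genome_order(out)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_inadmissible") <- n_bad
  out
}

#' @export
predict.cnv_model <- function(object, query, ...) {
  call_cnvs(query, object, ...)
}

check_targets_match <- function(query_targets, model_targets) {
  if (nrow(query_targets) != nrow(model_targets))
    stop("query has ", nrow(query_targets), " targets but the model has ",
         nrow(model_targets))
  bad <- which(query_targets$chrom != model_targets$chrom |
               query_targets$start != model_targets$start |
               query_targets$end != model_targets$end)
  if (length(bad))
    stop(length(bad), " query target(s) differ from the model; first: ",
         sprintf("%s:%d-%d vs %s:%d-%d",
                 query_targets$chrom[bad[1L]], query_targets$start[bad[1L]],
                 query_targets$end[bad[1L]],
                 model_targets$chrom[bad[1L]], model_targets$start[bad[1L]],
                 model_targets$end[bad[1L]]))
  invisible(TRUE)
}

#' Write / read CNV calls in BED format
#'
#' Columns: chrom, start, end, state label, quality (4 decimals), number of
#' targets, sample. Calls are written sorted by (chromosome, start).
#'
#' @param calls data.frame of calls from [call_cnvs()].
#' @param path file path.
#' @export
write_calls_bed <- function(calls, path) {
  header <- "#chrom\tstart\tend\tstate\tquality\tn_targets\tsample"
  if (!nrow(calls)) {
    writeLines(header, path)
    return(invisible(path))
  }
  calls <- calls[genome_order(calls), , drop = FALSE]
  rows <- paste(calls$chrom, calls$start, calls$end, calls$state,
                sprintf("%.4f", calls$quality), calls$n_targets,
                calls$sample, sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_calls_bed
#' @return `read_calls_bed()` returns a data.frame with the written
#'   columns.
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      quality = numeric(0), n_targets = integer(0),
                      sample = character(0), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = f[, 1L], start = as.integer(f[, 2L]),
             end = as.integer(f[, 3L]), state = f[, 4L],
             quality = as.numeric(f[, 5L]), n_targets = as.integer(f[, 6L]),
             sample = f[, 7L], stringsAsFactors = FALSE)
}
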