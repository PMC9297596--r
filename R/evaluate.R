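#' Reciprocal overlap of two genomic intervals
#'
#' Intersection-over-union of base-pair intervals; 0 when the chromosomes
#' differ. Symmetric in its arguments.
#'
#' @param chrom1,start1,end1 first interval (0-based half-open).
#' @param chrom2,start2,end2 second interval.
#' @return Fraction in `[0, 1]` (vectorized).
#' @export
reciprocal_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  inter <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  uni <- (end1 - start1) + (end2 - start2) - inter
  ifelse(chrom1 == chrom2, inter / uni, 0)
}

#' Target-level Jaccard between a truth CNV and called targets
#'
#' `|intersection| / |union|` of target-index sets; 0 when no called target
#' overlaps the truth.
#'
#' @param truth_targets integer indices of the true CNV's targets
#'   (non-empty).
#' @param called_targets integer indices covered by calls (possibly empty).
#' @return Fraction in `[0, 1]`.
#' @export
target_jaccard <- function(truth_targets, called_targets) {
  if (!length(truth_targets)) stop("truth target set must be non-empty")
  if (!length(called_targets)) return(0)
  length(intersect(truth_targets, called_targets)) /
    length(union(truth_targets, called_targets))
}

call_direction <- function(coef) ifelse(coef < 1, "DEL", "DUP")

# union metric of one truth record against all same-sample calls
match_truth <- function(tr, calls, rule) {
  dir <- call_direction(tr$coef)
  cand <- calls[calls$sample == tr$sample &
                calls$chrom == tr$chrom &
                call_direction(calls$coef) == dir, , drop = FALSE]
  if (!nrow(cand)) return(list(metric = 0, call_idx = integer(0)))

  if (rule == "target_jaccard") {
    hit <- cand$last_target >= tr$first_target &
           cand$first_target <= tr$last_target
    cand <- cand[hit, , drop = FALSE]
    if (!nrow(cand)) return(list(metric = 0, call_idx = integer(0)))
    called <- unlist(mapply(seq, cand$first_target, cand$last_target,
                            SIMPLIFY = FALSE))
    metric <- target_jaccard(tr$first_target:tr$last_target, called)
  } else {
    hit <- cand$end > tr$start & cand$start < tr$end
    cand <- cand[hit, , drop = FALSE]
    if (!nrow(cand)) return(list(metric = 0, call_idx = integer(0)))
    # union of base pairs covered by the overlapping calls
    iv <- cand[order(cand$start), c("start", "end"), drop = FALSE]
    merged <- list()
    cur_s <- iv$start[1L]; cur_e <- iv$end[1L]
    if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
      if (iv$start[i] <= cur_e) cur_e <- max(cur_e, iv$end[i])
      else { merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
             cur_s <- iv$start[i]; cur_e <- iv$end[i] }
    }
    merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
    inter <- sum(vapply(merged, function(m)
      max(0, min(m[2L], tr$end) - max(m[1L], tr$start)), numeric(1)))
    covered <- sum(vapply(merged, function(m) m[2L] - m[1L], numeric(1)))
    uni <- covered + (tr$end - tr$start) - inter
    metric <- inter / uni
  }
  list(metric = metric, call_idx = rownames(cand))
}

#' Score CNV calls against a truth set
#'
#' Applies the quality-threshold filter, matches each truth CNV against the
#' union of same-direction calls overlapping it in the same sample (50%
#' cutoff on the chosen rule), and tabulates sensitivity and positive
#' predictive value per sample and pooled. A call counts as a true positive
#' when it overlaps a truth CNV that is correctly called under the rule.
#' PPV is `NA` (not 0) for samples with no calls.
#'
#' @param calls data.frame from [call_cnvs()] (columns including `sample`,
#'   `chrom`, `start`, `end`, `coef`, `quality`, `first_target`,
#'   `last_target`).
#' @param truth a [make_truth_set()] data.frame.
#' @param rule `"reciprocal"` (base-pair reciprocal overlap, default) or
#'   `"target_jaccard"` (modified target-level Jaccard).
#' @param quality_threshold keep calls with quality >= this (default 0).
#' @param cutoff match cutoff on the rule's fraction (default 0.5).
#' @return list of class `eval_result`: `pooled` (sensitivity, ppv, tp, fn,
#'   n_calls, tp_calls), `per_sample` and `by_span` data.frames,
#'   `truth_metric` vector, plus the rule and threshold used.
#' @export
score_calls <- function(calls, truth, rule = c("reciprocal", "target_jaccard"),
                        quality_threshold = 0, cutoff = 0.5) {
  rule <- match.arg(rule)
  calls <- calls[calls$quality >= quality_threshold, , drop = FALSE]
  rownames(calls) <- if (nrow(calls)) as.character(seq_len(nrow(calls)))
                     else NULL

  metric <- numeric(nrow(truth))
  tp_call_ids <- character(0)
  for (i in seq_len(nrow(truth))) {
    m <- match_truth(truth[i, ], calls, rule)
    metric[i] <- m$metric
    if (m$metric >= cutoff) tp_call_ids <- c(tp_call_ids, m$call_idx)
  }
  matched <- metric >= cutoff
  is_tp_call <- rownames(calls) %in% tp_call_ids

  per_sample <- do.call(rbind, lapply(
    sort(unique(c(truth$sample, calls$sample))), function(sm) {
      ti <- truth$sample == sm
      ci <- calls$sample == sm
      data.frame(sample = sm,
                 n_truth = sum(ti), tp = sum(matched[ti]),
                 fn = sum(ti) - sum(matched[ti]),
                 n_calls = sum(ci), tp_calls = sum(is_tp_call[ci]),
                 sensitivity = if (sum(ti)) mean(matched[ti]) else NA_real_,
                 ppv = if (sum(ci)) sum(is_tp_call[ci]) / sum(ci)
                       else NA_real_,
                 stringsAsFactors = FALSE)
    }))

  by_span <- do.call(rbind, lapply(sort(unique(truth$span)), function(sp) {
    si <- truth$span == sp
    data.frame(span = sp, n_truth = sum(si), tp = sum(matched[si]),
               sensitivity = mean(matched[si]), stringsAsFactors = FALSE)
  }))

  pooled <- list(
    tp = sum(matched), fn = sum(!matched),
    n_calls = nrow(calls), tp_calls = sum(is_tp_call),
    sensitivity = if (nrow(truth)) mean(matched) else NA_real_,
    ppv = if (nrow(calls)) mean(is_tp_call) else NA_real_)

  structure(list(pooled = pooled, per_sample = per_sample, by_span = by_span,
                 truth_metric = metric, rule = rule,
                 quality_threshold = quality_threshold, cutoff = cutoff),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result (%s rule, q >= %g): sensitivity %.3f (%d/%d), PPV %s (%d calls)\n",
    x$rule, x$quality_threshold, x$pooled$sensitivity, x$pooled$tp,
    x$pooled$tp + x$pooled$fn,
    ifelse(is.na(x$pooled$ppv), "NA", sprintf("%.3f", x$pooled$ppv)),
    x$pooled$n_calls))
  invisible(x)
}

#' Choose a quality threshold by maximum F1
#'
#' Evaluates `F1 = 2 * sens * PPV / (sens + PPV)` at 10 evenly spaced
#' thresholds spanning the observed quality range (inclusive) and returns
#' the maximizing threshold; ties break toward the higher threshold.
#'
#' @param calls calls with a `quality` column (non-empty).
#' @param truth truth set.
#' @param rule matching rule, as in [score_calls()].
#' @return list with `best_threshold`, `best_f1`, and `curve` (data.frame
#'   of threshold, sensitivity, ppv, f1).
#' @export
optimize_quality_threshold <- function(calls, truth,
                                       rule = c("reciprocal",
                                                "target_jaccard")) {
  rule <- match.arg(rule)
  if (!nrow(calls)) stop("cannot optimize a threshold with no calls")
  qs <- seq(min(calls$quality), max(calls$quality), length.out = 10L)
  curve <- do.call(rbind, lapply(qs, function(q) {
    ev <- score_calls(calls, truth, rule, quality_threshold = q)
    sens <- ev$pooled$sensitivity; ppv <- ev$pooled$ppv
    f1 <- if (is.na(ppv) || is.na(sens) || sens + ppv == 0) 0
          else 2 * sens * ppv / (sens + ppv)
    data.frame(threshold = q, sensitivity = sens, ppv = ppv, f1 = f1)
  }))
  best <- max(which(curve$f1 == max(curve$f1)))
  list(best_threshold = curve$threshold[best], best_f1 = curve$f1[best],
       curve = curve)
}
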