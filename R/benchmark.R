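#' Run a spike-in benchmarking experiment
#'
#' The simulation study machinery in one call: build a truth set of CNVs of
#' the requested spans, spike them into the background samples, call CNVs
#' in every (spiked) sample with the supplied model, and score the calls
#' against the truth. Spiking into the background samples themselves
#' mirrors benchmark designs that inject simulated CNVs into the same
#' sample set that forms the reference panel.
#'
#' @param bg background [depth_matrix] the model was trained on.
#' @param model trained `cnv_model` over the same targets.
#' @param sizes data.frame of `span`/`count` pairs for [make_truth_set()].
#' @param coefficient spike coefficient (0.5 het-del, 1.5 het-dup, ...).
#' @param seed seed for truth-set placement.
#' @param alpha,beta,quality_threshold calling parameters (defaults as in
#'   [call_cnvs()]).
#' @param rule scoring rule for [score_calls()].
#' @return list: `eval` (an `eval_result`), `truth`, `calls`.
#' @export
run_spikein_experiment <- function(bg, model, sizes, coefficient, seed,
                                   alpha = 0.0025, beta = 0.0025,
                                   quality_threshold = 0.95,
                                   rule = c("reciprocal", "target_jaccard")) {
  rule <- match.arg(rule)
  stopifnot(inherits(bg, "depth_matrix"), inherits(model, "cnv_model"))
  truth <- make_truth_set(bg$targets, colnames(bg$counts), sizes,
                          coefficient, seed = seed)
  spiked <- spike_cnv(bg, truth)
  calls <- do.call(rbind, lapply(colnames(spiked$counts), function(sm) {
    q <- depth_matrix(spiked$targets,
                      spiked$counts[, sm, drop = FALSE], sm)
    call_cnvs(q, model, alpha = alpha, beta = beta,
              quality_threshold = quality_threshold)
  }))
  if (is.null(calls)) calls <- empty_calls()
  list(eval = score_calls(calls, truth, rule,
                          quality_threshold = quality_threshold),
       truth = truth, calls = calls)
}
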