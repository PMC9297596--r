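MODEL_FORMAT <- "rdcnv_model"
MODEL_VERSION <- 1L

#' Train a CNV model from background samples
#'
#' The training phase: partition the targets, fit the per-partition SVD
#' normalization basis on the centered log depths, and estimate per-target,
#' per-state Gaussian emission parameters by pseudo-CNV rescaling. The
#' result bundles everything prediction needs and can be persisted with
#' [save_model()].
#'
#' @param depths a [depth_matrix] of p >= 2 background ("control") samples.
#' @param v variance-explained threshold for rank selection (default 0.90).
#' @param j approximate partition size (default 1000).
#' @param states state coefficient table (default [default_states()]).
#' @param svd_method `"exact"` or `"randomized"`.
#' @param seed integer; seeds the randomized SVD sketch (exact SVD is
#'   deterministic regardless).
#' @param emission_method passed to [estimate_emissions()].
#' @return Object of class `cnv_model` with `targets`, `basis`,
#'   `emissions`, and a `config` record.
#' @export
train_model <- function(depths, v = 0.90, j = 1000L,
                        states = default_states(),
                        svd_method = c("exact", "randomized"),
                        seed = 1L,
                        emission_method = c("incremental", "reference")) {
  svd_method <- match.arg(svd_method)
  emission_method <- match.arg(emission_method)
  stopifnot(inherits(depths, "depth_matrix"))
  if (ncol(depths$counts) < 2L)
    stop("training requires at least 2 background samples")
  states <- validate_states(states)

  n <- nrow(depths$counts)
  parts <- partition_targets(n, j)
  X <- median_center(log_transform(depths$counts))
  basis <- fit_basis(X, v = v, partitions = parts, method = svd_method,
                     seed = seed)
  emissions <- estimate_emissions(depths, basis, states,
                                  method = emission_method)
  structure(list(targets = depths$targets,
                 basis = basis,
                 emissions = emissions,
                 config = list(v = v, j = as.integer(j),
                               svd_method = svd_method,
                               seed = as.integer(seed),
                               n_train = ncol(depths$counts),
                               package_version =
                                 as.character(utils::packageVersion("rdcnv")))),
            class = "cnv_model")
}

#' @export
print.cnv_model <- function(x, ...) {
  cat("cnv_model:", nrow(x$targets), "targets,",
      x$config$n_train, "background samples,",
      nrow(x$emissions$states), "states; v =", x$config$v,
      "j =", x$config$j, "\n")
  ks <- vapply(x$basis$per_partition, `[[`, integer(1), "k")
  cat("  partitions:", length(ks), " retained ranks:",
      paste(ks, collapse = ", "), "\n")
  invisible(x)
}

#' Persist / reload a trained model
#'
#' Single-file, versioned container (R serialization with a format tag).
#' The round trip is lossless: arrays are restored bit-exactly, so
#' predictions from a reloaded model are identical to those from the
#' in-memory one.
#'
#' @param model a `cnv_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnv_model"))
  payload <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
                  model = unclass(model))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `cnv_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable model file (", conditionMessage(e), "): ", path,
         call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, MODEL_FORMAT))
    stop("file is not an rdcnv model container: ", path)
  if (!identical(payload$version, MODEL_VERSION))
    stop("model file version ", payload$version,
         " is not supported by this build (expected ", MODEL_VERSION, ")")
  structure(payload$model, class = "cnv_model")
}
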