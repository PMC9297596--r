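#' Construct a multi-sample depth matrix
#'
#' Bundles a table of capture targets with an n x p matrix of non-negative
#' read counts (or mean depths), one row per target and one column per
#' sample. Targets are sorted into genome order (chromosomes in order of
#' first appearance, then start coordinate) and validated: coordinates are
#' 0-based half-open, `start < end`, and no two targets on the same
#' chromosome may overlap.
#'
#' @param targets data.frame with columns `chrom`, `start`, `end`.
#' @param counts numeric matrix, `nrow(targets)` rows, one column per sample.
#' @param sample_names character vector of unique sample names; defaults to
#'   `colnames(counts)` or `sample_1 ... sample_p`.
#' @return An object of class `depth_matrix`: a list with elements
#'   `targets` (sorted data.frame) and `counts` (matrix with sample names as
#'   column names).
#' @export
depth_matrix <- function(targets, counts, sample_names = NULL) {
  stopifnot(is.data.frame(targets),
            all(c("chrom", "start", "end") %in% names(targets)))
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != nrow(targets))
    stop("counts has ", nrow(counts), " rows but there are ",
         nrow(targets), " targets")
  if (nrow(targets) < 1L) stop("at least one target is required")
  if (ncol(counts) < 1L) stop("at least one sample is required")
  if (is.null(sample_names)) sample_names <- colnames(counts)
  if (is.null(sample_names))
    sample_names <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(sample_names))
    stop("sample names must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")

  targets <- data.frame(chrom = as.character(targets$chrom),
                        start = as.integer(targets$start),
                        end = as.integer(targets$end),
                        stringsAsFactors = FALSE)
  if (any(targets$start >= targets$end))
    stop("all targets must satisfy start < end")

  ord <- genome_order(targets)
  targets <- targets[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(targets) <- NULL
  check_no_overlap(targets)

  dimnames(counts) <- list(NULL, as.character(sample_names))
  structure(list(targets = targets, counts = counts),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("depth_matrix:", nrow(x$counts), "targets x", ncol(x$counts),
      "samples on", length(unique(x$targets$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.depth_matrix <- function(x) dim(x$counts)

# Genome sort order: chromosomes in order of first appearance, then start.
genome_order <- function(targets) {
  chrom_rank <- match(targets$chrom, unique(targets$chrom))
  order(chrom_rank, targets$start, targets$end)
}

check_no_overlap <- function(targets) {
  n <- nrow(targets)
  if (n < 2L) return(invisible(TRUE))
  same_chrom <- targets$chrom[-n] == targets$chrom[-1L]
  clash <- same_chrom & targets$end[-n] > targets$start[-1L]
  if (any(clash)) {
    i <- which(clash)[1L]
    stop(sprintf("overlapping targets: %s:%d-%d and %s:%d-%d",
                 targets$chrom[i], targets$start[i], targets$end[i],
                 targets$chrom[i + 1L], targets$start[i + 1L],
                 targets$end[i + 1L]))
  }
  invisible(TRUE)
}

#' Read a multi-sample depth matrix from a BED-with-counts file
#'
#' The expected dialect is tab-separated BED: columns `chrom`, `start`,
#' `end` (0-based half-open) followed by one numeric count column per
#' sample. An optional leading header line prefixed with `#` carries the
#' sample names in columns 4+. Rows are genome-sorted on read.
#'
#' @param path path to an existing BED file.
#' @return A [depth_matrix].
#' @export
read_depth_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty depth file: ", path)

  sample_names <- NULL
  if (startsWith(lines[1L], "#")) {
    hdr <- strsplit(sub("^#\\s*", "", lines[1L]), "\t")[[1L]]
    if (length(hdr) > 3L) sample_names <- hdr[-(1:3)]
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("depth file has a header but no data rows: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: row ", which(widths != widths[1L])[1L],
         " has ", widths[widths != widths[1L]][1L],
         " fields, expected ", widths[1L])
  if (widths[1L] < 4L)
    stop("rows must have chrom, start, end and at least one count column")

  m <- do.call(rbind, fields)
  p <- ncol(m) - 3L
  counts <- suppressWarnings(
    matrix(as.numeric(m[, -(1:3), drop = FALSE]), ncol = p))
  if (anyNA(counts)) {
    bad <- which(rowSums(is.na(counts)) > 0L)[1L]
    stop("non-numeric count in data row ", bad)
  }
  if (any(counts < 0)) {
    bad <- which(rowSums(counts < 0) > 0L)[1L]
    stop("negative count in data row ", bad)
  }
  starts <- suppressWarnings(as.integer(m[, 2L]))
  ends <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(starts) || anyNA(ends))
    stop("non-integer coordinate in data row ",
         which(is.na(starts) | is.na(ends))[1L])

  if (!is.null(sample_names) && length(sample_names) != p)
    stop("header names ", length(sample_names),
         " samples but rows carry ", p, " count columns")

  depth_matrix(data.frame(chrom = m[, 1L], start = starts, end = ends,
                          stringsAsFactors = FALSE),
               counts, sample_names)
}

#' Write a depth matrix to a BED-with-counts file
#'
#' Emits the tab-separated dialect read by [read_depth_bed()], with a
#' `#chrom start end sample...` header line. Counts round-trip exactly
#' (written with full precision).
#'
#' @param x a [depth_matrix].
#' @param path output path.
#' @export
write_depth_bed <- function(x, path) {
  stopifnot(inherits(x, "depth_matrix"))
  if (ncol(x$counts) == 0L) stop("no samples to write")
  header <- paste0("#", paste(c("chrom", "start", "end",
                                colnames(x$counts)), collapse = "\t"))
  count_txt <- apply(x$counts, 1L, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  rows <- paste(x$targets$chrom, x$targets$start, x$targets$end,
                count_txt, sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Assign targets to strided partitions
#'
#' Targets are split into `ceiling(n / j)` partitions for independent SVD
#' normalization. Assignment is strided -- target `i` (0-based) goes to
#' partition `i mod num_partitions` -- so partition sizes differ by at most
#' one and adjacent targets always land in different partitions. Keeping
#' neighbours apart matters: a CNV spanning much of one partition would
#' otherwise surface as a top singular vector and be normalized away.
#'
#' @param n number of targets.
#' @param j approximate partition size (default 1000).
#' @return A list of class `partition_assignment` with `partition_of`
#'   (length-n integer vector of 0-based partition ids), `num_partitions`
#'   and `partition_size_j`.
#' @export
partition_targets <- function(n, j = 1000L) {
  stopifnot(n >= 1L, j >= 1L)
  m <- as.integer(ceiling(n / j))
  structure(list(partition_of = as.integer((seq_len(n) - 1L) %% m),
                 num_partitions = m,
                 partition_size_j = as.integer(j)),
            class = "partition_assignment")
}
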