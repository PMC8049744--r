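#' Construct a CountExperiment
#'
#' A `CountExperiment` is the common substrate for RNA-seq and ATAC-seq
#' testing: an integer feature-by-sample count matrix together with the
#' per-sample design metadata (regenerating structure, timepoint in hours
#' post amputation, treatment arm, replicate id).
#'
#' @param counts Integer matrix, features in rows, samples in columns.
#'   Dimnames are required and must be unique.
#' @param design `data.frame` with one row per sample and columns
#'   `sample`, `structure` (`"H"` or `"F"`), `timepoint` (hours post
#'   amputation), `treatment` (`"untreated"` or `"iCRT14"`), `replicate`.
#'
#' @return An object of class `CountExperiment`.
#' @export
count_experiment <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature and sample names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample", "structure", "timepoint", "treatment", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0)
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(design$sample, colnames(counts)) ||
      nrow(design) != ncol(counts))
    stop("design must cover every sample in the count matrix exactly once")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  ## canonical column types so that disk round-trips are exact
  design$sample <- as.character(design$sample)
  design$structure <- as.character(design$structure)
  design$treatment <- as.character(design$treatment)
  design$timepoint <- as.numeric(design$timepoint)
  design$replicate <- as.integer(design$replicate)
  structure(list(counts = counts, design = design),
            class = "CountExperiment")
}

#' @export
print.CountExperiment <- function(x, ...) {
  cat(sprintf("CountExperiment: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("design cells: ",
      paste(sort(unique(design_group(x))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountExperiment <- function(x) dim(x$counts)

#' Per-sample design-cell label
#'
#' Concatenates structure, timepoint and treatment into one factor label
#' per sample (e.g. `"H.3.untreated"`), the grouping used throughout the
#' differential-testing design matrices.
#'
#' @param exp A [count_experiment()].
#' @return Character vector, one label per sample.
#' @export
design_group <- function(exp) {
  with(exp$design, paste(structure, timepoint, treatment, sep = "."))
}

#' Subset a CountExperiment by features and/or samples
#'
#' @param exp A [count_experiment()].
#' @param features Feature ids or index vector (default all).
#' @param samples Sample ids or index vector (default all).
#' @return A new `CountExperiment`.
#' @export
subset_experiment <- function(exp, features = NULL, samples = NULL) {
  counts <- exp$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  design <- exp$design[match(colnames(counts), exp$design$sample), ,
                       drop = FALSE]
  count_experiment(counts, design)
}
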