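## File formats: TSV count matrices + sample sheets, narrowPeak/BED6
## intervals, JASPAR-like PWM text.  All genomic coordinates are 0-based
## half-open (BED convention): width = end - start.

#' Read a count matrix and sample sheet into a CountExperiment
#'
#' The count matrix is tab-separated with feature ids in the first column
#' and one column per sample; the sample sheet is tab-separated with
#' columns `sample`, `structure`, `timepoint`, `treatment`, `replicate`.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the count matrix TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return A [count_experiment()].
#' @export
read_counts <- function(path, sample_sheet_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  features <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(features, colnames(mat))))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed numeric '%s' at feature '%s', sample '%s'",
                 mat[bad[1, 1], bad[1, 2]], features[bad[1, 1]],
                 colnames(mat)[bad[1, 2]]))
  sheet <- utils::read.table(sample_sheet_path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(colnames(num), sheet$sample)
  if (length(missing) > 0)
    stop("samples in matrix missing from sample sheet: ",
         paste(missing, collapse = ", "))
  count_experiment(num, sheet[sheet$sample %in% colnames(num), ])
}

#' Write a CountExperiment to a count matrix TSV and sample sheet TSV
#'
#' Inverse of [read_counts()]: writing then reading yields an identical
#' object.
#'
#' @param exp A [count_experiment()].
#' @param path Output path for the count matrix.
#' @param sample_sheet_path Output path for the sample sheet.
#' @export
write_counts <- function(exp, path, sample_sheet_path) {
  tab <- data.frame(feature = rownames(exp$counts), exp$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(exp$design, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(exp)
}

#' Construct a PeakSet
#'
#' A plain-data.frame genomic interval container in the narrowPeak dialect:
#' 0-based half-open coordinates, optional summit offset (-1 when absent).
#'
#' @param chrom,start,end,name,score,strand,summit_offset Vectors as in
#'   BED6+4; `strand` one of `+`, `-`, `.`.
#' @return A `data.frame` of class `PeakSet`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     strand = ".", summit_offset = -1L) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(start >= end))
    stop("invalid interval: require 0 <= start < end")
  summit_offset <- as.integer(rep_len(summit_offset, n))
  if (any(summit_offset >= end - start))
    stop("summit_offset must be < width or -1")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = as.character(name),
                   score = as.numeric(rep_len(score, n)),
                   strand = as.character(rep_len(strand, n)),
                   summit_offset = summit_offset,
                   stringsAsFactors = FALSE)
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' Read a narrowPeak or BED6 file
#'
#' Ten-column files preserve the summit offset (column 10); six-column
#' files get `summit_offset = -1`.
#'
#' @param path Path to a tab-separated BED6 or narrowPeak (BED6+4) file.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 6)
    stop("expected at least 6 tab-separated columns, got ", ncol(tab))
  if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]]))
    stop("non-numeric coordinates")
  summit <- if (ncol(tab) >= 10) as.integer(tab[[10]]) else -1L
  peak_set(tab[[1]], tab[[2]], tab[[3]], tab[[4]], as.numeric(tab[[5]]),
           tab[[6]], summit)
}

#' Write a PeakSet as narrowPeak (BED6+4)
#'
#' signalValue (column 7) carries the score; pValue and qValue columns are
#' written as -1 (not computed here).
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    peaks$score, peaks$strand, peaks$score, -1, -1,
                    peaks$summit_offset)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(peaks)
}

#' Write gene models as BED6
#'
#' @param genes `data.frame` with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; the interval start is used as the TSS proxy
#'   downstream.
#' @param path Output path.
#' @export
write_bed6 <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "name", "score",
                               "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(genes)
}

#' Read BED6 gene models
#'
#' @param path Path to a BED6 file.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("expected 6 columns")
  names(tab)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(tab$start >= tab$end)) stop("invalid interval: start >= end")
  tab[, 1:6]
}

#' Construct a MotifModel (position weight matrix)
#'
#' @param id Motif identifier.
#' @param matrix 4 x L matrix of base probabilities or counts, rows
#'   A, C, G, T. Counts are converted to probabilities after adding
#'   `pseudocount` to every cell.
#' @param background Base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Added to every cell before normalisation of count
#'   matrices and before taking log-odds.
#' @return An object of class `MotifModel`.
#' @export
motif_model <- function(id, matrix, background = rep(0.25, 4),
                        pseudocount = 0.008) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) stop("motif length must be >= 4")
  cs <- colSums(matrix)
  if (any(cs == 0)) stop("PWM column sums to zero")
  if (any(abs(cs - 1) > 1e-6)) {      # count matrix: smooth + normalise
    matrix <- sweep(matrix + pseudocount, 2, cs + 4 * pseudocount, "/")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(id = id, matrix = matrix,
                 background = background / sum(background),
                 pseudocount = pseudocount),
            class = "MotifModel")
}

#' Read JASPAR-like PWM files
#'
#' Accepts blocks of the form
#' ```
#' >MOTIF_ID
#' A [ 10  0  3 ... ]
#' C [  0 12  1 ... ]
#' G [ ... ]
#' T [ ... ]
#' ```
#' with or without the base letter and brackets. Counts are converted to
#' probabilities with pseudocount smoothing; already-normalised
#' probability columns are kept as-is.
#'
#' @param path Path to the motif file.
#' @param pseudocount Passed to [motif_model()].
#' @return Named list of `MotifModel` objects.
#' @export
read_pwm <- function(path, pseudocount = 0.008) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif headers ('>') found")
  ends <- c(starts[-1] - 1, length(lines))
  motifs <- list()
  for (i in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1):ends[i]]
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(rows) != 4) stop("motif '", id, "' needs 4 base rows")
    lens <- vapply(rows, length, 1L)
    if (length(unique(lens)) != 1)
      stop("ragged matrix for motif '", id, "'")
    motifs[[id]] <- motif_model(id, do.call(rbind, rows),
                                pseudocount = pseudocount)
  }
  motifs
}

#' Write motifs in the same JASPAR-like layout read by [read_pwm()]
#'
#' @param motifs Named list of [motif_model()] objects.
#' @param path Output path.
#' @export
write_pwm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste(b, "[", paste(sprintf("%.6f", m$matrix[b, ]),
                                     collapse = " "), "]"), con)
    }
  }
  invisible(motifs)
}
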