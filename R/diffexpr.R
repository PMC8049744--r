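## Differential testing of RNA-seq and ATAC-seq count experiments:
## CPM filtering, TMM normalisation, NB quasi-likelihood GLM fits and
## contrasts (via edgeR), BH adjustment, the regeneration context-effect
## contrast, TCF-dependence classification, and the single-cell
## Wilcoxon structural-enrichment test.
##
## Default thresholds are the study's: FDR <= 1e-3 (RNA), 1e-4 (ATAC);
## filters >= 2 CPM in >= 3 samples (RNA), >= 10 CPM in >= 3 (ATAC);
## single-cell adjusted p <= 1e-6.

#' Counts per million
#'
#' @param counts Count matrix.
#' @param lib_sizes Effective library sizes (default: column sums).
#' @return Matrix of CPM values.
#' @export
cpm_matrix <- function(counts, lib_sizes = colSums(counts)) {
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Filter features on a minimum-CPM rule
#'
#' A feature is kept iff its CPM is `>= min_cpm` (inclusive boundary) in
#' at least `min_samples` samples. Defaults are the RNA-seq rule
#' (2 CPM in 3 samples); use `min_cpm = 10` for ATAC peaks.
#'
#' @param exp A [count_experiment()].
#' @param min_cpm Minimum counts-per-million (> 0).
#' @param min_samples Minimum number of samples meeting `min_cpm`.
#' @return Character vector of kept feature ids.
#' @export
filter_features <- function(exp, min_cpm = 2, min_samples = 3) {
  if (min_cpm <= 0) stop("min_cpm must be > 0")
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (min_samples > ncol(exp$counts))
    stop("min_samples exceeds the number of samples")
  cpm <- cpm_matrix(exp$counts)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  rownames(exp$counts)[keep]
}

#' Trimmed mean of M-values (TMM) normalisation factors
#'
#' Computes per-sample scaling factors by the TMM method: for each
#' sample vs the reference, gene-wise log-ratios (M) are trimmed by 30%
#' on each side and log-intensities (A) by 5% on each side, and the
#' factor is the precision-weighted mean of the surviving M-values.
#' Factors are re-centred to geometric mean 1.
#'
#' @param exp A [count_experiment()] (>= 2 samples, no all-zero sample).
#' @param reference Reference sample id, or `"auto"` to pick the sample
#'   whose upper-quartile CPM is closest to the mean upper quartile.
#' @param logratio_trim,abundance_trim Two-sided trim fractions.
#' @return Named numeric vector of normalisation factors.
#' @export
tmm_factors <- function(exp, reference = "auto", logratio_trim = 0.30,
                        abundance_trim = 0.05) {
  counts <- exp$counts
  if (ncol(counts) < 2) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample: ", colnames(counts)[which(lib == 0)[1]])
  if (identical(reference, "auto")) {
    uq <- apply(cpm_matrix(counts), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(reference, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim,
                      abundance_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  if (max(abs(m)) < 1e-6) return(1)
  ## asymptotic (delta-method) variance of M
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
           rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Normalise a CountExperiment
#'
#' Attaches TMM factors, effective library sizes and the CPM matrix.
#'
#' @param exp A [count_experiment()].
#' @param ... Passed to [tmm_factors()].
#' @return A list of class `NormalizedExperiment` with fields
#'   `experiment`, `norm_factors`, `effective_lib_size`, `cpm`.
#' @export
normalize_experiment <- function(exp, ...) {
  nf <- tmm_factors(exp, ...)
  eff <- colSums(exp$counts) * nf
  structure(list(experiment = exp, norm_factors = nf,
                 effective_lib_size = eff,
                 cpm = cpm_matrix(exp$counts, eff)),
            class = "NormalizedExperiment")
}

#' Design matrix of design-cell means
#'
#' One indicator column per structure.timepoint.treatment cell
#' (no-intercept group-means parameterisation), used for all contrasts.
#'
#' @param design Per-sample design `data.frame` (see
#'   [count_experiment()]).
#' @return Design matrix with syntactic group column names.
#' @export
group_design <- function(design) {
  grp <- factor(paste(design$structure, design$timepoint,
                      design$treatment, sep = "."))
  mm <- stats::model.matrix(~ 0 + grp)
  colnames(mm) <- levels(grp)
  rownames(mm) <- design$sample
  mm
}

#' Fit the NB quasi-likelihood GLM
#'
#' Fits, per feature, a negative-binomial log-linear model with
#' log(effective library size) offsets; tagwise dispersions are shrunk
#' toward the trend by empirical Bayes with `prior_df`, and
#' quasi-dispersions are moderated across features (edgeR's
#' quasi-likelihood pipeline).
#'
#' @param nexp A [normalize_experiment()] result, optionally subset to
#'   filtered features first.
#' @param design Design matrix (e.g. [group_design()]); must be full
#'   rank with >= 1 residual df.
#' @param features Optional feature subset to fit (default all).
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @return A list of class `NbQlFit` wrapping the edgeR fit.
#' @export
fit_nb_ql <- function(nexp, design, features = NULL, prior_df = 10) {
  exp <- nexp$experiment
  counts <- exp$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank-deficient")
  if (nrow(design) - ncol(design) < 1) stop("zero residual degrees of freedom")
  y <- edgeR::DGEList(counts = counts, lib.size = colSums(exp$counts),
                      norm.factors = nexp$norm_factors)
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
  fit <- edgeR::glmQLFit(y, design)
  structure(list(fit = fit, design = design), class = "NbQlFit")
}

#' Quasi-likelihood F-test of a contrast
#'
#' @param fit A [fit_nb_ql()] result.
#' @param contrast Numeric contrast vector conformable with the design
#'   (or a named specification resolved against its column names).
#' @param name Contrast label carried into the result.
#' @return `data.frame` of class `DifferentialResult` with columns
#'   `feature`, `log2FC`, `F`, `p`, `fdr`, `contrast`.
#' @export
ql_test <- function(fit, contrast, name = "contrast") {
  if (length(contrast) == 0) stop("zero-length contrast")
  if (all(contrast == 0)) stop("contrast is the zero vector")
  res <- edgeR::glmQLFTest(fit$fit, contrast = contrast)
  tab <- res$table
  out <- data.frame(feature = rownames(tab), log2FC = tab$logFC,
                    F = tab$F, p = tab$PValue,
                    fdr = bh_adjust(tab$PValue), contrast = name,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$feature
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR), in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Named contrast between two design cells
#'
#' @param design_mat A [group_design()] matrix.
#' @param plus,minus Column names receiving +1 and -1.
#' @return Numeric contrast vector.
#' @export
cell_contrast <- function(design_mat, plus, minus) {
  cols <- colnames(design_mat)
  bad <- setdiff(c(plus, minus), cols)
  if (length(bad) > 0)
    stop("unknown design cells: ", paste(bad, collapse = ", "))
  ctr <- stats::setNames(numeric(length(cols)), cols)
  ctr[plus] <- ctr[plus] + 1
  ctr[minus] <- ctr[minus] - 1
  ctr
}

#' Injury-response test: timepoint vs 0 hpa within one structure
#'
#' @param fit A [fit_nb_ql()] result on a [group_design()] matrix.
#' @param structure `"H"` or `"F"`.
#' @param timepoint Timepoint in hpa.
#' @param treatment Treatment arm.
#' @return A [ql_test()] result named `injury_<structure>_<t>v0`.
#' @export
injury_response <- function(fit, structure, timepoint,
                            treatment = "untreated") {
  ctr <- cell_contrast(fit$design,
                       paste(structure, timepoint, treatment, sep = "."),
                       paste(structure, 0, treatment, sep = "."))
  ql_test(fit, ctr, sprintf("injury_%s_%sv0", structure, timepoint))
}

#' Regeneration context effect at a timepoint
#'
#' For every feature, `delta` is the head-regeneration log2FC (t vs
#' 0 hpa) minus the foot-regeneration log2FC (t vs 0 hpa); a positive
#' delta means head-regeneration-specific. The head/foot difference is
#' tested with the QL F-test on the difference-of-differences contrast
#' `(H_t - H_0) - (F_t - F_0)`, and features are called
#' head-/foot-regeneration-specific at `fdr_cut`.
#'
#' @param fit A [fit_nb_ql()] on a [group_design()] covering both
#'   structures at `timepoint` and 0 hpa.
#' @param timepoint Timepoint in hpa (> 0).
#' @param treatment Treatment arm.
#' @param fdr_cut Significance threshold (1e-3 RNA, 1e-4 ATAC).
#' @return `data.frame` of class `ContextEffect`: `feature`, `delta`,
#'   `lfc_head`, `lfc_foot`, `interaction_p`, `interaction_fdr`, `call`
#'   (`"head"`, `"foot"`, `"none"`).
#' @export
context_effect <- function(fit, timepoint, treatment = "untreated",
                           fdr_cut = 1e-3) {
  cells <- c(paste("H", timepoint, treatment, sep = "."),
             paste("H", 0, treatment, sep = "."),
             paste("F", timepoint, treatment, sep = "."),
             paste("F", 0, treatment, sep = "."))
  missing <- setdiff(cells, colnames(fit$design))
  if (length(missing) > 0)
    stop("missing design cells: ", paste(missing, collapse = ", "))
  head_res <- ql_test(fit, cell_contrast(fit$design, cells[1], cells[2]),
                      "head")
  foot_res <- ql_test(fit, cell_contrast(fit$design, cells[3], cells[4]),
                      "foot")
  inter <- ql_test(fit,
                   cell_contrast(fit$design, cells[c(1, 4)],
                                 cells[c(2, 3)]),
                   sprintf("context_%s", timepoint))
  delta <- head_res$log2FC - foot_res$log2FC
  call <- ifelse(inter$fdr <= fdr_cut & delta > 0, "head",
                 ifelse(inter$fdr <= fdr_cut & delta < 0, "foot", "none"))
  out <- data.frame(feature = inter$feature, delta = delta,
                    lfc_head = head_res$log2FC,
                    lfc_foot = foot_res$log2FC,
                    interaction_p = inter$p, interaction_fdr = inter$fdr,
                    call = call, stringsAsFactors = FALSE)
  rownames(out) <- out$feature
  class(out) <- c("ContextEffect", "data.frame")
  out
}

#' Classify transcripts as TCF-dependent or TCF-inhibited
#'
#' TCF-dependent: not significantly upregulated after injury under
#' iCRT14, and a significant reduction of the injury-induced response
#' relative to untreated animals. TCF-inhibited: significantly
#' upregulated under iCRT14, and a significant increase relative to
#' untreated. Everything else is unclassified. All three calls use the
#' same FDR threshold.
#'
#' @param untreated,icrt [ql_test()] results for the injury response
#'   (t vs 0 hpa) in the untreated and iCRT14 arms, same features.
#' @param cross [ql_test()] result for the treatment-by-injury
#'   interaction `(iCRT14_t - iCRT14_0) - (untreated_t - untreated_0)`;
#'   negative log2FC = reduction under iCRT14.
#' @param fdr_cut Significance threshold (default 1e-3).
#' @return `data.frame` of class `TcfClass` with `feature` and `label`
#'   in `{"TCF-dependent", "TCF-inhibited", "unclassified"}`.
#' @export
classify_tcf <- function(untreated, icrt, cross, fdr_cut = 1e-3) {
  if (!identical(untreated$feature, icrt$feature) ||
      !identical(untreated$feature, cross$feature))
    stop("result sets must cover the same features in the same order")
  up_icrt <- icrt$fdr <= fdr_cut & icrt$log2FC > 0
  reduced <- cross$fdr <= fdr_cut & cross$log2FC < 0
  increased <- cross$fdr <= fdr_cut & cross$log2FC > 0
  label <- ifelse(!up_icrt & reduced, "TCF-dependent",
                  ifelse(up_icrt & increased, "TCF-inhibited",
                         "unclassified"))
  out <- data.frame(feature = untreated$feature, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("TcfClass", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when `min(n) <= 25` and there are no ties;
#' otherwise the normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && min(nx, ny) <= 25) {
    return(stats::wilcox.test(x, y, exact = TRUE,
                              correct = FALSE)$p.value)
  }
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U
  mu <- nx * ny / 2
  tie_tab <- table(r)
  n <- nx + ny
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 == 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Head/foot structural enrichment from single-cell counts
#'
#' Per-gene two-sided Wilcoxon rank-sum test between the head and foot
#' epithelial clusters, BH adjustment, calls at `p_cut` (adjusted), and
#' the log2 ratio of cluster mean expression ("SC atlas structural
#' enrichment"; positive = head-enriched).
#'
#' @param counts Gene x cell count matrix.
#' @param clusters `"head"`/`"foot"` label per cell; both clusters need
#'   >= 2 cells.
#' @param p_cut Adjusted-p cutoff (default 1e-6).
#' @return `data.frame` with `gene`, `log2FC`, `p`, `padj`, `call`.
#' @export
structural_enrichment <- function(counts, clusters, p_cut = 1e-6) {
  ih <- which(clusters == "head"); if_ <- which(clusters == "foot")
  if (length(ih) < 2 || length(if_) < 2)
    stop("each cluster needs >= 2 cells")
  p <- vapply(seq_len(nrow(counts)), function(g) {
    wilcoxon_p(counts[g, ih], counts[g, if_])
  }, numeric(1))
  mh <- rowMeans(counts[, ih, drop = FALSE])
  mf <- rowMeans(counts[, if_, drop = FALSE])
  lfc <- log2((mh + 1e-9) / (mf + 1e-9))
  lfc[mh == mf] <- 0
  padj <- bh_adjust(p)
  data.frame(gene = rownames(counts), log2FC = lfc, p = p, padj = padj,
             call = ifelse(padj <= p_cut,
                           ifelse(lfc > 0, "head", "foot"), "none"),
             stringsAsFactors = FALSE)
}

#' Write differential results as TSV
#'
#' @param res A `DifferentialResult` (or any data.frame).
#' @param path Output path.
#' @export
write_results <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}
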