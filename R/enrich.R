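## Enrichment statistics and the candidate-TF screen: exact
## hypergeometric upper-tail tests (log-gamma arithmetic), peak-to-gene
## assignment, peak/gene concordance, per-motif Fisher enrichment, and
## the four-criteria screen for injury-responsive transcription factors.

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed by direct
#' summation of log-gamma terms.
#'
#' @param k Overlap count.
#' @param K Successes in the universe.
#' @param n Draws.
#' @param N Universe size.
#' @return Upper-tail probability.
#' @keywords internal
hyper_upper_tail <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, max(0, n + K - N)):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Hypergeometric enrichment of one set in another
#'
#' Tests whether `set_a` is enriched for members of `set_b` within a
#' shared universe: `k = |a intersect b|`, fold = `k / (n K / N)`, and
#' the exact upper-tail p-value `P(X >= k)`.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all tested items.
#' @return A list of class `EnrichmentResult`: `k`, `n`, `K`, `N`,
#'   `fold`, `p`.
#' @export
hypergeom_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  k <- length(intersect(set_a, set_b))
  n <- length(set_a); K <- length(set_b); N <- length(universe)
  expected <- n * K / N
  structure(list(k = k, n = n, K = K, N = N,
                 fold = if (expected > 0) k / expected else NA_real_,
                 p = hyper_upper_tail(k, K, n, N)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: k=%d of n=%d vs K=%d in N=%d; fold=%.3g, p=%.3g\n",
    x$k, x$n, x$K, x$N, x$fold, x$p))
  invisible(x)
}

#' Assign peaks to genes
#'
#' A peak is assigned to the gene whose body it overlaps (ties: the
#' gene with the lower start coordinate); otherwise to the gene with
#' the nearest start (the TSS proxy) within `max_distance`; otherwise
#' it stays unassigned.
#'
#' @param peaks A [peak_set()].
#' @param genes Gene models (`chrom`, `start`, `end`, `name`).
#' @param max_distance Maximum peak-to-TSS distance in bp.
#' @return `data.frame` with `peak`, `gene` (NA if unassigned),
#'   `distance` (0 for body overlap).
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_distance = 20000) {
  gene <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    hits <- as.data.frame(IRanges::findOverlaps(
      IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]),
      IRanges::IRanges(g$start + 1L, g$end)))
    if (nrow(hits) > 0) {
      hits <- hits[order(hits$queryHits, g$start[hits$subjectHits]), ,
                   drop = FALSE]
      first <- hits[!duplicated(hits$queryHits), , drop = FALSE]
      gene[pi[first$queryHits]] <- g$name[first$subjectHits]
      distance[pi[first$queryHits]] <- 0
    }
    todo <- pi[is.na(gene[pi])]
    if (length(todo) == 0) next
    starts <- g$start
    for (p in todo) {
      lo <- findInterval(peaks$start[p], starts)
      cand <- unique(pmin(pmax(c(lo, lo + 1), 1), length(starts)))
      d <- vapply(cand, function(ci) {
        s <- starts[ci]
        if (s >= peaks$start[p] && s < peaks$end[p]) 0
        else min(abs(s - peaks$start[p]), abs(s - (peaks$end[p] - 1L)))
      }, numeric(1))
      ord <- order(d, starts[cand])
      if (d[ord[1]] <= max_distance) {
        gene[p] <- g$name[cand[ord[1]]]
        distance[p] <- d[ord[1]]
      }
    }
  }
  data.frame(peak = peaks$name, gene = gene, distance = distance,
             stringsAsFactors = FALSE)
}

#' Concordance between structure-specific peaks and genes
#'
#' Tests whether structure-specific ATAC peaks are enriched among peaks
#' assigned to structure-specific genes: `set_a` = the structure-
#' specific peaks, `set_b` = universe peaks mapped to a structure-
#' specific gene, universe = all tested peaks.
#'
#' @param structure_peaks Structure-specific peak ids (subset of
#'   `universe`).
#' @param structure_genes Structure-specific gene ids.
#' @param mapping [assign_peaks_to_genes()] result covering the
#'   universe.
#' @param universe All tested peak ids.
#' @return An `EnrichmentResult`.
#' @export
peak_gene_concordance <- function(structure_peaks, structure_genes,
                                  mapping, universe) {
  if (length(structure_peaks) == 0 || length(structure_genes) == 0)
    stop("empty structure-specific set")
  near <- mapping$peak[!is.na(mapping$gene) &
                         mapping$gene %in% structure_genes]
  hypergeom_enrichment(intersect(structure_peaks, universe),
                       intersect(near, universe), universe)
}

#' Per-motif enrichment in a target peak set
#'
#' One-sided Fisher exact test, per motif, of the 2x2 table motif
#' presence x target membership, against disjoint background peaks;
#' fold is the ratio of presence fractions; BH across motifs.
#'
#' @param target_peaks,background_peaks Disjoint peak id vectors.
#' @param annotation A [motif_annotation()] whose placement matrix rows
#'   are named by peak id.
#' @return `data.frame` with `motif`, `k_target`, `n_target`,
#'   `k_background`, `n_background`, `fold`, `p`, `fdr`.
#' @export
motif_enrichment_in_peaks <- function(target_peaks, background_peaks,
                                      annotation) {
  if (length(intersect(target_peaks, background_peaks)) > 0)
    stop("target and background peaks must be disjoint")
  A <- annotation$matrix
  tg <- A[intersect(target_peaks, rownames(A)), , drop = FALSE]
  bg <- A[intersect(background_peaks, rownames(A)), , drop = FALSE]
  n_t <- nrow(tg); n_b <- nrow(bg)
  a <- colSums(tg); c_ <- colSums(bg)
  if (any(a + c_ == 0))
    stop("motif absent from all peaks: ",
         paste(colnames(A)[a + c_ == 0], collapse = ", "))
  p <- vapply(seq_along(a), function(i) {
    hyper_upper_tail(a[i], a[i] + c_[i], n_t, n_t + n_b)
  }, numeric(1))
  frac_b <- c_ / n_b
  fold <- ifelse(frac_b > 0, (a / n_t) / frac_b, Inf)
  data.frame(motif = colnames(A), k_target = a, n_target = n_t,
             k_background = c_, n_background = n_b, fold = fold,
             p = p, fdr = bh_adjust(p), stringsAsFactors = FALSE,
             row.names = colnames(A))
}

#' Four-criteria screen for candidate injury-response TFs
#'
#' A motif is a candidate regulator iff (1) its accessibility increases
#' significantly at 3 hpa in both regenerating structures, (2) at least
#' one TF that can plausibly bind it is significantly upregulated at
#' 3 hpa in both structures, (3) it is significantly enriched in peaks
#' gaining accessibility at 3 hpa, and (4) it has at least one hit in a
#' peak assigned to one of the queried (Wnt-component) genes.
#'
#' @param sig_motifs List with elements `H` and `F`:
#'   [significant_motifs()] results at 3 hpa per structure.
#' @param tf_de List with elements `H` and `F`: [ql_test()] injury-
#'   response results at 3 hpa per structure.
#' @param motif_enrichment A [motif_enrichment_in_peaks()] result.
#' @param promoter_hits Logical peak x motif hit matrix (e.g. PWM scan
#'   hits, or planted placements in the synthetic world).
#' @param peak_genes [assign_peaks_to_genes()] mapping.
#' @param wnt_genes Non-empty character vector of queried gene ids.
#' @param motif_tf_map `data.frame` with columns `motif`, `tf` mapping
#'   every screened motif to candidate binding TFs.
#' @param tf_fdr FDR threshold for TF upregulation (default 1e-3).
#' @param enrich_fdr FDR threshold for criterion 3 (default 0.05).
#' @return `data.frame` of class `ScreenTable`: `motif`,
#'   `accessibility_up`, `tf_up`, `enriched`, one `near_<gene>` column
#'   per queried gene, `candidate`.
#' @export
run_screen <- function(sig_motifs, tf_de, motif_enrichment,
                       promoter_hits, peak_genes, wnt_genes,
                       motif_tf_map, tf_fdr = 1e-3, enrich_fdr = 0.05) {
  if (length(wnt_genes) == 0) stop("wnt_genes must be non-empty")
  motifs <- motif_enrichment$motif
  unmapped <- setdiff(motifs, motif_tf_map$motif)
  if (length(unmapped) > 0)
    stop("motifs missing from motif_tf_map: ",
         paste(unmapped, collapse = ", "))
  acc_up <- vapply(motifs, function(m) {
    all(vapply(sig_motifs, function(s) {
      row <- s[s$motif == m, ]
      nrow(row) == 1 && row$significant && row$direction == "increased"
    }, logical(1)))
  }, logical(1))
  tf_up <- vapply(motifs, function(m) {
    tfs <- motif_tf_map$tf[motif_tf_map$motif == m]
    if (length(tfs) == 0) return(FALSE)
    all(vapply(tf_de, function(d) {
      rows <- d[d$feature %in% tfs, , drop = FALSE]
      any(rows$fdr <= tf_fdr & rows$log2FC > 0)
    }, logical(1)))
  }, logical(1))
  enriched <- motif_enrichment$fdr <= enrich_fdr &
    motif_enrichment$fold > 1
  presence <- sapply(wnt_genes, function(g) {
    gp <- peak_genes$peak[!is.na(peak_genes$gene) & peak_genes$gene == g]
    gp <- intersect(gp, rownames(promoter_hits))
    if (length(gp) == 0) return(rep(FALSE, length(motifs)))
    colSums(promoter_hits[gp, motifs, drop = FALSE]) > 0
  })
  presence <- matrix(presence, nrow = length(motifs),
                     dimnames = list(motifs, paste0("near_", wnt_genes)))
  out <- data.frame(motif = motifs, accessibility_up = acc_up,
                    tf_up = tf_up, enriched = enriched,
                    presence,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$candidate <- acc_up & tf_up & enriched & rowSums(presence) > 0
  class(out) <- c("ScreenTable", "data.frame")
  out
}
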