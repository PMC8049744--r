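## Motif machinery: PWM log-odds scanning on both strands, fixed-width
## peak re-centring, chromVAR-style bias-corrected deviation z-scores
## with background peaks matched on (GC, mean count), per-motif
## significance calls, and motif-redundancy clustering.

.base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

logodds_matrix <- function(motif) {
  p <- (motif$matrix + motif$pseudocount) /
    (1 + 4 * motif$pseudocount)
  log2(sweep(p, 1, motif$background, "/"))
}

revcomp_matrix <- function(m) m[4:1, ncol(m):1, drop = FALSE]

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the log2-odds of the motif
#' versus its background; positions containing `N` contribute 0
#' (background odds). An offset is a hit iff its score is at least
#' `threshold` times the maximum achievable score. Motifs whose maximum
#' achievable score is not positive (e.g. a uniform PWM on a uniform
#' background) yield no hits.
#'
#' @param sequence Character scalar over `A C G T N`.
#' @param motif A [motif_model()].
#' @param threshold Fraction of the maximum log-odds score in `(0, 1]`.
#' @param both_strands Also scan the reverse complement (reported on
#'   forward coordinates with `strand = "-"`).
#' @return `data.frame` with `position` (1-based offset of the match
#'   start on the forward strand), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, motif, threshold = 0.8,
                     both_strands = TRUE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  s <- .base_idx[strsplit(toupper(sequence), "")[[1]]]
  if (anyNA(s)) stop("sequence contains characters outside {A,C,G,T,N}")
  lo <- logodds_matrix(motif)
  L <- ncol(lo)
  if (L > length(s)) stop("motif longer than sequence")
  max_score <- sum(apply(lo, 2, max))
  if (max_score <= 0)
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  mats <- list("+" = lo)
  if (both_strands) mats[["-"]] <- revcomp_matrix(lo)
  n_off <- length(s) - L + 1
  out <- lapply(names(mats), function(st) {
    m <- mats[[st]]
    sc <- vapply(seq_len(n_off), function(i) {
      b <- s[i:(i + L - 1)]
      sum(m[cbind(b, seq_len(L))[b > 0, , drop = FALSE]])
    }, numeric(1))
    hit <- sc >= threshold * max_score
    data.frame(position = which(hit), strand = st, score = sc[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Re-centre peaks at a fixed width
#'
#' Each peak is re-centred on its summit (its midpoint when
#' `summit_offset` is -1) and resized to exactly `width` bp; peaks
#' running off the chromosome are clipped with a warning and flagged.
#'
#' @param peaks A [peak_set()].
#' @param width Target width in bp (default 250, the width used for
#'   motif-deviation recounting).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   right-side clipping.
#' @return A `PeakSet` with an added logical `clipped` column.
#' @export
fix_peak_width <- function(peaks, width = 250, chrom_sizes = NULL) {
  centre <- ifelse(peaks$summit_offset >= 0,
                   peaks$start + peaks$summit_offset,
                   (peaks$start + peaks$end) %/% 2)
  new_start <- centre - width %/% 2
  new_end <- new_start + width
  clipped <- new_start < 0
  new_start[new_start < 0] <- 0L
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[peaks$chrom]
    over <- !is.na(lim) & new_end > lim
    new_end[over] <- as.integer(lim[over])
    clipped <- clipped | over
  }
  if (any(clipped))
    warning(sum(clipped), " peak(s) clipped at chromosome bounds")
  out <- peaks
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  out$summit_offset <- -1L
  out$clipped <- clipped
  out
}

#' Peak-by-motif annotation
#'
#' @param placements Logical peak x motif matrix (every motif must
#'   annotate >= 1 peak before deviation scoring).
#' @param peak_gc Optional per-peak GC fraction used for background
#'   matching.
#' @return A list of class `MotifAnnotation`.
#' @export
motif_annotation <- function(placements, peak_gc = NULL) {
  placements <- as.matrix(placements)
  storage.mode(placements) <- "logical"
  if (any(colSums(placements) == 0))
    stop("motif(s) with zero annotated peaks: ",
         paste(colnames(placements)[colSums(placements) == 0],
               collapse = ", "))
  structure(list(matrix = placements, peak_gc = peak_gc),
            class = "MotifAnnotation")
}

## k nearest neighbours in standardized (GC, log mean count) space,
## computed blockwise; each row of the result holds the neighbour
## indices (possibly including the peak itself).
knn_indices <- function(feats, k) {
  n <- nrow(feats)
  k <- min(k, n)
  feats <- scale(feats)
  feats[is.nan(feats)] <- 0
  out <- matrix(0L, n, k)
  block <- 1000L
  for (b in seq(1, n, by = block)) {
    idx <- b:min(b + block - 1, n)
    d2 <- outer(feats[idx, 1], feats[, 1], "-")^2
    if (ncol(feats) > 1)
      for (c in 2:ncol(feats))
        d2 <- d2 + outer(feats[idx, c], feats[, c], "-")^2
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Bias-corrected motif deviation z-scores
#'
#' For motif i and sample j the expected count is
#' `E_ij = (total counts in motif-i peaks across all samples /
#' grand total) * total counts of sample j`, and the raw deviation is
#' `(X_ij - E_ij) / E_ij`. Each of `n_background` background iterations
#' replaces every peak by one sampled from its `k_neighbors` nearest
#' neighbours in standardised (GC, log mean count) space; the z-score is
#' the raw deviation centred and scaled by the background deviations.
#'
#' @param counts Peak x sample count matrix (row order matching the
#'   annotation).
#' @param annotation A [motif_annotation()].
#' @param n_background Background iterations.
#' @param k_neighbors Neighbourhood size for background matching.
#' @param seed Integer seed for background sampling.
#' @return A list of class `DeviationMatrix`: `z` and `raw`
#'   (motif x sample) and per-motif `variability` (sd of z across
#'   samples).
#' @export
deviation_scores <- function(counts, annotation, n_background = 50,
                             k_neighbors = 50, seed = 1L) {
  A <- annotation$matrix * 1
  if (nrow(A) != nrow(counts))
    stop("annotation does not match the peak set")
  T_j <- colSums(counts)
  if (any(T_j == 0))
    stop("sample with zero counts: ", colnames(counts)[which(T_j == 0)[1]])
  row_tot <- rowSums(counts)
  grand <- sum(row_tot)
  X <- crossprod(A, counts)
  E <- (crossprod(A, row_tot) / grand) %*% t(T_j)
  raw <- (X - E) / E

  ## depth feature on the relative scale so that a common scaling of
  ## all samples leaves neighbourhoods (and hence z-scores) unchanged
  feats <- cbind(log1p(row_tot / grand * 1e6))
  if (!is.null(annotation$peak_gc)) feats <- cbind(annotation$peak_gc,
                                                   feats)
  nn <- knn_indices(feats, k_neighbors)
  n_peaks <- nrow(counts)
  bg_sum <- matrix(0, nrow(X), ncol(X))
  bg_sumsq <- matrix(0, nrow(X), ncol(X))
  with_seed(seed, {
    ## balanced sampling: each peak cycles through its neighbours in a
    ## shuffled order, so the substitute multiset is (nearly) the same
    ## for every seed and z-scores are stable across seeds
    perm <- t(apply(matrix(0, n_peaks, 1), 1,
                    function(.) sample.int(ncol(nn))))
    for (b in seq_len(n_background)) {
      col <- (b - 1) %% ncol(nn) + 1
      pick <- nn[cbind(seq_len(n_peaks), perm[, col])]
      Xb <- crossprod(A, counts[pick, , drop = FALSE])
      Eb <- (crossprod(A, row_tot[pick]) / grand) %*% t(T_j)
      rb <- (Xb - Eb) / Eb
      bg_sum <- bg_sum + rb
      bg_sumsq <- bg_sumsq + rb^2
    }
  })
  bg_mean <- bg_sum / n_background
  bg_sd <- sqrt(pmax(bg_sumsq / n_background - bg_mean^2, 0) *
                  n_background / (n_background - 1))
  z <- (raw - bg_mean) / pmax(bg_sd, 1e-12)
  dimnames(z) <- dimnames(raw) <- list(colnames(A), colnames(counts))
  structure(list(z = z, raw = raw,
                 variability = apply(z, 1, stats::sd)),
            class = "DeviationMatrix")
}

#' Motifs with a significant accessibility change at a timepoint
#'
#' Per motif, compares deviation z-scores of the replicates at
#' `timepoint` against the 0 hpa controls (same arm; within one
#' structure, or pooled over structures when `structure` is `NULL`)
#' with a two-sided Welch t-test, BH-adjusted across motifs.
#'
#' @param dev A [deviation_scores()] result.
#' @param design Per-sample design `data.frame` (see
#'   [count_experiment()]); rows must match the columns of `dev$z`.
#' @param timepoint Timepoint (hpa) to compare against 0.
#' @param alpha BH-adjusted significance level.
#' @param structure `"H"`, `"F"`, or `NULL` for both.
#' @param treatment Treatment arm.
#' @return `data.frame` with `motif`, `mean_diff`, `p`, `fdr`,
#'   `direction` (`"increased"`/`"decreased"`), `significant`.
#' @export
significant_motifs <- function(dev, design, timepoint, alpha = 0.05,
                               structure = NULL,
                               treatment = "untreated") {
  sel <- design$treatment == treatment
  if (!is.null(structure)) sel <- sel & design$structure %in% structure
  at_t <- which(sel & design$timepoint == timepoint)
  at_0 <- which(sel & design$timepoint == 0)
  if (length(at_t) < 2 || length(at_0) < 2)
    stop("need >= 2 replicates at the timepoint and at 0 hpa")
  res <- t(apply(dev$z, 1, function(z) {
    a <- z[at_t]; b <- z[at_0]
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    c(mean_diff = mean(a) - mean(b), p = p)
  }))
  fdr <- bh_adjust(res[, "p"])
  data.frame(motif = rownames(dev$z), mean_diff = res[, "mean_diff"],
             p = res[, "p"], fdr = fdr,
             direction = ifelse(res[, "mean_diff"] >= 0, "increased",
                                "decreased"),
             significant = fdr <= alpha,
             stringsAsFactors = FALSE, row.names = rownames(dev$z))
}

#' Pairwise motif similarity
#'
#' Maximum Pearson correlation of aligned probability columns over all
#' ungapped offsets and both orientations (reverse complement), with a
#' minimum overlap of 4 columns.
#'
#' @param m1,m2 [motif_model()] objects.
#' @return Similarity in `[-1, 1]`.
#' @export
motif_similarity <- function(m1, m2) {
  a <- m1$matrix
  best <- -1
  for (b in list(m2$matrix, revcomp_matrix(m2$matrix))) {
    la <- ncol(a); lb <- ncol(b)
    for (off in seq(-(lb - 4), la - 4)) {
      ia <- max(1, 1 + off):min(la, lb + off)
      ib <- ia - off
      if (length(ia) < 4) next
      r <- suppressWarnings(stats::cor(as.vector(a[, ia]),
                                       as.vector(b[, ib])))
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}

#' Cluster redundant motifs and pick representatives
#'
#' Average-linkage hierarchical clustering on `1 - similarity`
#' ([motif_similarity()]), cut at `1 - similarity_cut`. The
#' representative of each cluster is the member with the largest range
#' of mean deviation z-scores across the design groups (the motif
#' showing the greatest accessibility change).
#'
#' @param motifs Named list of [motif_model()]s (>= 2).
#' @param dev A [deviation_scores()] result covering these motifs.
#' @param similarity_cut Clustering cut in `(0, 1)`.
#' @param groups Optional per-sample grouping for the group means
#'   (default: each sample its own group).
#' @return List with `cluster` (named membership vector),
#'   `representatives` (one motif id per cluster) and the `similarity`
#'   matrix.
#' @export
cluster_motifs <- function(motifs, dev, similarity_cut = 0.6,
                           groups = NULL) {
  if (length(motifs) < 2) stop("need >= 2 motifs")
  if (similarity_cut <= 0 || similarity_cut >= 1)
    stop("similarity_cut must be in (0, 1)")
  ids <- names(motifs)
  n <- length(ids)
  sim <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- motif_similarity(motifs[[i]],
                                                 motifs[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, h = 1 - similarity_cut)
  z <- dev$z[ids, , drop = FALSE]
  if (!is.null(groups)) {
    z <- t(apply(z, 1, function(r) tapply(r, groups, mean)))
  }
  rng <- apply(z, 1, function(r) diff(range(r)))
  reps <- vapply(split(ids, cl), function(members) {
    members[which.max(rng[members])]
  }, character(1))
  list(cluster = cl, representatives = unname(reps), similarity = sim)
}
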