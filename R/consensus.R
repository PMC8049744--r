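## Reproducible-peak consensus and ATAC-seq QC: the rank-based Gaussian
## copula mixture IDR model (fitted by EM), the >= 3-pairwise-comparisons
## consensus rule, pseudo-replicate splitting, self-consistency / rescue
## ratios, and the TSS enrichment score.

dbvnorm <- function(z1, z2, mu, sigma, rho) {
  ## bivariate normal density, equal means/variances in both margins
  q <- ((z1 - mu)^2 - 2 * rho * (z1 - mu) * (z2 - mu) + (z2 - mu)^2) /
    (sigma^2 * (1 - rho^2))
  exp(-q / 2) / (2 * pi * sigma^2 * sqrt(1 - rho^2))
}

#' Fit the two-component copula mixture IDR model
#'
#' Scores are converted to ranks, then through the shifted empirical CDF
#' `u = rank / (n + 1)` to pseudo-values `z = G^{-1}(u)`, where `G` is
#' the marginal CDF of the current mixture model (recomputed every EM
#' iteration, the self-consistent transform of the copula framework).
#' The pseudo-value pairs are modelled as a mixture of an
#' irreproducible component (standard bivariate normal, correlation 0)
#' and a reproducible component (correlation `rho`, common mean `mu`,
#' variance `sigma^2`), fitted by EM from five grid starts. `local_idr`
#' is the posterior probability of the irreproducible component;
#' `global_idr` is the running mean of sorted `local_idr` (an
#' expected-FDR-style quantity).
#'
#' @param scores_a,scores_b Scores for the same >= 50 peaks in two
#'   replicates (higher = stronger). Only ranks are used, so any
#'   strictly monotone transform of either vector leaves the fit
#'   unchanged.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A list of class `IdrFit`: `pi_noise`, `rho`, `mu`, `sigma`,
#'   `local_idr`, `global_idr`, `loglik`.
#' @export
idr_fit <- function(scores_a, scores_b, max_iter = 500, tol = 1e-6) {
  n <- length(scores_a)
  if (length(scores_b) != n) stop("score vectors differ in length")
  if (n < 50) stop("need >= 50 shared peaks, got ", n)
  if (!all(is.finite(scores_a)) || !all(is.finite(scores_b)))
    stop("scores must be finite")
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0)
    stop("constant score vector")
  u1 <- rank(scores_a, ties.method = "average") / (n + 1)
  u2 <- rank(scores_b, ties.method = "average") / (n + 1)

  ## invert the mixture marginal CDF G at the ECDF values by monotone
  ## interpolation on a dense grid
  pseudo <- function(u, pi_r, mu, sigma) {
    lo <- min(stats::qnorm(min(u)), mu - 5 * sigma, -8)
    hi <- max(stats::qnorm(max(u)), mu + 5 * sigma, 8)
    zg <- seq(lo, hi, length.out = 4096)
    gg <- (1 - pi_r) * stats::pnorm(zg) +
      pi_r * stats::pnorm(zg, mu, sigma)
    stats::approx(gg, zg, xout = u, rule = 2, ties = "ordered")$y
  }

  starts <- list(c(pi = 0.3, mu = 2, sigma = 1, rho = 0.8),
                 c(pi = 0.5, mu = 1, sigma = 1, rho = 0.5),
                 c(pi = 0.7, mu = 2, sigma = 1, rho = 0.9),
                 c(pi = 0.5, mu = 3, sigma = 2, rho = 0.8),
                 c(pi = 0.9, mu = 1, sigma = 0.5, rho = 0.95))
  best <- NULL
  for (s in starts) {
    pi_r <- s["pi"]; mu <- s["mu"]; sigma <- s["sigma"]; rho <- s["rho"]
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      z1 <- pseudo(u1, pi_r, mu, sigma)
      z2 <- pseudo(u2, pi_r, mu, sigma)
      d0 <- stats::dnorm(z1) * stats::dnorm(z2)
      d1 <- dbvnorm(z1, z2, mu, sigma, rho)
      num <- pi_r * d1
      den <- num + (1 - pi_r) * d0
      g <- num / den                     # P(reproducible | z)
      ll <- sum(log(den))
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
      w <- sum(g)
      pi_r <- min(max(w / n, 1e-4), 1 - 1e-4)
      ## floors on mu and rho keep the reproducible component genuinely
      ## distinct from the noise component; without them the mixture is
      ## unidentifiable on irreproducible data (both components collapse
      ## onto the standard normal and the posterior drifts)
      mu <- max(sum(g * (z1 + z2)) / (2 * w), 0.5)
      sigma2 <- sum(g * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * w)
      sigma <- max(sqrt(sigma2), 0.05)
      rho <- sum(g * (z1 - mu) * (z2 - mu)) / (w * sigma^2)
      rho <- min(max(rho, 0.2), 0.999)
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(pi_noise = unname(1 - pi_r), rho = unname(rho),
                   mu = unname(mu), sigma = unname(sigma),
                   local_idr = unname(1 - g), loglik = unname(ll))
    }
  }
  ## degeneracy guard: a "reproducible" component stuck at the
  ## separation floors is indistinguishable from noise (this is where
  ## the EM lands on fully irreproducible input) — report accordingly
  if (best$rho <= 0.21 || best$mu <= 0.51) {
    best$pi_noise <- 1
    best$local_idr <- rep(1, n)
  }
  o <- order(best$local_idr)
  gidr <- numeric(n)
  gidr[o] <- cumsum(best$local_idr[o]) / seq_len(n)
  best$global_idr <- gidr
  class(best) <- "IdrFit"
  best
}

## --- peak matching ---------------------------------------------------

## Match each query peak to reference regions by >= 50% reciprocal
## overlap; ties broken by larger overlap, then lower start.  Returns an
## integer index into `ref` (NA if unmatched), one per query row.
match_peaks <- function(query, ref, min_frac = 0.5) {
  hits <- as.data.frame(IRanges::findOverlaps(
    IRanges::IRanges(query$start + 1L, query$end),
    IRanges::IRanges(ref$start + 1L, ref$end)))
  same_chrom <- query$chrom[hits$queryHits] == ref$chrom[hits$subjectHits]
  hits <- hits[same_chrom, , drop = FALSE]
  if (nrow(hits) == 0) return(rep(NA_integer_, nrow(query)))
  ov <- pmin(query$end[hits$queryHits], ref$end[hits$subjectHits]) -
        pmax(query$start[hits$queryHits], ref$start[hits$subjectHits])
  wq <- query$end[hits$queryHits] - query$start[hits$queryHits]
  wr <- ref$end[hits$subjectHits] - ref$start[hits$subjectHits]
  keep <- ov >= min_frac * wq & ov >= min_frac * wr
  hits <- hits[keep, , drop = FALSE]; ov <- ov[keep]
  out <- rep(NA_integer_, nrow(query))
  if (nrow(hits) == 0) return(out)
  ord <- order(hits$queryHits, -ov, ref$start[hits$subjectHits])
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$queryHits)
  out[hits$queryHits[first]] <- hits$subjectHits[first]
  out
}

## Reference regions for a group: merged union of all replicate peaks.
reference_regions <- function(peak_sets) {
  all <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  out <- do.call(rbind, lapply(split(all, all$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' The consensus inclusion rule
#'
#' A peak enters the consensus iff it passes the IDR cut in at least
#' `min_pairs` pairwise replicate comparisons.
#'
#' @param n_pass Integer vector: per peak, the number of pairwise
#'   comparisons with global IDR <= cutoff.
#' @param min_pairs Required number of passing comparisons (default 3).
#' @return Logical vector.
#' @export
consensus_rule <- function(n_pass, min_pairs = 3) {
  n_pass >= min_pairs
}

#' Reproducible-peak consensus across replicates and treatment groups
#'
#' For each treatment group, replicate peaks are unified into reference
#' regions (merged union, matched back by >= 50% reciprocal overlap);
#' every replicate pair is compared with [idr_fit()] on the shared
#' regions; a region enters the group consensus iff its global IDR is
#' <= `idr_cut` in at least `min_pairs` pairwise comparisons. The
#' pipeline consensus is the merged union over group consensus sets.
#'
#' @param replicate_sets Named list of groups; each group is a list of
#'   >= 3 scored [peak_set()]s (or a `ScoredPeakReplicates`).
#' @param idr_cut Global IDR cutoff (default 0.1).
#' @param min_pairs Minimum passing pairwise comparisons (default 3).
#' @return List with `groups` (per-group consensus `PeakSet` plus a
#'   `n_pass` column), `consensus` (union `PeakSet`) and
#'   `n_reproducible` (per-group consensus sizes).
#' @export
consensus_peaks <- function(replicate_sets, idr_cut = 0.1, min_pairs = 3) {
  group_out <- lapply(names(replicate_sets), function(gname) {
    reps <- replicate_sets[[gname]]
    if (inherits(reps, "ScoredPeakReplicates")) reps <- reps$replicates
    if (length(reps) < 3)
      stop("group '", gname, "' has < 3 replicates")
    ref <- reference_regions(reps)
    score <- matrix(NA_real_, nrow(ref), length(reps))
    for (k in seq_along(reps)) {
      idx <- match_peaks(reps[[k]], ref)
      ok <- !is.na(idx)
      ## several replicate peaks may map to one merged region: keep max
      sc <- tapply(reps[[k]]$score[ok], idx[ok], max)
      score[as.integer(names(sc)), k] <- sc
    }
    pairs <- utils::combn(length(reps), 2)
    n_pass <- integer(nrow(ref))
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      shared <- which(!is.na(score[, a]) & !is.na(score[, b]))
      if (length(shared) < 50) next
      fit <- idr_fit(score[shared, a], score[shared, b])
      pass <- shared[fit$global_idr <= idr_cut]
      n_pass[pass] <- n_pass[pass] + 1L
    }
    keep <- consensus_rule(n_pass, min_pairs)
    out <- peak_set(ref$chrom[keep], ref$start[keep], ref$end[keep],
                    name = sprintf("%s_cons_%d", gname, seq_len(sum(keep))),
                    score = rowMeans(score, na.rm = TRUE)[keep])
    out$n_pass <- n_pass[keep]
    out
  })
  names(group_out) <- names(replicate_sets)
  union_ref <- reference_regions(group_out)
  consensus <- peak_set(union_ref$chrom, union_ref$start, union_ref$end,
                        name = sprintf("cons_%05d",
                                       seq_len(nrow(union_ref))))
  list(groups = group_out, consensus = consensus,
       n_reproducible = vapply(group_out, nrow, 1L))
}

#' Split pooled peak weights into two pseudo-replicates
#'
#' Emulates pooling reads from all replicates and randomly re-splitting
#' them: each peak's integer weight (read count) is divided
#' Binomial(w, 0.5) between the two pseudo-replicates, and scores are
#' the assigned weights.
#'
#' @param peaks A [peak_set()] with a `weight` column (integer >= 1), or
#'   weights supplied separately.
#' @param weights Optional integer weights overriding `peaks$weight`.
#' @param seed Integer seed.
#' @return List of two `PeakSet`s whose `score`/`weight` columns sum to
#'   the input weights.
#' @export
pseudo_replicates <- function(peaks, weights = peaks$weight, seed = 1L) {
  if (nrow(peaks) == 0) stop("empty peak set")
  if (is.null(weights)) stop("per-peak weights required")
  weights <- as.integer(weights)
  if (any(weights < 1)) stop("weights must be >= 1")
  w1 <- with_seed(seed, stats::rbinom(length(weights), weights, 0.5))
  mk <- function(w) {
    out <- peaks
    out$weight <- w
    out$score <- as.numeric(w)
    out
  }
  list(mk(w1), mk(weights - w1))
}

#' Self-consistency and rescue ratios
#'
#' Both are max/min fold differences in reproducible-peak counts: the
#' self-consistency ratio over within-replicate pseudo-replicate splits
#' (largest pairwise ratio when more than two replicates are given), and
#' the rescue ratio between the true-replicate count and the
#' pooled-pseudo-replicate count. Either ratio >= 2 fails QC.
#'
#' @param n_pseudo Integer vector (length >= 2) of reproducible-peak
#'   counts from each replicate's pseudo-replicate split.
#' @param n_true Reproducible peaks from the true biological replicates.
#' @param n_pooled Reproducible peaks from the pooled pseudo-replicates.
#' @return List with `self_consistency_ratio`, `rescue_ratio`, `pass`.
#' @export
qc_ratios <- function(n_pseudo, n_true, n_pooled) {
  if (any(c(n_pseudo, n_true, n_pooled) <= 0))
    stop("all reproducible-peak counts must be > 0")
  pairs <- utils::combn(n_pseudo, 2)
  self_ratio <- max(apply(pairs, 2, max) / apply(pairs, 2, min))
  rescue <- max(n_true, n_pooled) / min(n_true, n_pooled)
  list(self_consistency_ratio = self_ratio, rescue_ratio = rescue,
       pass = self_ratio < 2 && rescue < 2)
}

#' TSS enrichment score from aggregate coverage profiles
#'
#' Averages the per-gene profiles, normalises by the mean coverage of
#' the two outermost `flank_window`-bp segments, smooths with a centred
#' running mean of width `smooth`, and reports the maximum of the
#' normalised profile within +/- 50 bp of the TSS.
#'
#' @param profiles Gene x position matrix over `-flank .. +flank`
#'   (width >= 2001, i.e. flank >= 1000).
#' @param flank_window Width (bp) of each outermost flank segment used
#'   for normalisation.
#' @param smooth Running-mean window (odd, bp).
#' @return The TSS enrichment score (fold over flank).
#' @export
tss_enrichment <- function(profiles, flank_window = 100, smooth = 21) {
  w <- ncol(profiles)
  if (w < 2 * 1000 + 1)
    stop("profile width must be >= 2001 (flank >= 1 kb)")
  agg <- colMeans(profiles)
  flank_mean <- mean(c(agg[seq_len(flank_window)],
                       agg[seq(w - flank_window + 1, w)]))
  if (flank_mean == 0) stop("zero flank signal; cannot normalise")
  norm <- agg / flank_mean
  sm <- as.numeric(stats::filter(norm, rep(1 / smooth, smooth),
                                 sides = 2))
  centre <- (w + 1) / 2
  idx <- seq(centre - 50, centre + 50)
  max(sm[idx], na.rm = TRUE)
}

#' Assemble the ATAC QC report
#'
#' @param tss_score [tss_enrichment()] result.
#' @param n_reproducible Reproducible-peak count for the group.
#' @param ratios [qc_ratios()] result.
#' @return One-row `data.frame` of class `QcReport`.
#' @export
qc_report <- function(tss_score, n_reproducible, ratios) {
  out <- data.frame(tss_score = tss_score,
                    n_reproducible = n_reproducible,
                    self_consistency_ratio = ratios$self_consistency_ratio,
                    rescue_ratio = ratios$rescue_ratio,
                    pass = ratios$pass)
  class(out) <- c("QcReport", "data.frame")
  out
}
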