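make_pwm <- function(id, cols) {
  # cols: string like "ACGT"; near-deterministic PWM for that word
  bases <- strsplit(cols, "")[[1]]
  m <- matrix(0.02, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) m[bases[i], i] <- 0.94
  motif_model(id, m)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("PWM scanning: consensus, uniform, and hand-computed cases", {
  m <- make_pwm("w", "ACGT")
  lo <- hydrareg:::logodds_matrix(m)
  max_score <- sum(apply(lo, 2, max))
  hits <- scan_pwm("ACGT", m, threshold = 1, both_strands = FALSE)
  expect_equal(hits$position, 1)
  expect_equal(hits$score, max_score)

  # uniform PWM on uniform background: max achievable score is 0
  unif <- motif_model("u", matrix(0.25, 4, 4))
  expect_equal(nrow(scan_pwm("ACGTACGTAC", unif, threshold = 0.5)), 0)

  # planted 4-mer in a 10-mer: exactly the planted offset, score equal
  # to the hand-computed log-odds sum
  seqs <- "TTTTACGTTT"
  hits <- scan_pwm(seqs, m, threshold = 0.9, both_strands = FALSE)
  expect_equal(hits$position, 5)
  hand <- unname(lo["A", 1] + lo["C", 2] + lo["G", 3] + lo["T", 4])
  expect_equal(hits$score, hand)

  expect_error(scan_pwm("ACG", m), "longer than")
  expect_error(scan_pwm("ACGT", m, threshold = 0), "\\(0, 1\\]")
  expect_error(scan_pwm("ACXT", m), "outside")
})

test_that("N bases contribute background log-odds (zero)", {
  m <- make_pwm("w", "ACGT")
  lo <- hydrareg:::logodds_matrix(m)
  h <- scan_pwm("ANGT", m, threshold = 0.1, both_strands = FALSE)
  expect_equal(h$score, unname(lo["A", 1] + lo["G", 3] + lo["T", 4]))
})

test_that("hit set is strand-symmetric under reverse complement", {
  m <- make_pwm("w", "ACGGT")
  s <- "GGACGGTTTACCGTCC"
  fwd <- scan_pwm(s, m, threshold = 0.8)
  rev <- scan_pwm(revcomp(s), m, threshold = 0.8)
  n <- nchar(s); L <- 5
  mapped <- sort(n - rev$position - L + 2)
  expect_equal(sort(fwd$position), mapped)
  expect_equal(sort(fwd$score), sort(rev$score))
})

test_that("fixed-width re-centring follows the summit/midpoint rule", {
  p <- peak_set("chr1", c(100L, 10L, 875L), c(600L, 110L, 1125L),
                c("a", "b", "c"), summit_offset = c(250L, -1L, -1L))
  expect_warning(out <- fix_peak_width(p, 250), "clipped")
  expect_equal(out$start[1], 225)   # summit at 350, re-centred
  expect_equal(out$end[1], 475)
  expect_true(out$clipped[2])       # midpoint 60 - 125 < 0
  expect_equal(out$start[2], 0)
  # already 250 bp wide and summit-centred: unchanged
  expect_equal(out$start[3], 875)
  expect_equal(out$end[3], 1125)
  expect_false(out$clipped[3])
})

test_that("raw deviations vanish for exactly proportional counts", {
  set.seed(2)
  base <- rpois(400, 100) + 1
  counts <- outer(base, c(1, 2, 4, 8))   # X_pj = c_p * T_j pattern
  rownames(counts) <- sprintf("p%03d", 1:400)
  colnames(counts) <- sprintf("s%d", 1:4)
  ann <- motif_annotation(matrix(runif(400 * 5) < 0.2, 400, 5,
                                 dimnames = list(rownames(counts),
                                                 sprintf("m%d", 1:5))))
  dev <- deviation_scores(counts, ann, n_background = 10, seed = 1)
  expect_equal(max(abs(dev$raw)), 0, tolerance = 1e-12)
})

test_that("deviation z-scores are invariant to common depth scaling", {
  set.seed(3)
  counts <- matrix(rnbinom(2000 * 12, mu = 60, size = 5), 2000, 12,
                   dimnames = list(sprintf("p%04d", 1:2000),
                                   sprintf("s%d", 1:12)))
  ann <- motif_annotation(matrix(runif(2000 * 8) < 0.15, 2000, 8,
                                 dimnames = list(rownames(counts),
                                                 sprintf("m%d", 1:8))),
                          peak_gc = runif(2000, 0.3, 0.6))
  d1 <- deviation_scores(counts, ann, seed = 7)
  d2 <- deviation_scores(counts * 3L, ann, seed = 7)
  expect_equal(d1$z, d2$z, tolerance = 1e-9)
  expect_error(deviation_scores(counts[1:10, ], ann), "match")
  zero <- counts; zero[, 2] <- 0L
  expect_error(deviation_scores(zero, ann), "zero counts")
})

test_that("background sampling is stable across seeds", {
  # balanced neighbour cycling makes the background substitute multiset
  # seed-independent; only the per-iteration pairing varies
  set.seed(3)
  counts <- matrix(rnbinom(2000 * 12, mu = 60, size = 5), 2000, 12,
                   dimnames = list(sprintf("p%04d", 1:2000),
                                   sprintf("s%d", 1:12)))
  ann <- motif_annotation(matrix(runif(2000 * 8) < 0.15, 2000, 8,
                                 dimnames = list(rownames(counts),
                                                 sprintf("m%d", 1:8))),
                          peak_gc = runif(2000, 0.3, 0.6))
  d1 <- deviation_scores(counts, ann, seed = 7)
  d2 <- deviation_scores(counts, ann, seed = 99)
  expect_gt(cor(as.vector(d1$z), as.vector(d2$z)), 0.99)
})

test_that("planted accessibility program yields positive z-scores", {
  set.seed(4)
  n_p <- 800; n_s <- 12
  counts <- matrix(rnbinom(n_p * n_s, mu = 80, size = 8), n_p, n_s,
                   dimnames = list(sprintf("p%03d", 1:n_p),
                                   sprintf("s%d", 1:n_s)))
  target <- 1:80
  boosted <- 7:12
  counts[target, boosted] <- counts[target, boosted] * 2L
  plc <- matrix(runif(n_p * 3) < 0.1, n_p, 3,
                dimnames = list(rownames(counts), c("hit", "d1", "d2")))
  plc[target, "hit"] <- TRUE
  dev <- deviation_scores(counts, motif_annotation(plc), seed = 5)
  expect_gte(mean(dev$z["hit", boosted] > 0), 0.95)
  expect_gt(dev$variability["hit"], max(dev$variability[c("d1", "d2")]))
})

test_that("significant_motifs needs replicates and respects alpha", {
  sim <- small_sim()
  ann <- motif_annotation(sim$truth$motif_placements, sim$truth$peak_gc)
  dev <- deviation_scores(sim$atac$counts, ann, n_background = 20,
                          seed = 2)
  sig <- significant_motifs(dev, sim$atac$design, 3, structure = "H")
  expect_true(sig["M_INJ", "significant"])
  expect_equal(sig["M_INJ", "direction"], "increased")
  none <- significant_motifs(dev, sim$atac$design, 3, alpha = 0,
                             structure = "H")
  expect_false(any(none$significant))
  one_rep <- sim$atac$design[c(1, 2), ]
  expect_error(significant_motifs(dev, sim$atac$design, 3,
                                  structure = "H",
                                  treatment = "nosuch"),
               ">= 2 replicates")
})

test_that("motif clustering merges identical PWMs, keeps orthogonal ones", {
  m1 <- make_pwm("a", "ACGTAC")
  m2 <- make_pwm("b", "ACGTAC")
  # c shares no column pattern with a at any offset
  m3 <- motif_model("c", matrix(c(0.25, 0.25, 0.25, 0.25), 4, 6))
  expect_equal(motif_similarity(m1, m2), 1, tolerance = 1e-9)
  # reverse-complement similarity is recognised
  m4 <- make_pwm("d", revcomp("ACGTAC"))
  expect_equal(motif_similarity(m1, m4), 1, tolerance = 1e-9)

  z <- matrix(c(0, 1, 0, 3, 1, 1, 0, 0, 2, 0, 0, 1), 4, 3,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  dev <- list(z = z)
  cl <- cluster_motifs(list(a = m1, b = m2, c = m3, d = m4), dev,
                       similarity_cut = 0.7)
  expect_equal(cl$cluster[["a"]], cl$cluster[["b"]])
  expect_equal(cl$cluster[["a"]], cl$cluster[["d"]])
  expect_false(cl$cluster[["c"]] == cl$cluster[["a"]])
  # representative = member with the largest range of z across groups
  ranges <- apply(z, 1, function(r) diff(range(r)))
  merged <- names(cl$cluster)[cl$cluster == cl$cluster[["a"]]]
  expect_equal(sort(setdiff(cl$representatives, "c")),
               merged[which.max(ranges[merged])])
  expect_error(cluster_motifs(list(a = m1), dev, 0.5), ">= 2")
  expect_error(cluster_motifs(list(a = m1, b = m2), dev, 1.5),
               "\\(0, 1\\)")
})
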