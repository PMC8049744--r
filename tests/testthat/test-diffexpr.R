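test_that("CPM filter applies the inclusive boundary rule", {
  # library sizes of 1e6 make counts and CPM coincide
  pad <- matrix(1e6 - 13, 1, 6)
  counts <- rbind(rna_rule = c(3, 3, 3, 0, 0, 0),
                  zero = c(0, 0, 0, 0, 0, 0),
                  atac_boundary = c(10, 10, 10, 0, 0, 0),
                  below = c(10, 10, 9, 0, 0, 0),
                  filler = 1e6 - c(13, 13, 22, 0, 0, 0) - 0)
  counts["filler", ] <- 1e6 - colSums(counts[1:4, , drop = FALSE])
  exp <- toy_experiment(counts)
  expect_true("rna_rule" %in% filter_features(exp, 2, 3))
  expect_false("zero" %in% filter_features(exp, 2, 3))
  kept_atac <- filter_features(exp, 10, 3)
  expect_true("atac_boundary" %in% kept_atac)   # exactly 10 CPM counts
  expect_false("below" %in% kept_atac)
  expect_error(filter_features(exp, 2, 7), "exceeds")
  expect_error(filter_features(exp, 0, 3), "> 0")
})

test_that("TMM factors: symmetry, scale invariance, centring", {
  x <- matrix(rpois(600, 50), 100, 6)
  exp <- toy_experiment(cbind(x[, 1], x[, 1], x[, 1]))
  expect_equal(unname(tmm_factors(exp)), rep(1, 3))

  # one column a constant multiple of another: M-values all equal, so
  # both factors are 1 after re-centring
  exp2 <- toy_experiment(cbind(x[, 1], x[, 1] * 5L))
  expect_equal(unname(tmm_factors(exp2, reference = "s1")), c(1, 1))

  nf <- tmm_factors(toy_experiment(x))
  expect_equal(exp(mean(log(nf))), 1, tolerance = 1e-9)

  bad <- x; bad[, 2] <- 0L
  expect_error(tmm_factors(toy_experiment(bad)), "all-zero sample")
})

test_that("TMM factor equals the hand-computed trimmed weighted mean", {
  # 6 features, two samples; worked by hand below
  obs <- c(100, 200, 300, 400, 500, 1000)
  ref <- c(100, 100, 320, 410, 220, 1010)
  exp <- toy_experiment(cbind(ref, obs))
  n_o <- sum(obs); n_r <- sum(ref)
  m <- log2((obs / n_o) / (ref / n_r))
  a <- 0.5 * log2((obs / n_o) * (ref / n_r))
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  # 30% two-sided M-trim keeps M-ranks 2..5; 5% A-trim keeps all 6
  keep <- rank(m) %in% 2:5
  f_obs <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  expected <- c(1 / sqrt(f_obs), sqrt(f_obs))  # geometric re-centring
  expect_equal(unname(tmm_factors(exp, reference = "s1")), expected,
               tolerance = 1e-12)
})

test_that("TMM factors agree with edgeR's implementation", {
  set.seed(7)
  x <- matrix(rnbinom(500 * 6, mu = exp(runif(500 * 6, 2, 7)),
                      size = 10), 500, 6)
  exp <- toy_experiment(x)
  mine <- tmm_factors(exp)
  theirs <- edgeR::calcNormFactors(edgeR::DGEList(x))$samples$norm.factors
  expect_equal(unname(mine), theirs, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(1)
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  # monotone in rank order and invariant to input ordering
  o <- sample(200)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_true(all(diff(bh_adjust(sort(p))) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("QL fit recovers large-count log2 ratios and nulls", {
  set.seed(11)
  n <- 200
  mu <- exp(runif(n, 8, 10))
  ratio <- rep(1, n); ratio[1:20] <- 4
  counts <- cbind(matrix(rpois(n * 3, mu), n, 3),
                  matrix(rpois(n * 3, mu * ratio), n, 3))
  exp <- toy_experiment(counts)
  exp$design$structure <- rep(c("H", "F"), each = 3)
  nexp <- normalize_experiment(exp)
  fit <- fit_nb_ql(nexp, group_design(exp$design))
  res <- ql_test(fit, cell_contrast(fit$design, "F.0.untreated",
                                    "H.0.untreated"), "FvH")
  expect_equal(res$log2FC[1:20], rep(2, 20), tolerance = 0.1)
  expect_equal(mean(res$log2FC[21:n]), 0, tolerance = 0.02)
  # determinism and contrast validation
  res2 <- ql_test(fit, cell_contrast(fit$design, "F.0.untreated",
                                     "H.0.untreated"), "FvH")
  expect_identical(res, res2)
  expect_error(ql_test(fit, rep(0, 2)), "zero")
  expect_error(ql_test(fit, numeric(0)), "zero-length")
})

test_that("fit_nb_ql validates its design", {
  sim <- small_sim()
  nexp <- normalize_experiment(sim$rna)
  mm <- group_design(sim$rna$design)
  expect_error(fit_nb_ql(nexp, cbind(mm, mm[, 1])), "rank-deficient")
})

test_that("context effect: exact delta and correct calls", {
  fit <- small_rna_fit()
  ctx8 <- context_effect(fit, 8, fdr_cut = 1e-3)
  expect_equal(ctx8$delta, ctx8$lfc_head - ctx8$lfc_foot,
               tolerance = 1e-12)
  truth <- small_sim()$truth
  head_called <- ctx8$feature[ctx8$call == "head"]
  foot_called <- ctx8$feature[ctx8$call == "foot"]
  expect_gt(length(head_called), 10)
  expect_gt(mean(head_called %in% names(truth$realized$head)), 0.95)
  expect_gt(mean(foot_called %in% names(truth$realized$foot)), 0.95)
  # the symmetric injury program at 3 hpa produces no context calls
  ctx3 <- context_effect(fit, 3, fdr_cut = 1e-3)
  expect_lte(sum(ctx3$call != "none"), 2)
  expect_error(context_effect(fit, 99), "missing design cells")
})

test_that("TCF classification follows the definitions", {
  mk <- function(lfc, fdr) {
    data.frame(feature = sprintf("f%d", seq_along(lfc)), log2FC = lfc,
               F = 1, p = fdr, fdr = fdr, contrast = "x",
               stringsAsFactors = FALSE)
  }
  # f1: up untreated, not up in iCRT14, significant reduction -> dependent
  # f2: up in both, significant increase -> inhibited
  # f3: nothing significant -> unclassified
  untr <- mk(c(3, 3, 0.2), c(1e-5, 1e-5, 0.5))
  icrt <- mk(c(0.1, 3, 0.2), c(0.8, 1e-5, 0.5))
  cross <- mk(c(-2.5, 1.5, 0), c(1e-4, 1e-4, 0.9))
  cls <- classify_tcf(untr, icrt, cross)
  expect_equal(cls$label,
               c("TCF-dependent", "TCF-inhibited", "unclassified"))
  expect_error(classify_tcf(untr, icrt[c(2, 1, 3), ], cross),
               "same features")
})

test_that("Wilcoxon p-values: spec example and enumeration oracle", {
  expect_equal(wilcoxon_p(c(1, 2, 3), c(4, 5, 6)), 0.1)

  enum_p <- function(x, y) {
    pooled <- c(x, y); nx <- length(x)
    u_of <- function(idx) {
      r <- rank(pooled)
      sum(r[idx]) - nx * (nx + 1) / 2
    }
    obs <- u_of(seq_len(nx))
    all_u <- combn(length(pooled), nx, u_of)
    min(1, 2 * min(mean(all_u <= obs), mean(all_u >= obs)))
  }
  set.seed(21)
  for (i in 1:5) {
    nx <- sample(3:4, 1); ny <- sample(3:4, 1)
    v <- sample(1000, nx + ny)  # no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxon_p(x, y), enum_p(x, y))
  }
  # tie-corrected normal approximation agrees with wilcox.test
  set.seed(3)
  x <- rpois(40, 3); y <- rpois(45, 5)
  expect_equal(wilcoxon_p(x, y),
               wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("structural enrichment calls planted markers only", {
  genes <- sprintf("g%03d", 1:80)
  sc <- generate_single_cell(genes, markers_head = genes[1:8],
                             markers_foot = genes[9:16],
                             n_cells_per_cluster = 150,
                             effect_log2fc = 3, seed = 2)
  res <- structural_enrichment(sc$counts, sc$clusters)
  called <- res$gene[res$call != "none"]
  expect_gte(mean(genes[1:16] %in% called), 0.9)
  expect_equal(res$call[res$gene %in% genes[1:8] & res$call != "none"][1],
               "head")
  # identical clusters: log2FC 0, no calls
  same <- cbind(sc$counts[, 1:20], sc$counts[, 1:20])
  res0 <- structural_enrichment(same, rep(c("head", "foot"), each = 20))
  expect_equal(res0$log2FC, rep(0, nrow(same)))
  expect_true(all(res0$call == "none"))
  expect_error(structural_enrichment(sc$counts,
                                     rep(c("head", "foot"),
                                         c(1, ncol(sc$counts) - 1))),
               ">= 2 cells")
})
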