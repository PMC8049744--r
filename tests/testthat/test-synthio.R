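test_that("generator output is a pure function of (config, seed)", {
  cfg <- design_config(n_genes = 100, n_peaks = 220, seed = 9)
  eff <- effect_model(injury_set = sprintf("g%04d", 1:10))
  a <- generate_experiment(cfg, eff)
  b <- generate_experiment(cfg, eff)
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$atac$counts, b$atac$counts)
  expect_identical(a$truth$realized, b$truth$realized)
  expect_identical(a$truth$motif_placements, b$truth$motif_placements)
  c <- generate_experiment(design_config(n_genes = 100, n_peaks = 220,
                                         seed = 10), eff)
  expect_false(identical(a$rna$counts, c$rna$counts))
})

test_that("with_seed leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(with_seed(1, runif(100)))
  expect_identical(.Random.seed, before)
})

test_that("effect model validates sets", {
  expect_error(effect_model(head_set = "g1", foot_set = "g1"),
               "disjoint")
  cfg <- design_config(n_genes = 50, n_peaks = 60, seed = 1)
  expect_error(generate_experiment(cfg,
                                   effect_model(injury_set = "nope")),
               "unknown feature ids")
})

test_that("planted injury effect matches the stated moments", {
  # mu_inj = 2 over 200 injury features: the empirical mean log2FC at
  # 3 hpa vs 0 hpa must sit within 2 SE of 2.0
  cfg <- design_config(n_genes = 1000, n_peaks = 1000, seed = 5)
  eff <- effect_model(injury_set = sprintf("g%04d", 1:200),
                      mu_inj = 2, sd_inj = 0.5)
  sim <- generate_experiment(cfg, eff)
  d <- sim$rna$design
  # TMM-normalised CPM: with 20% of the library planted upward, raw CPM
  # carries a composition bias that TMM is designed to remove
  cpm <- normalize_experiment(sim$rna)$cpm
  m3 <- rowMeans(cpm[eff$injury_set,
                     d$timepoint == 3 & d$treatment == "untreated"])
  m0 <- rowMeans(cpm[eff$injury_set,
                     d$timepoint == 0 & d$treatment == "untreated"])
  lfc <- log2(m3 / m0)
  se <- sd(lfc) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc) - 2), 2 * se + 0.1)
  # realised effects recorded in the truth have the planted moments too
  expect_equal(mean(sim$truth$realized$injury), 2,
               tolerance = 3 * 0.5 / sqrt(200))
})

test_that("generated counts have NB mean-variance structure", {
  # pooled across 0 hpa replicates of a null experiment, the observed
  # CV^2 should track 1/mu + phi
  cfg <- design_config(n_genes = 2000, n_peaks = 10,
                       replicates_per_cell = 6, seed = 3,
                       library_size_cv = 0)
  sim <- generate_experiment(cfg, effect_model())
  d <- sim$rna$design
  j <- which(d$timepoint == 0)
  x <- sim$rna$counts[, j]
  mu <- rowMeans(x)
  keep <- mu > 50
  cv2 <- apply(x[keep, ], 1, var) / mu[keep]^2
  expected <- 1 / mu[keep] + sim$truth$dispersion$rna[keep]
  expect_equal(mean(cv2) / mean(expected), 1, tolerance = 0.15)
})

test_that("toy genome layout links promoter peaks to genes", {
  sim <- small_sim()
  pg <- sim$truth$peak_gene
  prom <- pg[pg$role == "promoter", ]
  expect_equal(nrow(prom), 300)
  # promoter peaks straddle their gene's start
  g <- sim$genes[match(prom$gene, sim$genes$name), ]
  p <- sim$peaks[match(prom$peak, sim$peaks$name), ]
  expect_true(all(p$start < g$start & g$start < p$end))
  # orphans are > 20 kb from every gene start
  orph <- sim$peaks[match(pg$peak[pg$role == "orphan"], sim$peaks$name), ]
  expect_true(all(orph$start > max(sim$genes$end) + 20000))
})

test_that("scored replicate lists behave at the extremes", {
  pk <- peak_set("chr1", seq(0, by = 1000, length.out = 400),
                 seq(0, by = 1000, length.out = 400) + 500)
  same <- generate_scored_replicates(pk, 3, reproducible_fraction = 1,
                                     noise_sd = 0, seed = 4)
  expect_identical(same$replicates[[1]]$score, same$replicates[[2]]$score)
  expect_identical(same$replicates[[1]]$score, same$replicates[[3]]$score)

  indep <- generate_scored_replicates(pk, 2, reproducible_fraction = 0,
                                      seed = 4)
  rho <- cor(indep$replicates[[1]]$score, indep$replicates[[2]]$score,
             method = "spearman")
  expect_lt(abs(rho), 0.15)
  expect_length(indep$reproducible, 0)

  expect_error(generate_scored_replicates(pk, 1), ">= 2")
  expect_error(generate_scored_replicates(pk, 2, reproducible_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("TSS profile generator hits its expected enrichment", {
  flat <- generate_tss_profiles(500, enrichment = 1, seed = 2)
  expect_equal(tss_enrichment(flat), 1, tolerance = 0.05)
  expect_error(generate_tss_profiles(0, 7), "> 0")
  expect_error(generate_tss_profiles(10, 7, flank = 0), "> 0")
  expect_error(generate_tss_profiles(10, 0.5), ">= 1")
  expect_identical(generate_tss_profiles(50, 7, seed = 8),
                   generate_tss_profiles(50, 7, seed = 8))
})

test_that("single-cell generator plants recoverable markers", {
  genes <- sprintf("g%03d", 1:50)
  expect_error(generate_single_cell(genes, markers_head = "g001",
                                    markers_foot = "g001"), "disjoint")
  sc <- generate_single_cell(genes, markers_head = genes[1:5],
                             markers_foot = genes[6:10],
                             n_cells_per_cluster = 50, seed = 6)
  expect_identical(sc$counts,
                   generate_single_cell(genes, markers_head = genes[1:5],
                                        markers_foot = genes[6:10],
                                        n_cells_per_cluster = 50,
                                        seed = 6)$counts)
  mh <- rowMeans(sc$counts[, sc$clusters == "head"])
  mf <- rowMeans(sc$counts[, sc$clusters == "foot"])
  expect_true(all(mh[genes[1:5]] > mf[genes[1:5]]))
  expect_true(all(mf[genes[6:10]] > mh[genes[6:10]]))
})

test_that("truth serialises to JSON and back", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_truth(sim$truth, file.path(d, "truth.json"))
  back <- read_truth(file.path(d, "truth.json"))
  expect_identical(back$motif_placements, sim$truth$motif_placements)
  expect_equal(back$realized$injury, sim$truth$realized$injury)
  expect_equal(back$dispersion$rna, sim$truth$dispersion$rna)
  expect_identical(back$peak_gene$gene, sim$truth$peak_gene$gene)
  expect_identical(back$wnt_genes, sim$truth$wnt_genes)
  # every planted feature id exists in the generated matrices
  expect_true(all(names(back$realized$injury) %in%
                    rownames(sim$rna$counts)))
})

test_that("written experiment round-trips through the standard formats", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_experiment(sim, d)
  rna <- read_counts(file.path(d, "rna_counts.tsv"),
                     file.path(d, "rna_samples.tsv"))
  expect_identical(rna$counts, sim$rna$counts)
  pk <- read_narrowpeak(file.path(d, "peaks.narrowPeak"))
  expect_equal(pk$start, sim$peaks$start)
  expect_equal(nrow(read_bed6(file.path(d, "genes.bed"))), 300)
  expect_named(yaml::read_yaml(file.path(d, "config.yaml")),
               names(unclass(design_config())), ignore.order = TRUE)
})
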