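## Synthetic multi-omic experiment generator.
##
## Emulates the bisection study design: 2 regenerating structures (H =
## head, F = foot) x 4 timepoints (0, 3, 8, 12 hours post amputation) x
## 2 treatment arms (untreated, iCRT14) x n replicates, for both an
## RNA-seq gene count matrix and an ATAC-seq peak count matrix on a toy
## genome, with planted effect programs and a machine-readable truth.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' their seed and never perturb the caller's RNG stream.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Design configuration for the synthetic experiment
#'
#' Defaults follow the study design this generator emulates: a 2 x 4 x 2
#' factorial (structure x timepoint x treatment) with 3 biological
#' replicates per cell, negative-binomial counts with log-normal
#' dispersions, and moderately variable library sizes.
#'
#' @param n_genes,n_peaks Number of RNA features and ATAC peaks (>= 1).
#' @param structures,timepoints,treatments Design levels; `timepoints`
#'   must include the 0 hpa control.
#' @param replicates_per_cell Biological replicates per design cell.
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of per-sample sequencing depth.
#' @param dispersion_log_mean,dispersion_log_sd Hyperparameters of the
#'   log-normal feature-wise NB dispersion (defaults give a typical bulk
#'   biological CV of ~0.22).
#' @param baseline_log2_range Range of per-feature baseline log2 relative
#'   abundance, drawn uniformly.
#' @param seed Root seed; fully determines all generator output.
#' @return A list of class `DesignConfig`.
#' @export
design_config <- function(n_genes = 2000, n_peaks = 5000,
                          structures = c("H", "F"),
                          timepoints = c(0, 3, 8, 12),
                          replicates_per_cell = 3,
                          treatments = c("untreated", "iCRT14"),
                          library_size_mean = 3e6,
                          library_size_cv = 0.15,
                          dispersion_log_mean = log(0.05),
                          dispersion_log_sd = 0.5,
                          baseline_log2_range = c(2, 10),
                          seed = 1L) {
  if (n_genes < 1 || n_peaks < 1 || replicates_per_cell < 1)
    stop("n_genes, n_peaks and replicates_per_cell must be >= 1")
  if (!0 %in% timepoints) stop("timepoints must include the 0 hpa control")
  structure(list(n_genes = n_genes, n_peaks = n_peaks,
                 structures = structures, timepoints = timepoints,
                 replicates_per_cell = replicates_per_cell,
                 treatments = treatments,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 dispersion_log_mean = dispersion_log_mean,
                 dispersion_log_sd = dispersion_log_sd,
                 baseline_log2_range = baseline_log2_range,
                 seed = as.integer(seed)),
            class = "DesignConfig")
}

#' Planted effect programs
#'
#' Describes what the generator plants, on top of flat baselines, as
#' log2 fold changes relative to the 0 hpa control:
#' * a generic, structure-independent injury program at 3 hpa
#'   (`injury_set`, effects ~ Normal(`mu_inj`, `sd_inj`));
#' * an apoptosis-like program, also symmetric at 3 hpa;
#' * structure-specific programs from 8 hpa onward: `head_set` features
#'   gain their context effect only in head-regenerating samples,
#'   `foot_set` only in foot-regenerating samples
#'   (effects ~ Normal(`mu_ctx`, `sd_ctx`));
#' * under iCRT14 the context effect is scaled by `icrt_delay`
#'   (default 0 at 8 hpa, 0.5 at 12 hpa: divergence is abolished at 8 and
#'   only partially recovered by 12), and a `prolong_fraction` of the
#'   injury program persists into 8/12 hpa (wound-response prolongation).
#'
#' @param injury_set,head_set,foot_set,apoptosis_set Character vectors of
#'   gene ids; `head_set` and `foot_set` must be disjoint.
#' @param mu_inj,sd_inj,mu_ctx,sd_ctx Effect-size distributions (log2FC).
#' @param icrt_delay Named numeric: fraction of the context effect
#'   retained under iCRT14 at each post-divergence timepoint.
#' @param prolong_injury,prolong_fraction Whether and for which fraction
#'   of injury features the 3 hpa program persists at 8/12 hpa under
#'   iCRT14.
#' @return A list of class `EffectModel`.
#' @export
effect_model <- function(injury_set = character(), head_set = character(),
                         foot_set = character(),
                         apoptosis_set = character(),
                         mu_inj = 2, sd_inj = 0.5,
                         mu_ctx = 2.5, sd_ctx = 0.5,
                         icrt_delay = c("8" = 0, "12" = 0.5),
                         prolong_injury = TRUE, prolong_fraction = 0.3) {
  if (length(intersect(head_set, foot_set)) > 0)
    stop("head_set and foot_set must be disjoint")
  structure(list(injury_set = injury_set, head_set = head_set,
                 foot_set = foot_set, apoptosis_set = apoptosis_set,
                 mu_inj = mu_inj, sd_inj = sd_inj,
                 mu_ctx = mu_ctx, sd_ctx = sd_ctx,
                 icrt_delay = icrt_delay,
                 prolong_injury = prolong_injury,
                 prolong_fraction = prolong_fraction),
            class = "EffectModel")
}

## Toy genome layout: one chromosome; each gene owns a 5 kb locus with a
## promoter peak straddling the gene start and (budget permitting) one
## distal peak inside the locus; leftover peaks are "orphans" placed in a
## gene-free region > 20 kb away from every gene.
.locus_size <- 5000L

synth_gene_models <- function(n_genes) {
  locus <- (seq_len(n_genes) - 1L) * .locus_size
  data.frame(chrom = "chr1", start = locus + 1000L, end = locus + 3000L,
             name = sprintf("g%04d", seq_len(n_genes)), score = 0,
             strand = "+", stringsAsFactors = FALSE)
}

synth_peak_layout <- function(n_genes, n_peaks) {
  n_prom <- min(n_genes, n_peaks)
  n_dist <- min(n_genes, n_peaks - n_prom)
  n_orph <- n_peaks - n_prom - n_dist
  locus <- (seq_len(n_genes) - 1L) * .locus_size
  starts <- c(locus[seq_len(n_prom)] + 900L,
              locus[seq_len(n_dist)] + 3500L)
  gene_of <- c(seq_len(n_prom), seq_len(n_dist))
  role <- c(rep("promoter", n_prom), rep("distal", n_dist))
  if (n_orph > 0) {
    orph0 <- n_genes * .locus_size + 50000L
    starts <- c(starts, orph0 + (seq_len(n_orph) - 1L) * 1500L)
    gene_of <- c(gene_of, rep(NA_integer_, n_orph))
    role <- c(role, rep("orphan", n_orph))
  }
  ord <- order(starts)
  peaks <- peak_set("chr1", starts[ord], starts[ord] + 500L,
                    name = sprintf("p%05d", seq_len(n_peaks)),
                    summit_offset = 250L)
  genes <- synth_gene_models(n_genes)
  list(peaks = peaks,
       peak_gene = data.frame(
         peak = peaks$name,
         gene = ifelse(is.na(gene_of[ord]), NA_character_,
                       genes$name[gene_of[ord]]),
         role = role[ord], stringsAsFactors = FALSE),
       genes = genes)
}

## log2FC matrix (features x design cells) implied by an EffectModel.
## `features` must contain every planted id.  Realised per-feature effect
## sizes are drawn here (deterministic given the stream seed).
synth_effect_lfc <- function(features, effects, config, seed) {
  groups <- expand.grid(structure = config$structures,
                        timepoint = config$timepoints,
                        treatment = config$treatments,
                        stringsAsFactors = FALSE)
  gl <- paste(groups$structure, groups$timepoint, groups$treatment,
              sep = ".")
  lfc <- matrix(0, length(features), nrow(groups),
                dimnames = list(features, gl))
  unknown <- setdiff(c(effects$injury_set, effects$head_set,
                       effects$foot_set, effects$apoptosis_set), features)
  if (length(unknown) > 0)
    stop("unknown feature ids in effect sets: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  eff <- with_seed(seed, list(
    inj = stats::rnorm(length(effects$injury_set), effects$mu_inj,
                       effects$sd_inj),
    apo = stats::rnorm(length(effects$apoptosis_set), effects$mu_inj,
                       effects$sd_inj),
    head = stats::rnorm(length(effects$head_set), effects$mu_ctx,
                        effects$sd_ctx),
    foot = stats::rnorm(length(effects$foot_set), effects$mu_ctx,
                        effects$sd_ctx),
    prolong = if (effects$prolong_injury && length(effects$injury_set) > 0)
      sample(effects$injury_set,
             round(effects$prolong_fraction * length(effects$injury_set)))
    else character()
  ))
  late <- setdiff(config$timepoints, c(0, 3))
  for (k in seq_len(nrow(groups))) {
    s <- groups$structure[k]; t <- groups$timepoint[k]
    tr <- groups$treatment[k]
    if (t == 3) {
      lfc[effects$injury_set, k] <- lfc[effects$injury_set, k] + eff$inj
      lfc[effects$apoptosis_set, k] <-
        lfc[effects$apoptosis_set, k] + eff$apo
    }
    if (t %in% late) {
      scale <- if (tr == "iCRT14") {
        d <- effects$icrt_delay[as.character(t)]
        if (is.na(d)) 0 else d
      } else 1
      if (s == "H")
        lfc[effects$head_set, k] <- lfc[effects$head_set, k] +
          scale * eff$head
      if (s == "F")
        lfc[effects$foot_set, k] <- lfc[effects$foot_set, k] +
          scale * eff$foot
      if (tr == "iCRT14" && length(eff$prolong) > 0) {
        idx <- match(eff$prolong, effects$injury_set)
        lfc[eff$prolong, k] <- lfc[eff$prolong, k] + eff$inj[idx]
      }
    }
  }
  list(lfc = lfc, effects = eff, groups = gl)
}

synth_counts <- function(lfc, baseline_log2, dispersion, design, lib_sizes,
                         seed) {
  q <- 2^baseline_log2
  q <- q / sum(q)
  gl <- paste(design$structure, design$timepoint, design$treatment,
              sep = ".")
  with_seed(seed, {
    n <- nrow(lfc)
    counts <- matrix(0L, n, nrow(design),
                     dimnames = list(rownames(lfc), design$sample))
    for (j in seq_len(nrow(design))) {
      mu <- lib_sizes[j] * q * 2^lfc[, gl[j]]
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    }
    counts
  })
}

#' Generate a synthetic RNA + ATAC experiment with ground truth
#'
#' Draws per-feature baselines and dispersions, plants the effect
#' programs of `effects` on the genes, propagates them to the linked ATAC
#' peaks (a gene's promoter and distal peaks inherit its log2FC), places
#' a planted injury-TF motif in the promoter peaks of injury genes plus
#' decoy motifs at random, and samples NB counts for every sample of the
#' factorial design.
#'
#' Counts are `NB(mean = library size x relative abundance x 2^log2FC,
#' dispersion = phi_feature)`. The root seed spawns one child stream per
#' stage, in this documented order: (1) child-seed draw, (2) RNA
#' baselines/dispersions, (3) ATAC baselines/dispersions, (4) library
#' sizes, (5) effect-size realisation, (6) RNA counts, (7) ATAC counts,
#' (8) motif placements and peak GC. Identical `(config, effects)` give
#' byte-identical output.
#'
#' @param config A [design_config()].
#' @param effects An [effect_model()] over gene ids `g0001`, ... If the
#'   planted sets are empty the experiment is a pure null.
#' @param n_decoy_motifs Decoy motifs placed independently of any planted
#'   program.
#' @param motif_background_rate Probability that a non-target peak
#'   carries the injury motif.
#' @param n_wnt_genes How many injury genes are flagged as the Wnt-like
#'   query list for the candidate-TF screen.
#' @return A list with elements `rna` and `atac` (both
#'   [count_experiment()]), `peaks`, `genes`, and `truth` (class
#'   `SyntheticTruth`): planted sets and realised effect sizes, per-
#'   feature baselines/dispersions, peak-to-gene links, motif placement
#'   matrix, peak GC, motif models, the injury motif id, decoys, the
#'   motif-to-TF map and the Wnt-like gene list.
#' @export
generate_experiment <- function(config, effects = effect_model(),
                                n_decoy_motifs = 8,
                                motif_background_rate = 0.05,
                                n_wnt_genes = 4) {
  stopifnot(inherits(config, "DesignConfig"),
            inherits(effects, "EffectModel"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 8))
  layout <- synth_peak_layout(config$n_genes, config$n_peaks)
  genes <- layout$genes$name
  peaks <- layout$peaks$name

  base_rna <- with_seed(seeds[1], list(
    b = stats::runif(config$n_genes, config$baseline_log2_range[1],
                     config$baseline_log2_range[2]),
    phi = exp(stats::rnorm(config$n_genes, config$dispersion_log_mean,
                           config$dispersion_log_sd))))
  base_atac <- with_seed(seeds[2], list(
    b = stats::runif(config$n_peaks, config$baseline_log2_range[1],
                     config$baseline_log2_range[2]),
    phi = exp(stats::rnorm(config$n_peaks, config$dispersion_log_mean,
                           config$dispersion_log_sd))))

  design <- expand.grid(structure = config$structures,
                        timepoint = config$timepoints,
                        treatment = config$treatments,
                        replicate = seq_len(config$replicates_per_cell),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%sh_%s_r%d",
                           design$structure, design$timepoint,
                           ifelse(design$treatment == "iCRT14", "icrt",
                                  "untr"),
                           design$replicate)
  design <- design[, c("sample", "structure", "timepoint", "treatment",
                       "replicate")]
  n_samp <- nrow(design)
  libs <- with_seed(seeds[3], pmax(
    stats::rnorm(2 * n_samp, config$library_size_mean,
                 config$library_size_cv * config$library_size_mean),
    0.2 * config$library_size_mean))
  lib_rna <- libs[seq_len(n_samp)]
  lib_atac <- libs[n_samp + seq_len(n_samp)]

  gene_eff <- synth_effect_lfc(genes, effects, config, seeds[4])
  ## ATAC peaks inherit the log2FC of their linked gene
  peak_lfc <- matrix(0, config$n_peaks, ncol(gene_eff$lfc),
                     dimnames = list(peaks, colnames(gene_eff$lfc)))
  linked <- !is.na(layout$peak_gene$gene)
  peak_lfc[linked, ] <- gene_eff$lfc[layout$peak_gene$gene[linked], ]

  rna <- count_experiment(
    synth_counts(gene_eff$lfc, base_rna$b, base_rna$phi, design, lib_rna,
                 seeds[5]), design)
  atac <- count_experiment(
    synth_counts(peak_lfc, base_atac$b, base_atac$phi, design, lib_atac,
                 seeds[6]), design)

  mot <- with_seed(seeds[7], {
    injury_prom <- layout$peak_gene$peak[
      layout$peak_gene$role == "promoter" &
      layout$peak_gene$gene %in% effects$injury_set]
    placements <- matrix(FALSE, config$n_peaks, 1 + n_decoy_motifs,
                         dimnames = list(peaks, c("M_INJ",
                           sprintf("M_DEC%02d", seq_len(n_decoy_motifs)))))
    placements[, "M_INJ"] <-
      stats::runif(config$n_peaks) < motif_background_rate
    placements[injury_prom, "M_INJ"] <- TRUE
    for (k in seq_len(n_decoy_motifs))
      placements[, k + 1] <- stats::runif(config$n_peaks) < 0.10
    ## guarantee every motif annotates at least one peak
    for (k in seq_len(ncol(placements)))
      if (!any(placements[, k])) placements[1, k] <- TRUE
    gc <- stats::runif(config$n_peaks, 0.3, 0.6)
    models <- lapply(colnames(placements), function(id) {
      m <- matrix(stats::runif(4 * 8, 0.05, 1), 4, 8)
      motif_model(id, sweep(m, 2, colSums(m), "/"))
    })
    names(models) <- colnames(placements)
    list(placements = placements, gc = gc, models = models)
  })

  tf_genes <- c(utils::head(effects$injury_set, 1),
                setdiff(genes, c(effects$injury_set, effects$head_set,
                                 effects$foot_set))[seq_len(n_decoy_motifs)])
  motif_tf_map <- data.frame(motif = colnames(mot$placements),
                             tf = tf_genes[seq_len(1 + n_decoy_motifs)],
                             stringsAsFactors = FALSE)
  wnt_genes <- utils::head(effects$injury_set,
                           min(n_wnt_genes, length(effects$injury_set)))

  truth <- structure(list(
    config = unclass(config), effect_model = unclass(effects),
    realized = list(injury = stats::setNames(gene_eff$effects$inj,
                                             effects$injury_set),
                    apoptosis = stats::setNames(gene_eff$effects$apo,
                                                effects$apoptosis_set),
                    head = stats::setNames(gene_eff$effects$head,
                                           effects$head_set),
                    foot = stats::setNames(gene_eff$effects$foot,
                                           effects$foot_set),
                    prolonged = gene_eff$effects$prolong),
    baseline_log2 = list(rna = stats::setNames(base_rna$b, genes),
                         atac = stats::setNames(base_atac$b, peaks)),
    dispersion = list(rna = stats::setNames(base_rna$phi, genes),
                      atac = stats::setNames(base_atac$phi, peaks)),
    peak_gene = layout$peak_gene,
    motif_placements = mot$placements,
    peak_gc = stats::setNames(mot$gc, peaks),
    injury_motif = "M_INJ",
    decoy_motifs = setdiff(colnames(mot$placements), "M_INJ"),
    motif_tf_map = motif_tf_map,
    wnt_genes = wnt_genes), class = "SyntheticTruth")

  list(rna = rna, atac = atac, peaks = layout$peaks,
       genes = layout$genes, motifs = mot$models, truth = truth)
}

#' Generate per-replicate scored peak lists for IDR
#'
#' A `reproducible_fraction` of the peaks share a latent signal
#' (~ Normal(3, 1)) observed in every replicate with Normal(0,
#' `noise_sd`) measurement error; the remaining peaks get fully
#' independent Normal(0, 1) scores per replicate. With `noise_sd = 1/3`
#' the reproducible-component score correlation is 0.9.
#'
#' @param peaks A [peak_set()] giving peak identities and coordinates.
#' @param n_replicates Number of replicate score lists (>= 2).
#' @param reproducible_fraction Fraction of peaks in the reproducible
#'   component, in `[0, 1]`.
#' @param noise_sd Replicate measurement noise on the latent signal.
#' @param seed Integer seed.
#' @return Object of class `ScoredPeakReplicates`: a list with
#'   `replicates` (list of `PeakSet`s sharing coordinates, differing in
#'   score) and `reproducible` (the planted reproducible peak names).
#' @export
generate_scored_replicates <- function(peaks, n_replicates = 3,
                                       reproducible_fraction = 0.7,
                                       noise_sd = 1 / 3, seed = 1L) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (reproducible_fraction < 0 || reproducible_fraction > 1)
    stop("reproducible_fraction must be in [0, 1]")
  n <- nrow(peaks)
  with_seed(seed, {
    n_rep <- round(reproducible_fraction * n)
    rep_idx <- sort(sample.int(n, n_rep))
    latent <- stats::rnorm(n_rep, mean = 3, sd = 1)
    reps <- lapply(seq_len(n_replicates), function(k) {
      s <- stats::rnorm(n)               # irreproducible component
      s[rep_idx] <- latent +
        if (noise_sd > 0) stats::rnorm(n_rep, sd = noise_sd) else 0
      out <- peaks
      out$score <- s
      out
    })
    structure(list(replicates = reps,
                   reproducible = peaks$name[rep_idx]),
              class = "ScoredPeakReplicates")
  })
}

#' Generate synthetic TSS coverage profiles
#'
#' Per-gene Poisson coverage over positions `-flank .. +flank` around the
#' TSS with a Gaussian accessibility bump at the centre: the expected
#' central signal is `enrichment` times the expected flank signal.
#'
#' @param n_genes Number of genes (> 0).
#' @param enrichment Fold enrichment at the TSS (>= 1).
#' @param flank Flank half-width in bp (> 0).
#' @param base_rate Expected flank coverage per position.
#' @param bump_sd Width (sd, bp) of the central accessibility bump.
#' @param seed Integer seed.
#' @return Matrix `n_genes x (2 * flank + 1)`; column names are the
#'   positions relative to the TSS.
#' @export
generate_tss_profiles <- function(n_genes = 2000, enrichment = 7,
                                  flank = 1000, base_rate = 1,
                                  bump_sd = 50, seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be > 0")
  if (flank <= 0) stop("flank must be > 0")
  if (enrichment < 1) stop("enrichment must be >= 1")
  pos <- seq(-flank, flank)
  lambda <- base_rate * (1 + (enrichment - 1) * exp(-pos^2 / (2 * bump_sd^2)))
  with_seed(seed, {
    m <- matrix(stats::rpois(n_genes * length(pos),
                             rep(lambda, each = n_genes)),
                nrow = n_genes)
    colnames(m) <- pos
    m
  })
}

#' Generate a two-cluster head/foot single-cell count matrix
#'
#' Emulates epithelial head vs foot cells from a single-cell atlas:
#' sparse NB counts with planted marker genes differing between the two
#' clusters by `effect_log2fc` in expectation.
#'
#' @param genes All gene ids.
#' @param markers_head,markers_foot Disjoint subsets of `genes` elevated
#'   in the head or foot cluster.
#' @param n_cells_per_cluster Cells per cluster.
#' @param effect_log2fc Planted marker log2 fold change.
#' @param base_mean_log2_range Per-gene baseline mean expression range
#'   (log2 scale).
#' @param dispersion NB dispersion (1/size) for all genes.
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells) and `clusters`
#'   (`"head"`/`"foot"` per cell).
#' @export
generate_single_cell <- function(genes, markers_head = character(),
                                 markers_foot = character(),
                                 n_cells_per_cluster = 300,
                                 effect_log2fc = 3,
                                 base_mean_log2_range = c(-2, 2),
                                 dispersion = 0.5, seed = 1L) {
  if (length(intersect(markers_head, markers_foot)) > 0)
    stop("marker sets must be disjoint")
  unknown <- setdiff(c(markers_head, markers_foot), genes)
  if (length(unknown) > 0)
    stop("unknown marker genes: ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    n_g <- length(genes)
    mu <- 2^stats::runif(n_g, base_mean_log2_range[1],
                         base_mean_log2_range[2])
    names(mu) <- genes
    mu_head <- mu; mu_foot <- mu
    mu_head[markers_head] <- mu[markers_head] * 2^effect_log2fc
    mu_foot[markers_foot] <- mu[markers_foot] * 2^effect_log2fc
    draw <- function(mu_c, n_cells) {
      matrix(stats::rnbinom(n_g * n_cells, mu = rep(mu_c, n_cells),
                            size = 1 / dispersion), nrow = n_g)
    }
    counts <- cbind(draw(mu_head, n_cells_per_cluster),
                    draw(mu_foot, n_cells_per_cluster))
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell_%04d", seq_len(ncol(counts)))
    list(counts = counts,
         clusters = rep(c("head", "foot"), each = n_cells_per_cluster))
  })
}

#' Write a generated experiment to disk in standard formats
#'
#' Counts and sample sheets as TSV, peaks as narrowPeak, gene models as
#' BED6, the ground truth as JSON and the configuration as YAML.
#'
#' @param sim Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$rna, file.path(dir, "rna_counts.tsv"),
               file.path(dir, "rna_samples.tsv"))
  write_counts(sim$atac, file.path(dir, "atac_counts.tsv"),
               file.path(dir, "atac_samples.tsv"))
  write_narrowpeak(sim$peaks, file.path(dir, "peaks.narrowPeak"))
  write_bed6(sim$genes, file.path(dir, "genes.bed"))
  write_pwm(sim$motifs, file.path(dir, "motifs.pwm"))
  write_truth(sim$truth, file.path(dir, "truth.json"))
  yaml::write_yaml(sim$truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialise / deserialise the synthetic ground truth as JSON
#'
#' @param truth A `SyntheticTruth`.
#' @param path JSON path.
#' @return `read_truth` returns the reconstructed `SyntheticTruth`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  ## named numeric vectors must become JSON objects, not arrays,
  ## so that names survive the round-trip
  dictify <- function(v) if (length(v) && !is.null(names(v)))
    as.list(v) else v
  x$realized <- lapply(x$realized, dictify)
  x$baseline_log2 <- lapply(x$baseline_log2, dictify)
  x$dispersion <- lapply(x$dispersion, dictify)
  x$peak_gc <- dictify(x$peak_gc)
  x$motif_placements <- list(
    peaks = rownames(truth$motif_placements),
    motifs = colnames(truth$motif_placements),
    which = apply(truth$motif_placements, 2, which, simplify = FALSE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  undict <- function(v) if (is.list(v)) unlist(v) else v
  x$realized <- lapply(x$realized, undict)
  x$baseline_log2 <- lapply(x$baseline_log2, undict)
  x$dispersion <- lapply(x$dispersion, undict)
  x$peak_gc <- undict(x$peak_gc)
  mp <- matrix(FALSE, length(x$motif_placements$peaks),
               length(x$motif_placements$motifs),
               dimnames = list(x$motif_placements$peaks,
                               x$motif_placements$motifs))
  for (m in names(x$motif_placements$which))
    mp[x$motif_placements$which[[m]], m] <- TRUE
  x$motif_placements <- mp
  x$peak_gene <- as.data.frame(x$peak_gene, stringsAsFactors = FALSE)
  x$motif_tf_map <- as.data.frame(x$motif_tf_map, stringsAsFactors = FALSE)
  structure(x, class = "SyntheticTruth")
}
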