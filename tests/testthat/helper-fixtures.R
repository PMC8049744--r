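# Shared fixtures, built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixture_env)) {
    assign(name, force(expr), .fixture_env)
  }
  get(name, .fixture_env)
}

# A small experiment with planted injury + context programs.
small_sim <- function() {
  fixture("small_sim", {
    generate_experiment(
      design_config(n_genes = 300, n_peaks = 700, seed = 42),
      effect_model(injury_set = sprintf("g%04d", 1:30),
                   head_set = sprintf("g%04d", 31:55),
                   foot_set = sprintf("g%04d", 56:80),
                   apoptosis_set = sprintf("g%04d", 81:90)))
  })
}

small_rna_fit <- function() {
  fixture("small_rna_fit", {
    sim <- small_sim()
    nexp <- normalize_experiment(sim$rna)
    fit_nb_ql(nexp, group_design(sim$rna$design))
  })
}

# Deterministic toy CountExperiment: counts column sums = 1e6 so that
# counts and CPM coincide.
toy_experiment <- function(counts) {
  n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%d", seq_len(n))
  design <- data.frame(sample = colnames(counts),
                       structure = rep(c("H", "F"), length.out = n),
                       timepoint = 0, treatment = "untreated",
                       replicate = seq_len(n))
  count_experiment(counts, design)
}
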