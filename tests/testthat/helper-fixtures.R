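# Shared small simulation fixtures, built once per test run.

suppressMessages(library(dplyr))

fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2,
                   n_genes_per_chromosome = 40, nbs_fraction = 0.2,
                   protein_len_range = c(80, 150), loss_prob = 0.35)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# a noiseless genome set: no sequence divergence, no expression noise
noiseless_sim <- function() {
  if (is.null(fixture_env$noiseless)) {
    cfg <- small_sim_config(
      seed = 99,
      ks_target_per_lineage = c(lineage_a = 0, lineage_b = 0),
      tandem_ks = 0, expression_noise_sd = 0)
    fixture_env$noiseless <- generate_genome_set(cfg)
  }
  fixture_env$noiseless
}

# a default-divergence genome set for pipeline-level tests
default_sim_dir <- function() {
  if (is.null(fixture_env$pipe_dir)) {
    cfg <- pipeline_config(seed = 5, sim = small_sim_config(seed = 5))
    dir <- file.path(tempdir(), "nbsfam_pipe_fixture")
    run_pipeline(cfg, dir)
    fixture_env$pipe_dir <- dir
    fixture_env$pipe_cfg <- cfg
  }
  list(dir = fixture_env$pipe_dir, config = fixture_env$pipe_cfg)
}

# genes tibble shorthand for rule tests: one chromosome, given family ranks
genes_with_family_at <- function(fam_ranks, n = 30, chromosome = "chr01") {
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chromosome = chromosome,
    rank = seq_len(n) - 1L,
    is_family = (seq_len(n) - 1L) %in% fam_ranks)
}
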