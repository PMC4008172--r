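# Synthetic genome generator: configuration validation, determinism,
# degenerate dials, retention/loss behaviour, codon evolution, expression.

test_that("configuration rejects invalid probability vectors", {
  expect_error(simulation_config(nbs_fraction = 1.5), class = "nbsfam_config_error")
  expect_error(simulation_config(architecture_mix = c(TNL = 0.6, N = 0.3)),
               class = "nbsfam_config_error")
  expect_error(simulation_config(retention_probs = c(0.5, 0.5)),
               class = "nbsfam_config_error")
  expect_error(simulation_config(retention_probs = c(0.5, 0.4, 0.2)),
               class = "nbsfam_config_error")
  expect_error(simulation_config(loss_prob = -0.1), class = "nbsfam_config_error")
  expect_error(simulation_config(omega_per_lineage = c(a = -1),
                                 ks_target_per_lineage = c(a = 0.1)),
               class = "nbsfam_config_error")
  expect_error(simulation_config(expression_divergence = c(ortholog = 3,
                                                           paralog = 1)),
               class = "nbsfam_config_error")
  expect_error(simulation_config(architecture_mix = c(TNL = 0.5, QRS = 0.5)),
               class = "nbsfam_config_error")
})

test_that("the same seed reproduces byte-identical genome files", {
  cfg <- small_sim_config(seed = 7)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  write_genome_set(generate_genome_set(cfg), d1)
  write_genome_set(generate_genome_set(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(sums1), unname(sums2))
})

test_that("degenerate dials behave as documented", {
  # nbs_fraction 0 and no planted arrays: no gene carries NBS motifs
  cfg0 <- small_sim_config(
    nbs_fraction = 0,
    tandem_array_spec = tibble::tibble(len = integer(), epoch = character()))
  anc0 <- generate_ancestor(cfg0)
  expect_true(all(is.na(anc0$genes$family)))
  expect_equal(nrow(scan_domains(anc0$proteins)), 0)

  # point-mass architecture mix: every family gene is TNL
  cfg1 <- small_sim_config(nbs_fraction = 0.5,
                           architecture_mix = c(TNL = 1.0))
  anc1 <- generate_ancestor(cfg1)
  fam <- anc1$genes$architecture[!is.na(anc1$genes$architecture)]
  expect_gt(length(fam), 20)
  expect_true(all(fam == "TNL"))
})

test_that("ancestor gene models are well formed", {
  anc <- generate_ancestor(small_sim_config())
  ranks <- anc$genes %>% dplyr::group_by(chromosome) %>%
    dplyr::summarise(ok = all(rank == seq_len(dplyr::n()) - 1L))
  expect_true(all(ranks$ok))
  expect_true(all(nchar(anc$cds) %% 3 == 0))
  aa <- vapply(anc$cds, function(s)
    paste(Biostrings::GENETIC_CODE[substring(s, seq(1, nchar(s), 3),
                                             seq(3, nchar(s), 3))],
          collapse = ""), character(1))
  expect_false(any(grepl("*", aa, fixed = TRUE)))
  expect_true(all(anc$genes$start >= 1 & anc$genes$start <= anc$genes$end))
})

test_that("forced retention dials produce the forced copy-count histograms", {
  cfg3 <- small_sim_config(loss_prob = 0, retention_probs = c(0, 0, 1),
                           tandem_array_spec = tibble::tibble(
                             len = integer(), epoch = character()))
  anc <- generate_ancestor(cfg3)
  d <- triplicate_and_fractionate(anc, cfg3, "lineage_a")
  copies <- table(d$truth$copy_map$ancestor_gene)
  expect_equal(length(copies), nrow(anc$genes))
  expect_true(all(copies == 3))

  cfg1 <- small_sim_config(loss_prob = 0, retention_probs = c(1, 0, 0),
                           tandem_array_spec = tibble::tibble(
                             len = integer(), epoch = character()))
  anc1 <- generate_ancestor(cfg1)
  d1 <- triplicate_and_fractionate(anc1, cfg1, "lineage_a")
  copies1 <- table(d1$truth$copy_map$ancestor_gene)
  expect_equal(length(copies1), nrow(anc1$genes))
  expect_true(all(copies1 == 1))
})

test_that("descendant copies preserve ancestral order within subgenomes", {
  sim <- noiseless_sim()
  for (ln in c("lineage_a", "lineage_b")) {
    g <- sim$species[[ln]]$genes %>% dplyr::filter(origin == "wgt")
    anc_rank <- sim$species$ancestor$genes$rank
    names(anc_rank) <- sim$species$ancestor$genes$gene_id
    ok <- g %>% dplyr::group_by(chromosome) %>%
      dplyr::summarise(ok = !is.unsorted(anc_rank[ancestor_gene]))
    expect_true(all(ok$ok))
  }
})

test_that("truth tables account for every gene exactly once", {
  sim <- noiseless_sim()
  all_ids <- sim$truth$genes$gene_id
  expect_equal(anyDuplicated(all_ids), 0)
  emitted <- unlist(lapply(sim$species, function(s) s$genes$gene_id))
  expect_setequal(all_ids, emitted)
  copies_per_anc <- table(factor(sim$truth$copy_map$ancestor_gene,
                                 levels = sim$species$ancestor$genes$gene_id))
  expect_true(all(copies_per_anc >= 0 & copies_per_anc <= 6))  # 2 lineages x 0..3
  per_lineage <- sim$truth$copy_map %>% dplyr::count(lineage, ancestor_gene)
  expect_true(all(per_lineage$n <= 3))
  # sum over copies equals the number of wgt-descendant genes
  n_wgt <- sum(unlist(lapply(sim$species[-1], function(s)
    sum(s$genes$origin == "wgt"))))
  expect_equal(nrow(sim$truth$copy_map), n_wgt)
})

test_that("codon evolution honours its dials and rejects bad ones", {
  cds <- c(a = "ATGGCTAAGGGTTTGCGTACTGAAGATCCA",
           b = "ATGTCTGCTGCTAAGCGTGAAGGTATCACT")
  expect_identical(evolve_sequences(cds, omega = 0.5, ks_target = 0), cds)
  expect_error(evolve_sequences(cds, omega = -1, ks_target = 0.1),
               class = "nbsfam_config_error")

  evolved <- evolve_sequences(cds, omega = 0, ks_target = 0.6, seed = 3)
  translate <- function(s) paste(
    Biostrings::GENETIC_CODE[substring(s, seq(1, nchar(s), 3),
                                       seq(3, nchar(s), 3))], collapse = "")
  expect_false(identical(evolved, cds))
  expect_identical(vapply(evolved, translate, character(1)),
                   vapply(cds, translate, character(1)))
})

test_that("expression dials control pair divergence", {
  expect_error(
    simulate_expression(tibble::tibble(gene_a = "a", gene_b = "b",
                                       relation = "ortholog"),
                        tissues = letters[1:5],
                        divergence = c(ortholog = -1, paralog = 1)),
    class = "nbsfam_config_error")

  tissues <- c("root", "stalk", "leaf", "flower", "silique", "callus")
  pairs <- tibble::tibble(gene_a = sprintf("a%02d", 1:20),
                          gene_b = sprintf("b%02d", 1:20),
                          relation = "ortholog")
  # dial 0 with zero noise: correlation exactly 1
  m0 <- simulate_expression(pairs, tissues,
                            divergence = c(ortholog = 0, paralog = 1),
                            noise_sd = 0, seed = 8)
  vals <- as.matrix(m0[, tissues])
  rownames(vals) <- m0$gene_id
  for (i in 1:20) {
    expect_equal(unname(cor(log2(vals[pairs$gene_a[i], ] + 1),
                            log2(vals[pairs$gene_b[i], ] + 1))), 1,
                 tolerance = 1e-12)
  }
  expect_true(all(vals >= 0))

  # ordered dials give ordered mean divergence
  pairs2 <- tibble::tibble(
    gene_a = sprintf("g%03d_a", 1:80),
    gene_b = sprintf("g%03d_b", 1:80),
    relation = rep(c("ortholog", "paralog"), each = 40))
  m <- simulate_expression(pairs2, tissues,
                           divergence = c(ortholog = 0.2, paralog = 1.0),
                           noise_sd = 0.1, seed = 9)
  lg <- log_transform(m)
  div <- pair_divergence(lg, pairs2)
  means <- setNames(div$summary$mean_score, div$summary$relation)
  expect_gt(means["paralog"], means["ortholog"])
})
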