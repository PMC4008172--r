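# Anchor finding, collinear chaining, ortholog pair extraction and
# retention accounting.

mk_genes <- function(ids, chromosome = "c1") {
  tibble::tibble(gene_id = ids, chromosome = chromosome,
                 rank = seq_along(ids) - 1L)
}

test_that("anchors require known genes and pass the threshold", {
  ga <- mk_genes(sprintf("a%d", 1:10))
  gb <- mk_genes(sprintf("b%d", 1:10))
  empty <- tibble::tibble(gene_a = character(), gene_b = character(),
                          evalue = numeric())
  expect_equal(nrow(find_anchors(empty, ga, gb)), 0)

  sim <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                        evalue = c(1e-30, 1e-5))
  anc <- find_anchors(sim, ga, gb)
  expect_equal(nrow(anc), 1)  # 1e-5 fails the 1e-20 cutoff
  expect_equal(nrow(find_anchors(sim, ga, gb, evalue_max = 1e-40)), 0)

  bad <- tibble::tibble(gene_a = "zz", gene_b = "b1", evalue = 1e-30)
  expect_error(find_anchors(bad, ga, gb), class = "nbsfam_input_error")
})

test_that("block chaining honours the minimum anchor count", {
  ga <- mk_genes(sprintf("a%d", 1:10))
  gb <- mk_genes(sprintf("b%d", 1:10))
  mk_anchors <- function(k) {
    tibble::tibble(gene_a = sprintf("a%d", 1:k), gene_b = sprintf("b%d", 1:k),
                   evalue = 1e-30) |>
      find_anchors(ga, gb)
  }
  blk5 <- chain_blocks(mk_anchors(5))
  expect_equal(nrow(blk5), 5)
  expect_equal(dplyr::n_distinct(blk5$block_id), 1)
  expect_equal(unique(blk5$orientation), "same")
  expect_equal(nrow(chain_blocks(mk_anchors(4))), 0)
})

test_that("inverted blocks are chained", {
  ga <- mk_genes(sprintf("a%d", 1:6))
  gb <- mk_genes(sprintf("b%d", 1:6))
  sim <- tibble::tibble(gene_a = sprintf("a%d", 1:6),
                        gene_b = sprintf("b%d", 6:1), evalue = 1e-30)
  blk <- chain_blocks(find_anchors(sim, ga, gb))
  expect_equal(nrow(blk), 6)
  expect_equal(unique(blk$orientation), "inverted")
})

test_that("chaining matches the exhaustive maximum-chain oracle", {
  set.seed(77)
  for (rep in 1:12) {
    k <- sample(6:12, 1)
    anchors <- tibble::tibble(
      gene_a = sprintf("a%d", 1:k), gene_b = sprintf("b%d", 1:k),
      chr_a = "c1", chr_b = "c1",
      rank_a = sample(0:9, k, replace = TRUE),
      rank_b = sample(0:9, k, replace = TRUE))
    anchors <- dplyr::distinct(anchors, rank_a, rank_b, .keep_all = TRUE)
    got <- chain_blocks(anchors, min_anchors = 1L)
    # score of the best extracted block
    best_block <- got[got$block_id == got$block_id[1], ]
    da <- diff(best_block$rank_a)
    db <- abs(diff(best_block$rank_b))
    got_score <- nrow(best_block) * 10 -
      (sum(pmax(da - 1, 0)) + sum(pmax(db - 1, 0)))
    expect_equal(got_score, oracle_max_chain_score(anchors),
                 info = paste("instance", rep))
  }
})

test_that("ortholog pairs come only from NBS-NBS anchors inside blocks", {
  ga <- mk_genes(sprintf("a%d", 1:8))
  gb <- mk_genes(sprintf("b%d", 1:8))
  sim <- tibble::tibble(gene_a = sprintf("a%d", 1:8),
                        gene_b = sprintf("b%d", 1:8), evalue = 1e-30)
  blocks <- chain_blocks(find_anchors(sim, ga, gb))
  class_a <- tibble::tibble(gene_id = c("a2", "a5"),
                            category = c("TNL", "TIR-X"))
  class_b <- tibble::tibble(gene_id = c("b2", "b5"),
                            category = c("NBS", "TNL"))
  pairs <- extract_ortholog_pairs(blocks, class_a, class_b)
  expect_equal(nrow(pairs), 1)  # a5 is TIR-X (not NBS-encoding), b2 pairs a2
  expect_equal(pairs$ref_gene, "a2")
  expect_equal(pairs$counterpart, "b2")

  none <- extract_ortholog_pairs(blocks, tibble::tibble(gene_id = character(),
                                                        category = character()),
                                 class_b)
  expect_equal(nrow(none), 0)
})

test_that("retention accounting reproduces the published histograms", {
  empty <- retention_accounting(tibble::tibble(ref_gene = character(),
                                               counterpart = character()))
  expect_equal(nrow(empty$histogram), 0)

  bo <- retention_accounting(load_ortholog_pairs("boleracea"))
  expect_equal(bo$n_pairs, 42)
  h_bo <- setNames(bo$histogram$n_ref_genes, bo$histogram$copies)
  expect_equal(unname(h_bo[c("1", "2", "3")]), c(26, 5, 2))

  br <- retention_accounting(load_ortholog_pairs("brapa"))
  expect_equal(br$n_pairs, 62)
  h_br <- setNames(br$histogram$n_ref_genes, br$histogram$copies)
  expect_equal(unname(h_br[c("1", "2", "3")]), c(40, 8, 2))

  # conservation: sum(copies x count) = pairs; sum(count) = reference genes
  expect_equal(sum(bo$histogram$copies * bo$histogram$n_ref_genes), 42)
  expect_equal(sum(bo$histogram$n_ref_genes), 33)
  expect_equal(sum(br$histogram$n_ref_genes), 50)

  over <- tibble::tibble(ref_gene = rep("r", 4),
                         counterpart = sprintf("c%d", 1:4))
  expect_warning(retention_accounting(over), "over-retention")
})

test_that("cross-comparison reports overlap, union and retained fractions", {
  a <- retention_accounting(tibble::tibble(ref_gene = c("r1", "r2"),
                                           counterpart = c("x1", "x2")))
  b <- retention_accounting(tibble::tibble(ref_gene = c("r3"),
                                           counterpart = c("y1")))
  disjoint <- cross_comparison_sets(a, b)
  expect_equal(disjoint$overlap, 0)
  expect_equal(disjoint$union, 3)

  bo <- retention_accounting(load_ortholog_pairs("boleracea"))
  br <- retention_accounting(load_ortholog_pairs("brapa"))
  cross <- cross_comparison_sets(bo, br, total_a = 157, total_b = 206,
                                 total_ref = 167)
  expect_equal(cross$overlap, 24)
  expect_equal(cross$union, 59)
  expect_equal(cross$retained_a, 42)
  expect_equal(cross$retained_pct_a, 26.75)
  expect_equal(cross$retained_b, 62)
  expect_equal(cross$retained_pct_b, 30.1)
})

test_that("zero-divergence triplication is fully recovered by the synteny route", {
  cfg <- simulation_config(
    seed = 31, n_chromosomes = 2, n_genes_per_chromosome = 60,
    nbs_fraction = 0.2, protein_len_range = c(80, 150),
    loss_prob = 0.1, retention_probs = c(0.7, 0.2, 0.1),
    tandem_array_spec = tibble::tibble(len = integer(), epoch = character()),
    omega_per_lineage = c(lineage_a = 0.3),
    ks_target_per_lineage = c(lineage_a = 0))
  sim <- generate_genome_set(cfg)
  anc <- sim$species$ancestor
  d <- sim$species$lineage_a

  hom <- find_homolog_pairs(anc$proteins, d$proteins, min_identity = 95)
  # every surviving copy anchors to its ancestor gene
  truth_pairs <- paste(sim$truth$copy_map$ancestor_gene,
                       sim$truth$copy_map$gene_id)
  expect_true(all(truth_pairs %in% paste(hom$gene_a, hom$gene_b)))

  anchors <- find_anchors(hom, anc$genes, d$genes)
  blocks <- chain_blocks(anchors)
  cls_anc <- tibble::tibble(
    gene_id = anc$genes$gene_id[anc$genes$family %in% "NBS"],
    category = "NBS")
  cls_d <- tibble::tibble(
    gene_id = d$genes$gene_id[d$genes$family %in% "NBS"],
    category = "NBS")
  pairs <- extract_ortholog_pairs(blocks, cls_anc, cls_d)
  rec <- retention_accounting(pairs)

  truth_counts <- sim$truth$copy_map
  truth_counts <- truth_counts[truth_counts$gene_id %in% d$genes$gene_id &
                                 truth_counts$ancestor_gene %in%
                                 cls_anc$gene_id, ]
  truth_hist <- table(table(truth_counts$ancestor_gene))
  got_hist <- setNames(rec$histogram$n_ref_genes, rec$histogram$copies)
  expect_equal(got_hist[names(truth_hist)],
               setNames(as.integer(truth_hist), names(truth_hist)))
})
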