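# Cluster calling, homogeneity, tandem arrays and epoch classification.

test_that("the 8-ORF rule is applied at its boundaries", {
  g <- genes_with_family_at(c(10, 15), n = 30)
  cl <- call_clusters(g)
  expect_equal(nrow(cl), 2)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)

  g2 <- genes_with_family_at(c(10, 20), n = 30)
  expect_equal(nrow(call_clusters(g2)), 0)  # 9 intervening: singletons

  g3 <- genes_with_family_at(c(5, 13, 21), n = 30)
  cl3 <- call_clusters(g3)
  expect_equal(nrow(cl3), 3)
  expect_equal(dplyr::n_distinct(cl3$cluster_id), 1)
})

test_that("duplicate ranks are rejected", {
  g <- genes_with_family_at(c(2, 4), n = 10)
  g$rank[2] <- g$rank[3]
  expect_error(call_clusters(g), class = "nbsfam_input_error")
})

test_that("cluster calling matches the brute-force oracle on random placements", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    fam_ranks <- sort(sample(0:(n - 1), sample(2:8, 1)))
    g <- genes_with_family_at(fam_ranks, n = n)
    got <- call_clusters(g)
    got_sets <- unname(lapply(split(got$gene_id, got$cluster_id), sort))
    got_sets <- got_sets[order(vapply(got_sets, `[`, character(1), 1))]
    expect_identical(got_sets, oracle_clusters(g))
  }
})

test_that("homogeneity reflects member categories", {
  cl <- tibble::tibble(cluster_id = c("c1", "c1", "c1", "c2", "c2"),
                       chromosome = "chr01",
                       gene_id = c("a", "b", "c", "d", "e"),
                       rank = 0:4)
  cls <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e"),
                        category = c("TIR-NBS", "TIR-NBS", "TIR-NBS",
                                     "TNL", "NBS"))
  hom <- label_homogeneity(cl, cls)
  expect_equal(hom$homogeneity[hom$cluster_id == "c1"], "homogeneous")
  expect_equal(hom$homogeneity[hom$cluster_id == "c2"], "heterogeneous")

  hom1 <- label_homogeneity(cl[cl$cluster_id == "c1", ][1:2, ], cls)
  expect_equal(hom1$homogeneity, "homogeneous")
})

test_that("tandem arrays allow at most one intervening gene per adjacent pair", {
  edges <- tibble::tibble(gene_a = "g006", gene_b = c("g007", "g008", "g009"))
  g <- genes_with_family_at(c(5, 6), n = 12)
  expect_equal(nrow(detect_tandem_arrays(
    g, tibble::tibble(gene_a = "g006", gene_b = "g007"))), 2)

  g2 <- genes_with_family_at(c(5, 7), n = 12)
  expect_equal(nrow(detect_tandem_arrays(
    g2, tibble::tibble(gene_a = "g006", gene_b = "g008"))), 2)

  g3 <- genes_with_family_at(c(5, 8), n = 12)
  expect_equal(nrow(detect_tandem_arrays(
    g3, tibble::tibble(gene_a = "g006", gene_b = "g009"))), 0)

  # adjacency without similarity is not an array
  g4 <- genes_with_family_at(c(5, 6), n = 12)
  expect_equal(nrow(detect_tandem_arrays(
    g4, tibble::tibble(gene_a = character(), gene_b = character()))), 0)

  expect_error(detect_tandem_arrays(
    g, tibble::tibble(gene_a = "g006", gene_b = "nope")),
    class = "nbsfam_input_error")
})

test_that("no gene belongs to two arrays", {
  g <- genes_with_family_at(c(2, 3, 4, 6, 8), n = 15)
  edges <- tibble::tibble(
    gene_a = c("g003", "g004", "g005", "g007"),
    gene_b = c("g004", "g005", "g007", "g009"))
  arr <- detect_tandem_arrays(g, edges)
  expect_equal(anyDuplicated(arr$gene_id), 0)
})

test_that("planted arrays are recovered and epoch-labelled from truth maps", {
  sim <- noiseless_sim()
  arrays_by_sp <- lapply(c("ancestor", "lineage_a", "lineage_b"),
                         function(sp) {
    g <- sim$species[[sp]]$genes
    g$is_family <- g$family %in% "NBS"
    simed <- builtin_similarity(sim$species[[sp]]$proteins, genes = g)
    detect_tandem_arrays(g, simed)
  })
  names(arrays_by_sp) <- c("ancestor", "lineage_a", "lineage_b")

  # recall 1: every planted truth array sits inside one detected array
  for (sp in names(arrays_by_sp)) {
    truth <- sim$truth$tandem_arrays
    truth <- truth[truth$lineage == sp |
                     (sp == "ancestor" & truth$lineage == "ancestor"), ]
    det <- arrays_by_sp[[sp]]
    membership <- setNames(det$array_id, det$gene_id)
    for (aid in unique(truth$array_id)) {
      members <- truth$gene_id[truth$array_id == aid]
      det_ids <- membership[members]
      expect_false(anyNA(det_ids), info = paste(sp, aid))
      expect_equal(dplyr::n_distinct(det_ids), 1, info = paste(sp, aid))
    }
  }

  # epoch labels from the truth ortholog map
  for (ln in c("lineage_a", "lineage_b")) {
    map <- sim$truth$copy_map
    map <- map[map$lineage == ln, c("gene_id", "ancestor_gene")]
    names(map)[2] <- "counterpart"
    ep <- classify_epoch(arrays_by_sp[[ln]], arrays_by_sp$ancestor, map)
    det <- arrays_by_sp[[ln]]
    truth <- sim$truth$tandem_arrays
    truth <- truth[truth$lineage == ln, ]
    for (aid in unique(truth$array_id)) {
      members <- truth$gene_id[truth$array_id == aid]
      det_id <- unique(det$array_id[det$gene_id %in% members])
      got <- ep$epoch[ep$array_id == det_id]
      want <- unique(truth$epoch[truth$array_id == aid])
      expect_equal(got, want, info = paste(ln, aid))
    }
    # with no ortholog map all arrays are unassigned
    ep0 <- classify_epoch(arrays_by_sp[[ln]])
    expect_true(all(ep0$epoch == "unassigned"))
  }
})

test_that("tandem and cluster summaries reproduce the published percentages", {
  tand <- summarize_tandem(load_tandem_statistics())
  pct <- setNames(tand$tandem_pct, tand$species)
  expect_equal(unname(pct["A.thaliana"]), 55.7)
  expect_equal(unname(pct["B.rapa"]), 47.1)
  expect_equal(unname(pct["B.oleracea"]), 43.3)
  ss <- setNames(tand$species_specific_genes, tand$species)
  expect_equal(unname(ss["B.oleracea"]), 50)
  expect_equal(unname(ss["B.rapa"]), 83)

  cl <- summarize_clusters(load_cluster_statistics())
  pc <- setNames(cl$cluster_pct, cl$species)
  expect_equal(unname(pc["B.oleracea"]), 60.3)
  expect_equal(unname(pc["A.thaliana"]), 61.7)
  expect_equal(unname(pc["B.rapa"]), 59.4)
})
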