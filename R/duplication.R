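# Physical gene clusters (8-ORF rule), cluster homogeneity, tandem array
# detection (similarity + at most one intervening gene), and duplication
# epoch classification via a cross-species ortholog map.

#' Call physical gene clusters by the 8-ORF rule
#'
#' A cluster is a maximal chain of two or more family genes on one chromosome
#' in which each adjacent pair is separated by at most `window` intervening
#' ORFs (any genes, family or not). Genes carry consecutive 0-based ranks per
#' chromosome; an intervening count is therefore `rank difference - 1`.
#'
#' @param genes Gene-model tibble with `gene_id`, `chromosome`, `rank` and a
#'   logical `is_family` column flagging NBS-encoding genes.
#' @param window Maximum intervening ORFs between adjacent cluster members
#'   (default 8).
#' @return Tibble: `cluster_id`, `chromosome`, `gene_id`, `rank`, one row per
#'   member, empty when no cluster exists.
#' @export
call_clusters <- function(genes, window = 8L) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "chromosome", "rank", "is_family") %in%
                  names(genes)))
  dup <- genes %>% count(.data$chromosome, .data$rank) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate rank(s) on chromosome %s.", dup$chromosome[1]),
          class = "nbsfam_input_error")
  }
  fam <- genes %>% filter(.data$is_family) %>%
    arrange(.data$chromosome, .data$rank)
  if (nrow(fam) == 0) {
    return(tibble(cluster_id = character(), chromosome = character(),
                  gene_id = character(), rank = integer()))
  }
  out <- fam %>%
    group_by(.data$chromosome) %>%
    mutate(new_chain = c(TRUE, diff(.data$rank) - 1L > window),
           chain = cumsum(.data$new_chain)) %>%
    group_by(.data$chromosome, .data$chain) %>%
    filter(n() >= 2) %>%
    ungroup()
  if (nrow(out) == 0) {
    return(tibble(cluster_id = character(), chromosome = character(),
                  gene_id = character(), rank = integer()))
  }
  key <- paste(out$chromosome, out$chain)
  out %>%
    mutate(cluster_id = sprintf("cl%03d", match(key, unique(key)))) %>%
    select("cluster_id", "chromosome", "gene_id", "rank")
}

#' Label cluster homogeneity
#'
#' A cluster is homogeneous when all member genes share one category
#' (typically tandem duplicates of a single ancestor gene), heterogeneous
#' when member categories differ.
#'
#' @param clusters [call_clusters()] output.
#' @param classification Tibble with `gene_id` and `category`.
#' @return Tibble: `cluster_id`, `chromosome`, `n_members`, `homogeneity`.
#' @export
label_homogeneity <- function(clusters, classification) {
  clusters <- as_tibble(clusters)
  if (nrow(clusters) == 0) {
    return(tibble(cluster_id = character(), chromosome = character(),
                  n_members = integer(), homogeneity = character()))
  }
  clusters %>%
    left_join(as_tibble(classification)[, c("gene_id", "category")],
              by = "gene_id") %>%
    group_by(.data$cluster_id, .data$chromosome) %>%
    summarise(n_members = n(),
              homogeneity = if (n_distinct(.data$category) == 1)
                "homogeneous" else "heterogeneous",
              .groups = "drop")
}

#' Detect tandem duplicated arrays
#'
#' An array is a maximal run of mutually similar family genes on one
#' chromosome or scaffold in which consecutive members are separated by at
#' most `max_intervening` non-member genes (one unrelated gene allowed within
#' a tandem array, applied per adjacent pair), and every member is linked by
#' the similarity graph to at least one earlier member of the same array.
#'
#' @param genes Gene-model tibble (`gene_id`, `chromosome`, `rank`,
#'   `is_family`).
#' @param similarity_edges Tibble of symmetric similarity pairs (`gene_a`,
#'   `gene_b`), e.g. protein pairs passing the E-value cutoff of an external
#'   all-vs-all search (see [read_similarity_table()]) or the built-in
#'   alignment similarity ([builtin_similarity()]).
#' @param max_intervening Maximum unrelated genes between consecutive
#'   members (default 1).
#' @return Tibble: `array_id`, `chromosome`, `gene_id`, `rank`.
#' @export
detect_tandem_arrays <- function(genes, similarity_edges,
                                 max_intervening = 1L) {
  genes <- as_tibble(genes)
  edges <- as_tibble(similarity_edges)
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), genes$gene_id)
    if (length(unknown) > 0) {
      abort(sprintf("similarity edges reference unknown gene(s): %s",
                    paste(head(unknown, 3), collapse = ", ")),
            class = "nbsfam_input_error")
    }
  }
  ekey <- unique(c(paste(edges$gene_a, edges$gene_b),
                   paste(edges$gene_b, edges$gene_a)))
  similar <- function(a, b) paste(a, b) %in% ekey
  fam <- genes %>% filter(.data$is_family) %>%
    arrange(.data$chromosome, .data$rank)
  arrays <- list()
  for (chr in unique(fam$chromosome)) {
    g <- fam %>% filter(.data$chromosome == chr)
    current <- integer(0)
    flush <- function() {
      if (length(current) >= 2) {
        arrays[[length(arrays) + 1L]] <<- g[current, c("gene_id", "rank")] %>%
          mutate(chromosome = chr)
      }
    }
    for (i in seq_len(nrow(g))) {
      if (length(current) == 0) { current <- i; next }
      last <- current[length(current)]
      gap_ok <- (g$rank[i] - g$rank[last] - 1L) <= max_intervening
      sim_ok <- any(similar(g$gene_id[i], g$gene_id[current]))
      if (gap_ok && sim_ok) current <- c(current, i)
      else { flush(); current <- i }
    }
    flush()
  }
  if (length(arrays) == 0) {
    return(tibble(array_id = character(), chromosome = character(),
                  gene_id = character(), rank = integer()))
  }
  bind_rows(lapply(seq_along(arrays), function(i) {
    arrays[[i]] %>% mutate(array_id = sprintf("ta%03d", i))
  })) %>% select("array_id", "chromosome", "gene_id", "rank")
}

#' Classify tandem arrays by duplication epoch
#'
#' An array is `pre_split` when at least two of its members map through the
#' ortholog table to genes that are members of a single array in the
#' outgroup genome (its counterpart array predates the species split);
#' otherwise it is `species_specific`. With no ortholog map every array is
#' `unassigned`.
#'
#' @param arrays [detect_tandem_arrays()] output for the focal species.
#' @param outgroup_arrays The same for the outgroup species.
#' @param ortholog_map Tibble with `gene_id` (focal) and `counterpart`
#'   (outgroup), or `NULL`.
#' @return Tibble: `array_id`, `epoch`, `n_members`.
#' @export
classify_epoch <- function(arrays, outgroup_arrays = NULL,
                           ortholog_map = NULL) {
  arrays <- as_tibble(arrays)
  if (nrow(arrays) == 0) {
    return(tibble(array_id = character(), epoch = character(),
                  n_members = integer()))
  }
  sizes <- arrays %>% count(.data$array_id, name = "n_members")
  if (is.null(ortholog_map) || is.null(outgroup_arrays)) {
    return(sizes %>% mutate(epoch = "unassigned") %>%
             select("array_id", "epoch", "n_members"))
  }
  out_membership <- as_tibble(outgroup_arrays) %>%
    select(counterpart = "gene_id", out_array = "array_id")
  mapped <- arrays %>%
    inner_join(as_tibble(ortholog_map), by = "gene_id",
               relationship = "many-to-many") %>%
    inner_join(out_membership, by = "counterpart",
               relationship = "many-to-many") %>%
    distinct(.data$array_id, .data$gene_id, .data$out_array) %>%
    count(.data$array_id, .data$out_array, name = "n_shared") %>%
    group_by(.data$array_id) %>%
    summarise(pre_split = any(.data$n_shared >= 2), .groups = "drop")
  sizes %>%
    left_join(mapped, by = "array_id") %>%
    mutate(epoch = ifelse(!is.na(.data$pre_split) & .data$pre_split,
                          "pre_split", "species_specific")) %>%
    select("array_id", "epoch", "n_members")
}

#' Built-in protein similarity for tandem detection
#'
#' Global pairwise alignment over the supplied candidate pairs; a pair is
#' similar when its percent identity reaches `min_identity`. Serves as the
#' alignment-score proxy for an external-search E-value cutoff when no
#' imported similarity table is available.
#'
#' @param proteins Protein sequences.
#' @param candidate_pairs Tibble `gene_a`, `gene_b` of pairs to test; when
#'   `NULL`, all within-chromosome family pairs within `max_rank_gap` ranks
#'   are tested (requires `genes`).
#' @param genes Gene-model tibble, needed when `candidate_pairs` is `NULL`.
#' @param min_identity Minimum percent identity in `[0, 100]` (default 60).
#' @param max_rank_gap Candidate window in ranks (default 2 = adjacency with
#'   one intervening gene).
#' @return Tibble of similar pairs: `gene_a`, `gene_b`, `identity`.
#' @export
builtin_similarity <- function(proteins, candidate_pairs = NULL, genes = NULL,
                               min_identity = 50, max_rank_gap = 2L) {
  prot <- as_seq_tbl(proteins)
  seqs <- setNames(prot$sequence, prot$protein_id)
  if (is.null(candidate_pairs)) {
    stopifnot(!is.null(genes))
    fam <- as_tibble(genes) %>% filter(.data$is_family) %>%
      arrange(.data$chromosome, .data$rank)
    candidate_pairs <- fam %>%
      group_by(.data$chromosome) %>%
      group_modify(function(g, ...) {
        if (nrow(g) < 2) {
          return(tibble(gene_a = character(), gene_b = character()))
        }
        idx <- which(outer(g$rank, g$rank, function(a, b) {
          d <- b - a; d > 0 & d <= max_rank_gap + 1L
        }), arr.ind = TRUE)
        tibble(gene_a = g$gene_id[idx[, 1]], gene_b = g$gene_id[idx[, 2]])
      }) %>% ungroup() %>% select("gene_a", "gene_b")
  }
  candidate_pairs <- as_tibble(candidate_pairs)
  if (nrow(candidate_pairs) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  identity = numeric()))
  }
  pid <- purrr::map_dbl(seq_len(nrow(candidate_pairs)), function(i) {
    a <- seqs[[candidate_pairs$gene_a[i]]]
    b <- seqs[[candidate_pairs$gene_b[i]]]
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(al, type = "PID1")
  })
  candidate_pairs %>%
    mutate(identity = pid) %>%
    filter(.data$identity >= min_identity)
}

#' Read a 12-column tabular pairwise-alignment similarity table
#'
#' Standard tabular layout: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' E-value, bit score. Pairs passing `evalue_max` are returned as symmetric
#' similarity edges; self-hits are dropped.
#'
#' @param path File path (tab-separated, no header).
#' @param evalue_max E-value cutoff (default 1e-20).
#' @return Tibble: `gene_a`, `gene_b`, `identity`, `evalue`, `bitscore`.
#' @export
read_similarity_table <- function(path, evalue_max = 1e-20) {
  x <- readr::read_tsv(path, col_names = c(
    "gene_a", "gene_b", "identity", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"),
    show_col_types = FALSE, comment = "#")
  x %>%
    filter(.data$gene_a != .data$gene_b, .data$evalue <= evalue_max) %>%
    select("gene_a", "gene_b", "identity", "evalue", "bitscore")
}

#' Tandem duplication summary
#'
#' Census-style tandem statistics: per species, the tandem gene count as a
#' percentage of the family total, array counts, and pre-split (common)
#' tandem gene counts.
#'
#' @param stats Tibble with columns `species`, `total_nbs`, `tandem_genes`
#'   and optionally `tandem_arrays`, `common_tandem_genes`,
#'   `common_tandem_arrays`, `on_chromosomes`, `unanchored`.
#' @return The input with `tandem_pct` (= 100 * tandem_genes / total_nbs,
#'   one decimal) and `species_specific_genes` added.
#' @export
summarize_tandem <- function(stats) {
  stats <- as_tibble(stats)
  stopifnot(all(c("species", "total_nbs", "tandem_genes") %in% names(stats)))
  out <- stats %>%
    mutate(tandem_pct = round(100 * .data$tandem_genes / .data$total_nbs, 1))
  if ("common_tandem_genes" %in% names(out)) {
    out <- out %>%
      mutate(species_specific_genes =
               .data$tandem_genes - .data$common_tandem_genes)
  }
  out
}

#' Cluster summary
#'
#' Percentage of chromosome-anchored family genes located in clusters.
#'
#' @param stats Tibble with `species`, `genes_on_chromosomes`,
#'   `genes_in_clusters` and optionally `clusters`.
#' @return The input with `cluster_pct` (one decimal) added.
#' @export
summarize_clusters <- function(stats) {
  as_tibble(stats) %>%
    mutate(cluster_pct = round(100 * .data$genes_in_clusters /
                                 .data$genes_on_chromosomes, 1))
}
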