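# Collinearity: anchor finding, monotone chain DP over rank-sorted anchors,
# NBS ortholog pair extraction, and post-triplication retention accounting.

#' Find anchors between two genomes
#'
#' Anchors are homolog pairs passing the similarity threshold, annotated with
#' each gene's chromosome and rank. A gene may appear in several anchors.
#'
#' @param similarity Tibble of homolog pairs `gene_a`, `gene_b` with an
#'   `evalue` column (imported 12-column table via
#'   [read_similarity_table()]) or an `identity` column (built-in search via
#'   [find_homolog_pairs()]).
#' @param genes_a,genes_b Gene-model tibbles (`gene_id`, `chromosome`,
#'   `rank`) for the two genomes.
#' @param evalue_max E-value cutoff applied when an `evalue` column is
#'   present (default 1e-20).
#' @return Anchor tibble: `gene_a`, `gene_b`, `chr_a`, `rank_a`, `chr_b`,
#'   `rank_b`.
#' @export
find_anchors <- function(similarity, genes_a, genes_b, evalue_max = 1e-20) {
  sim <- as_tibble(similarity)
  if (nrow(sim) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  chr_a = character(), rank_a = integer(),
                  chr_b = character(), rank_b = integer()))
  }
  if ("evalue" %in% names(sim)) sim <- sim %>% filter(.data$evalue <= evalue_max)
  ga <- as_tibble(genes_a)
  gb <- as_tibble(genes_b)
  unknown <- c(setdiff(sim$gene_a, ga$gene_id), setdiff(sim$gene_b, gb$gene_id))
  if (length(unknown) > 0) {
    abort(sprintf("similarity references unknown gene(s): %s",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "nbsfam_input_error")
  }
  sim %>%
    inner_join(ga %>% select(gene_a = "gene_id", chr_a = "chromosome",
                             rank_a = "rank"), by = "gene_a") %>%
    inner_join(gb %>% select(gene_b = "gene_id", chr_b = "chromosome",
                             rank_b = "rank"), by = "gene_b") %>%
    select("gene_a", "gene_b", "chr_a", "rank_a", "chr_b", "rank_b") %>%
    arrange(.data$chr_a, .data$rank_a, .data$chr_b, .data$rank_b)
}

#' Built-in cross-genome homolog search
#'
#' Candidate pairs share at least `min_shared_kmers` amino-acid k-mers
#' (inverted-index prefilter); candidates are confirmed by global alignment
#' percent identity. Stands in for an external all-vs-all protein search.
#'
#' @param proteins_a,proteins_b Protein sequence sets.
#' @param k K-mer width (default 6).
#' @param min_shared_kmers Prefilter threshold (default 15).
#' @param min_identity Percent-identity threshold (default 50).
#' @return Tibble: `gene_a`, `gene_b`, `identity`.
#' @export
find_homolog_pairs <- function(proteins_a, proteins_b, k = 6L,
                               min_shared_kmers = 15L, min_identity = 50) {
  pa <- as_seq_tbl(proteins_a)
  pb <- as_seq_tbl(proteins_b)
  kmerize <- function(tb) {
    purrr::map2(tb$sequence, tb$protein_id, function(s, id) {
      n <- nchar(s)
      if (n < k) return(NULL)
      tibble(kmer = unique(substring(s, 1:(n - k + 1L), k:n)), id = id)
    }) %>% bind_rows()
  }
  ka <- kmerize(pa); kb <- kmerize(pb)
  if (nrow(ka) == 0 || nrow(kb) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  identity = numeric()))
  }
  cand <- inner_join(ka, kb, by = "kmer", relationship = "many-to-many") %>%
    count(gene_a = .data$id.x, gene_b = .data$id.y, name = "shared") %>%
    filter(.data$shared >= min_shared_kmers)
  if (nrow(cand) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  identity = numeric()))
  }
  sa <- setNames(pa$sequence, pa$protein_id)
  sb <- setNames(pb$sequence, pb$protein_id)
  cand$identity <- purrr::map_dbl(seq_len(nrow(cand)), function(i) {
    al <- Biostrings::pairwiseAlignment(sa[[cand$gene_a[i]]],
                                        sb[[cand$gene_b[i]]],
                                        type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(al, type = "PID1")
  })
  cand %>% filter(.data$identity >= min_identity) %>%
    select("gene_a", "gene_b", "identity")
}

# Score and extract the best monotone chain among anchors of one chromosome
# pair and orientation. DP over rank_a-sorted anchors; each anchor scores
# `anchor_score`, each skipped rank costs `gap_penalty`, consecutive gaps
# above `max_gap` break the chain.
chain_dp <- function(anc, orientation, anchor_score, gap_penalty, max_gap) {
  ord <- order(anc$rank_a, if (orientation == "same") anc$rank_b
               else -anc$rank_b)
  a <- anc[ord, , drop = FALSE]
  n <- nrow(a)
  score <- rep(anchor_score, n)
  parent <- rep(NA_integer_, n)
  span <- integer(n)  # for tie-breaking: total rank span so far
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- a$rank_a[j] - a$rank_a[i]
      db <- if (orientation == "same") a$rank_b[j] - a$rank_b[i]
            else a$rank_b[i] - a$rank_b[j]
      if (da <= 0 || db <= 0 || da > max_gap + 1L || db > max_gap + 1L) next
      cand <- score[i] + anchor_score - gap_penalty * ((da - 1L) + (db - 1L))
      cand_span <- span[i] + da + db
      if (cand > score[j] ||
          (cand == score[j] && (is.na(parent[j]) ||
                                cand_span < span[j]))) {
        score[j] <- cand
        parent[j] <- i
        span[j] <- cand_span
      }
    }
  }
  best <- which(score == max(score))
  best <- best[order(span[best], a$rank_a[best])][1]
  chain <- integer(0)
  jj <- best
  while (!is.na(jj)) { chain <- c(jj, chain); jj <- parent[jj] }
  list(idx = ord[chain], score = score[best], span = span[best])
}

#' Chain anchors into collinear synteny blocks
#'
#' Dynamic programming over rank-sorted anchors per chromosome pair and
#' orientation: maximal-score monotone chains with a unit penalty per
#' skipped rank and a consecutive-gap cutoff. Chains are extracted greedily
#' best-first; an anchor joins at most one block, and blocks shorter than
#' `min_anchors` are discarded. Ties between equal-score chains prefer the
#' smaller total rank span, then the lexicographically first anchor.
#'
#' @param anchors [find_anchors()] output.
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_gap Maximum consecutive skipped ranks within a block
#'   (default 25).
#' @param anchor_score Score per chained anchor (default 10).
#' @param gap_penalty Penalty per skipped rank (default 1).
#' @return Tibble: `block_id`, `chr_a`, `chr_b`, `orientation`, `gene_a`,
#'   `gene_b`, `rank_a`, `rank_b`, one row per chained anchor.
#' @export
chain_blocks <- function(anchors, min_anchors = 5L, max_gap = 25L,
                         anchor_score = 10, gap_penalty = 1) {
  anchors <- as_tibble(anchors)
  empty <- tibble(block_id = character(), chr_a = character(),
                  chr_b = character(), orientation = character(),
                  gene_a = character(), gene_b = character(),
                  rank_a = integer(), rank_b = integer())
  if (nrow(anchors) == 0) return(empty)
  blocks <- list()
  for (key in unique(paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    pool <- anchors %>% filter(.data$chr_a == parts[1],
                               .data$chr_b == parts[2])
    repeat {
      if (nrow(pool) < min_anchors) break
      cands <- lapply(c("same", "inverted"), function(o)
        c(chain_dp(pool, o, anchor_score, gap_penalty, max_gap),
          orientation = o))
      sc <- vapply(cands, function(x) x$score, numeric(1))
      sp <- vapply(cands, function(x) x$span, numeric(1))
      pick <- cands[[order(-sc, sp)[1]]]
      if (length(pick$idx) < min_anchors) break
      blocks[[length(blocks) + 1L]] <- pool[pick$idx, , drop = FALSE] %>%
        mutate(orientation = pick$orientation, score = pick$score)
      pool <- pool[-pick$idx, , drop = FALSE]
    }
  }
  if (length(blocks) == 0) return(empty)
  # a counterpart gene in several blocks keeps only its best-scoring block
  blk <- bind_rows(lapply(seq_along(blocks), function(i)
    blocks[[i]] %>% mutate(block_id = sprintf("blk%03d", i))))
  gene_best <- blk %>%
    group_by(.data$gene_b) %>%
    slice_max(.data$score, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("gene_b", keep_block = "block_id")
  blk %>%
    inner_join(gene_best, by = "gene_b") %>%
    filter(.data$block_id == .data$keep_block) %>%
    group_by(.data$block_id) %>% filter(n() >= min_anchors) %>% ungroup() %>%
    select("block_id", "chr_a", "chr_b", "orientation", "gene_a", "gene_b",
           "rank_a", "rank_b") %>%
    arrange(.data$block_id, .data$rank_a)
}

#' Extract NBS ortholog pairs from synteny blocks
#'
#' One pair per chained anchor whose two genes are both NBS-encoding; pairs
#' carry both genes' categories for CNL/TNL stratification.
#'
#' @param blocks [chain_blocks()] output.
#' @param class_a,class_b Classification tibbles (`gene_id`, `category`) for
#'   the two genomes; only categories in the NBS-encoding set count.
#' @return Tibble: `ref_gene`, `ref_category`, `counterpart`,
#'   `counterpart_category`, `block_id`.
#' @export
extract_ortholog_pairs <- function(blocks, class_a, class_b) {
  blocks <- as_tibble(blocks)
  empty <- tibble(ref_gene = character(), ref_category = character(),
                  counterpart = character(),
                  counterpart_category = character(), block_id = character())
  if (nrow(blocks) == 0) return(empty)
  ca <- as_tibble(class_a) %>% filter(.data$category %in% NBS_CATEGORIES)
  cb <- as_tibble(class_b) %>% filter(.data$category %in% NBS_CATEGORIES)
  blocks %>%
    inner_join(ca %>% select(gene_a = "gene_id", ref_category = "category"),
               by = "gene_a") %>%
    inner_join(cb %>% select(gene_b = "gene_id",
                             counterpart_category = "category"),
               by = "gene_b") %>%
    select(ref_gene = "gene_a", "ref_category", counterpart = "gene_b",
           "counterpart_category", "block_id")
}

#' Retention accounting over ortholog pairs
#'
#' Groups pairs by reference gene and tabulates how many descendant copies
#' each reference gene retained after the whole-genome triplication.
#'
#' @param pairs Tibble with `ref_gene` and `counterpart` columns.
#' @return Object of class `retention_accounting`: list with `records`
#'   (tibble: `ref_gene`, `copies`, `counterparts`) and `histogram` (tibble:
#'   `copies`, `n_ref_genes`). Reference genes with more than 3 counterparts
#'   are flagged with a warning but still counted.
#' @export
retention_accounting <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    res <- list(records = tibble(ref_gene = character(), copies = integer(),
                                 counterparts = character()),
                histogram = tibble(copies = integer(), n_ref_genes = integer()),
                n_pairs = 0L)
    class(res) <- "retention_accounting"
    return(res)
  }
  records <- pairs %>%
    distinct(.data$ref_gene, .data$counterpart) %>%
    group_by(.data$ref_gene) %>%
    summarise(copies = n(),
              counterparts = paste(.data$counterpart, collapse = ","),
              .groups = "drop")
  if (any(records$copies > 3)) {
    warn(sprintf("over-retention: %d reference gene(s) with > 3 counterparts.",
                 sum(records$copies > 3)))
  }
  hist <- records %>% count(.data$copies, name = "n_ref_genes")
  # conservation checks: sum(copies x count) = pairs, sum(count) = ref genes
  stopifnot(sum(hist$copies * hist$n_ref_genes) ==
              nrow(distinct(pairs, .data$ref_gene, .data$counterpart)),
            sum(hist$n_ref_genes) == n_distinct(pairs$ref_gene))
  res <- list(records = records, histogram = hist,
              n_pairs = nrow(distinct(pairs, .data$ref_gene,
                                      .data$counterpart)))
  class(res) <- "retention_accounting"
  res
}

#' @export
print.retention_accounting <- function(x, ...) {
  cat(sprintf("<retention_accounting> %d pairs, %d reference genes\n",
              x$n_pairs, sum(x$histogram$n_ref_genes)))
  print(x$histogram)
  invisible(x)
}

#' @export
tidy.retention_accounting <- function(x, ...) x$records

#' @export
glance.retention_accounting <- function(x, ...) {
  h <- setNames(x$histogram$n_ref_genes, x$histogram$copies)
  tibble(n_pairs = x$n_pairs, n_ref_genes = sum(x$histogram$n_ref_genes),
         one_copy = sum(h[names(h) == "1"], 0),
         two_copies = sum(h[names(h) == "2"], 0),
         three_copies = sum(h[names(h) == "3"], 0))
}

#' Compare retention across two genome comparisons
#'
#' For two retention accountings sharing the reference genome, reports the
#' overlap and union of reference gene sets and the retained-gene fraction of
#' each counterpart genome.
#'
#' @param rec_a,rec_b [retention_accounting()] results.
#' @param total_a,total_b Total NBS gene counts of the two counterpart
#'   genomes (denominators for the retained percentages).
#' @param total_ref Total NBS gene count of the reference genome (optional).
#' @return Tibble with `overlap`, `union`, `retained_a`, `retained_pct_a`,
#'   `retained_b`, `retained_pct_b` and, when `total_ref` is given,
#'   `union_pct_ref`.
#' @export
cross_comparison_sets <- function(rec_a, rec_b, total_a = NA, total_b = NA,
                                  total_ref = NA) {
  stopifnot(inherits(rec_a, "retention_accounting"),
            inherits(rec_b, "retention_accounting"))
  set_a <- rec_a$records$ref_gene
  set_b <- rec_b$records$ref_gene
  ret_a <- length(unique(unlist(strsplit(rec_a$records$counterparts, ","))))
  ret_b <- length(unique(unlist(strsplit(rec_b$records$counterparts, ","))))
  out <- tibble(
    overlap = length(intersect(set_a, set_b)),
    union = length(union(set_a, set_b)),
    retained_a = ret_a,
    retained_pct_a = round(100 * ret_a / total_a, 2),
    retained_b = ret_b,
    retained_pct_b = round(100 * ret_b / total_b, 2))
  if (!is.na(total_ref)) {
    out$union_pct_ref <- round(100 * out$union / total_ref, 2)
  }
  out
}
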