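# Expression analysis: log2 transform of FPKM matrices, Cluster-3.0-style
# hierarchical clustering (uncentered correlation, average linkage), and
# ortholog/paralog expression-divergence scoring.

expr_matrix <- function(mat) {
  mat <- as_tibble(mat)
  stopifnot("gene_id" %in% names(mat))
  vals <- as.matrix(mat[, setdiff(names(mat), "gene_id"), drop = FALSE])
  rownames(vals) <- mat$gene_id
  storage.mode(vals) <- "double"
  vals
}

#' Log2-transform an FPKM matrix
#'
#' `value <- log2(value + pseudocount)`; the pseudocount (default 1) keeps
#' zero FPKM finite and maps it to 0.
#'
#' @param mat Tibble with `gene_id` plus numeric tissue columns.
#' @param pseudocount Added before the log (default 1).
#' @return Tibble of the same shape, transformed.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  vals <- expr_matrix(mat)
  if (any(vals < 0, na.rm = TRUE)) {
    abort("negative FPKM values: matrix appears already transformed.",
          class = "nbsfam_input_error")
  }
  out <- log2(vals + pseudocount)
  bind_cols(tibble(gene_id = as_tibble(mat)$gene_id), as_tibble(out))
}

# Uncentered correlation (Cluster 3.0's default similarity): cosine of the
# un-centred profiles.
uncentered_cor <- function(m) {
  norms <- sqrt(rowSums(m^2))
  sim <- (m %*% t(m)) / outer(norms, norms)
  sim[!is.finite(sim)] <- 0
  sim
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with uncentered-correlation similarity and
#' average linkage (the defaults of the classic expression-clustering tool
#' this mirrors). Genes with zero-norm (all-zero) profiles are excluded with
#' a warning since their similarity is undefined.
#'
#' @param mat Transformed expression tibble (`gene_id` + tissue columns),
#'   at least 2 genes.
#' @param linkage Agglomeration method (default `"average"`).
#' @return Object of class `expr_clust`: list with `tree` (an
#'   [stats::hclust]), `order` (leaf-ordered gene ids) and `matrix` (the
#'   clustered values, leaf order).
#' @export
hier_cluster <- function(mat, linkage = "average") {
  vals <- expr_matrix(mat)
  keep <- sqrt(rowSums(vals^2)) > 0
  if (any(!keep)) {
    warn(sprintf("%d constant zero profile(s) excluded from clustering.",
                 sum(!keep)))
    vals <- vals[keep, , drop = FALSE]
  }
  if (nrow(vals) < 1) {
    abort("no usable profiles to cluster.", class = "nbsfam_input_error")
  }
  if (nrow(vals) == 1) {
    res <- list(tree = NULL, order = rownames(vals), matrix = vals)
    class(res) <- "expr_clust"
    return(res)
  }
  d <- as.dist(1 - uncentered_cor(vals))
  tree <- hclust(d, method = linkage)
  res <- list(tree = tree, order = rownames(vals)[tree$order],
              matrix = vals[tree$order, , drop = FALSE])
  class(res) <- "expr_clust"
  res
}

#' @export
print.expr_clust <- function(x, ...) {
  cat(sprintf("<expr_clust> %d gene(s), %d tissue(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
tidy.expr_clust <- function(x, ...) {
  as_tibble(x$matrix, rownames = "gene_id") %>%
    mutate(leaf_order = dplyr::row_number(), .after = "gene_id")
}

#' Heatmap of a clustered expression matrix
#'
#' Tile heatmap in leaf order; the colour scale clamps at +/-2 on the log2
#' scale (values beyond saturate), mirroring standard expression heat maps.
#'
#' @param object An [hier_cluster()] result.
#' @param ... Unused.
#' @export
autoplot.expr_clust <- function(object, ...) {
  df <- as_tibble(object$matrix, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "tissue",
                        values_to = "value") %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(object$order)),
           tissue = factor(.data$tissue, levels = colnames(object$matrix)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$gene_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black",
                                  high = "red", midpoint = 0,
                                  limits = c(-2, 2), oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(-2, 2)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Export a clustered heatmap table
#'
#' Writes the leaf-ordered transformed matrix exactly as clustered (no
#' re-scaling), plus the tree in Newick when available.
#'
#' @param clust An [hier_cluster()] result.
#' @param path Output TSV path; the Newick tree goes to
#'   `sub("\\\\.tsv$", ".nwk", path)`.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(clust, path) {
  readr::write_tsv(as_tibble(clust$matrix, rownames = "gene_id"), path)
  if (!is.null(clust$tree)) {
    readr::write_lines(hclust_to_newick(clust$tree),
                       sub("\\.tsv$", ".nwk", path))
  }
  invisible(path)
}

hclust_to_newick <- function(tree) {
  lab <- tree$labels
  rec <- function(i) {
    m <- tree$merge[i, ]
    part <- vapply(m, function(x) {
      if (x < 0) lab[-x] else rec(x)
    }, character(1))
    sprintf("(%s,%s)", part[1], part[2])
  }
  paste0(rec(nrow(tree$merge)), ";")
}

#' Expression divergence of gene pairs
#'
#' Per pair, `1 - Pearson correlation` of the transformed profiles (range
#' `[0, 2]`); pairs with a zero-variance profile are flagged undefined; the
#' score is symmetric in the two genes. The group summary reports the mean
#' score per relation and a one-sided Mann-Whitney comparison of paralog
#' versus ortholog scores.
#'
#' @param mat Transformed expression tibble (`gene_id` + tissues).
#' @param pairs Tibble with `gene_a`, `gene_b`, `relation`.
#' @return Object of class `pair_divergence`: list with `scores` (tibble:
#'   `gene_a`, `gene_b`, `relation`, `score`, `defined`) and `summary`
#'   (mean per relation); when both relations are present, also `comparison`
#'   (a [compare_lineages()] result, alternative `"greater"` for paralogs).
#' @export
pair_divergence <- function(mat, pairs) {
  vals <- expr_matrix(mat)
  pairs <- as_tibble(pairs)
  missing <- !(pairs$gene_a %in% rownames(vals)) |
    !(pairs$gene_b %in% rownames(vals))
  if (any(missing)) {
    warn(sprintf("%d pair(s) skipped: gene absent from matrix.",
                 sum(missing)))
    pairs <- pairs[!missing, , drop = FALSE]
  }
  scores <- pairs %>%
    mutate(score = purrr::map2_dbl(.data$gene_a, .data$gene_b, function(a, b) {
      x <- vals[a, ]; y <- vals[b, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      1 - cor(x, y)
    }),
    defined = !is.na(.data$score))
  summary <- scores %>%
    filter(.data$defined) %>%
    group_by(.data$relation) %>%
    summarise(n = n(), mean_score = mean(.data$score), .groups = "drop")
  res <- list(scores = scores, summary = summary)
  rel <- unique(scores$relation[scores$defined])
  if (all(c("ortholog", "paralog") %in% rel)) {
    cmp_data <- scores %>% filter(.data$defined) %>%
      mutate(relation = factor(.data$relation,
                               levels = c("paralog", "ortholog"))) %>%
      arrange(.data$relation) %>%
      mutate(relation = as.character(.data$relation))
    res$comparison <- compare_lineages(cmp_data, "relation", "score",
                                       alternative = "greater")
  }
  class(res) <- "pair_divergence"
  res
}

#' @export
print.pair_divergence <- function(x, ...) {
  cat(sprintf("<pair_divergence> %d pair(s)\n", nrow(x$scores)))
  print(x$summary)
  if (!is.null(x$comparison)) {
    cat(sprintf("  paralog > ortholog: Mann-Whitney p = %.3g\n",
                x$comparison$p_value))
  }
  invisible(x)
}

#' @export
tidy.pair_divergence <- function(x, ...) x$scores

#' @export
glance.pair_divergence <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "relation",
                             values_from = c("n", "mean_score"))
  if (!is.null(x$comparison)) wide$p_value <- x$comparison$p_value
  wide
}

#' @export
autoplot.pair_divergence <- function(object, ...) {
  df <- object$scores %>% filter(.data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relation, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation") +
    ggplot2::theme_minimal()
}
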