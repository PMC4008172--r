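# Selection analysis: codon-aware pairwise alignment, Nei-Gojobori (1986)
# Ka/Ks with Jukes-Cantor correction, and lineage-stratified Mann-Whitney
# comparison. A reader for externally computed branch-model results lets
# free-ratio estimates slot in downstream.

# ---- NG86 codon machinery -------------------------------------------------

# Per-ordered-codon-pair synonymous/nonsynonymous difference counts averaged
# over all shortest mutational pathways; pathways passing through a stop
# codon are excluded (all pathways are used if every one is blocked).
ng86_pair_counts <- function(c1, c2) {
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else {
    p <- list()
    rec <- function(prefix, rest) {
      if (length(rest) == 0) { p[[length(p) + 1L]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), pos)
    p
  }
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0
    for (pp in order) {
      nxt <- cur
      substr(nxt, pp, pp) <- substr(c2, pp, pp)
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- purrr::compact(lapply(perms, walk))
  if (length(res) == 0) {
    # every pathway passes a stop: fall back to counting through them
    res <- lapply(perms, function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (pp in order) {
        nxt <- cur
        substr(nxt, pp, pp) <- substr(c2, pp, pp)
        if (gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*") sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

# 61 x 61 lookup tables of averaged (sd, nd), built once per session.
ng86_tables <- function() {
  env <- nbsfam_cache()
  if (is.null(env$ng86_sd)) {
    sc <- sense_codons()
    m_sd <- matrix(0, length(sc), length(sc), dimnames = list(sc, sc))
    m_nd <- m_sd
    for (i in seq_along(sc)) {
      for (j in seq_along(sc)) {
        if (i == j) next
        cnt <- ng86_pair_counts(sc[i], sc[j])
        m_sd[i, j] <- cnt["sd"]
        m_nd[i, j] <- cnt["nd"]
      }
    }
    env$ng86_sd <- m_sd
    env$ng86_nd <- m_nd
  }
  list(sd = env$ng86_sd, nd = env$ng86_nd)
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) {
    abort(sprintf("substitution saturation: proportion %.3f >= 0.75, Jukes-Cantor correction undefined.",
                  p), class = "nbsfam_saturation_error")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# ---- Codon-aware alignment ------------------------------------------------

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Aligns the translated proteins globally and back-maps the alignment to
#' codons; gapped columns are retained in the alignment but excluded from
#' Ka/Ks site counting.
#'
#' @param cds_a,cds_b Codon-clean CDS strings (length divisible by 3, no
#'   internal stops).
#' @param id_a,id_b Sequence labels used in error messages.
#' @return Object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (aligned codon vectors, `"---"` for gaps) and the ids.
#' @export
align_codons <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b") {
  cod_a <- check_codon_clean(cds_a, id_a)
  cod_b <- check_codon_clean(cds_b, id_b)
  aa_a <- paste(genetic_code()[cod_a], collapse = "")
  aa_b <- paste(genetic_code()[cod_b], collapse = "")
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(aa_a),
                                      Biostrings::AAString(aa_b),
                                      type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- 0L; ib <- 0L
  out_a <- character(length(pa)); out_b <- character(length(pb))
  for (i in seq_along(pa)) {
    if (pa[i] == "-") out_a[i] <- "---"
    else { ia <- ia + 1L; out_a[i] <- cod_a[ia] }
    if (pb[i] == "-") out_b[i] <- "---"
    else { ib <- ib + 1L; out_b[i] <- cod_b[ib] }
  }
  structure(list(codons_a = out_a, codons_b = out_b,
                 id_a = id_a, id_b = id_b),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s vs %s: %d columns, %d gapped\n",
              x$id_a, x$id_b, length(x$codons_a),
              sum(x$codons_a == "---" | x$codons_b == "---")))
  invisible(x)
}

# ---- NG86 estimator -------------------------------------------------------

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Site counting apportions each codon position by the fraction of its three
#' possible changes that are synonymous; differences are averaged over all
#' shortest mutational pathways between the two codons, excluding pathways
#' through stop codons; proportions are corrected for multiple hits with
#' Jukes-Cantor, `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param alignment An [align_codons()] result, or a list with `codons_a`
#'   and `codons_b` aligned codon vectors.
#' @return One-row tibble: `ka`, `ks`, `ka_ks` (NA when `ks` is 0 or
#'   undefined), `S`, `N` (site counts, `S + N` = 3 x compared codons),
#'   `Sd`, `Nd` (difference counts), `n_codons` (compared codons).
#' @export
compute_kaks_ng86 <- function(alignment) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) {
    abort("no comparable (ungapped) codons in alignment.",
          class = "nbsfam_input_error")
  }
  s_a <- sum(vapply(ca, codon_syn_sites, numeric(1)))
  s_b <- sum(vapply(cb, codon_syn_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  tab <- ng86_tables()
  Sd <- sum(tab$sd[cbind(ca, cb)])
  Nd <- sum(tab$nd[cbind(ca, cb)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  ratio <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  tibble(ka = ka, ks = ks, ka_ks = ratio, S = S, N = N, Sd = Sd, Nd = Nd,
         n_codons = length(ca))
}

#' Ka/Ks for a table of CDS pairs
#'
#' Convenience wrapper: aligns and scores each pair, carrying through any
#' annotation columns (lineage, category).
#'
#' @param pairs Tibble with `gene_a`, `gene_b` plus annotation columns.
#' @param cds Named character vector holding every referenced CDS.
#' @return `pairs` with the [compute_kaks_ng86()] columns appended; pairs
#'   that fail (saturation, missing sequence) are dropped with a warning.
#' @export
compute_kaks_pairs <- function(pairs, cds) {
  pairs <- as_tibble(pairs)
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (!(a %in% names(cds)) || !(b %in% names(cds))) return(NULL)
    tryCatch(
      bind_cols(pairs[i, , drop = FALSE],
                compute_kaks_ng86(align_codons(cds[[a]], cds[[b]], a, b))),
      error = function(e) NULL)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("%d pair(s) dropped (missing sequence or saturation).",
                 dropped))
  }
  bind_rows(res)
}

# ---- Group comparison -----------------------------------------------------

#' Compare Ka/Ks (or any score) between two lineages
#'
#' Two-sided Mann-Whitney U test: exact null distribution when both groups
#' have at most `exact_limit` observations and no ties, normal approximation
#' with tie correction otherwise. Pairs with undefined ratios (`Ks = 0`) are
#' excluded before testing. The relative excess is `(a - b) / a` for group
#' means `a >= b` ordering as given.
#'
#' @param data Tibble with a grouping column and a value column.
#' @param group,value Column names (strings).
#' @param exact_limit Largest per-group size for the exact null (default 8).
#' @param alternative Passed to [stats::wilcox.test()] (default two-sided).
#' @return Object of class `lineage_comparison` with the group summaries,
#'   `U` statistic (first group as x), `p_value` and `relative_excess`.
#' @export
compare_lineages <- function(data, group, value = "ka_ks",
                             exact_limit = 8L,
                             alternative = "two.sided") {
  data <- as_tibble(data)
  stopifnot(group %in% names(data), value %in% names(data))
  data <- data %>% filter(is.finite(.data[[value]]))
  groups <- unique(data[[group]])
  if (length(groups) != 2) {
    abort(sprintf("need exactly 2 groups with finite values, got %d.",
                  length(groups)),
          class = "nbsfam_input_error")
  }
  x <- data[[value]][data[[group]] == groups[1]]
  y <- data[[value]][data[[group]] == groups[2]]
  if (length(x) == 0 || length(y) == 0) {
    abort("comparison refused: a group is empty.",
          class = "nbsfam_input_error")
  }
  use_exact <- length(x) <= exact_limit && length(y) <= exact_limit
  if (length(unique(c(x, y))) == 1) {
    # all observations identical: no evidence against the null
    wt <- list(statistic = length(x) * length(y) / 2, p.value = 1)
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = use_exact,
                  correct = FALSE))
  }
  mean_a <- mean(x); mean_b <- mean(y)
  structure(list(
    groups = as.character(groups),
    n = c(length(x), length(y)),
    means = c(mean_a, mean_b),
    U = unname(wt$statistic),
    p_value = wt$p.value,
    relative_excess = (mean_a - mean_b) / mean_a,
    alternative = alternative,
    data = data %>% select(group = dplyr::all_of(group),
                           value = dplyr::all_of(value))),
    class = "lineage_comparison")
}

#' Relative excess of one mean over another
#'
#' `100 * (a - b) / a`, the percentage by which mean `a` exceeds mean `b`
#' relative to `a`.
#'
#' @param a,b Numeric scalars (e.g. group mean Ka/Ks values).
#' @return Percentage.
#' @export
relative_excess_pct <- function(a, b) 100 * (a - b) / a

#' @export
print.lineage_comparison <- function(x, ...) {
  cat(sprintf("<lineage_comparison> %s (n=%d, mean %.3f) vs %s (n=%d, mean %.3f)\n",
              x$groups[1], x$n[1], x$means[1],
              x$groups[2], x$n[2], x$means[2]))
  cat(sprintf("  Mann-Whitney U = %g, p = %.4g (%s); relative excess %.2f%%\n",
              x$U, x$p_value, x$alternative, 100 * x$relative_excess))
  invisible(x)
}

#' @export
tidy.lineage_comparison <- function(x, ...) {
  tibble(group = x$groups, n = x$n, mean = x$means)
}

#' @export
glance.lineage_comparison <- function(x, ...) {
  tibble(U = x$U, p_value = x$p_value,
         relative_excess_pct = 100 * x$relative_excess,
         method = "Mann-Whitney U")
}

#' @export
autoplot.lineage_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Ka/Ks",
                  subtitle = sprintf("Mann-Whitney p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

# ---- External branch-model results ----------------------------------------

#' Read externally computed branch-model Ka/Ks results
#'
#' Parses the main-result text layout of maximum-likelihood branch models:
#' rows of the form `parent..child  t  N  S  dN/dS  dN  dS` (free-ratio
#' output). The parsed omegas are usable interchangeably with NG86 results
#' downstream.
#'
#' @param path Text file.
#' @return Tibble: `branch`, `t`, `N`, `S`, `omega`, `ka`, `ks`.
#' @export
read_branch_results <- function(path) {
  ln <- readr::read_lines(path)
  is_branch <- grepl("^\\s*\\S+\\.\\.\\S+\\s", ln)
  if (!any(is_branch)) {
    abort(sprintf("no branch rows found in '%s' (expected 'a..b t N S dN/dS dN dS').",
                  path), class = "nbsfam_parse_error")
  }
  rows <- purrr::map(which(is_branch), function(i) {
    f <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    if (length(f) < 7 || anyNA(suppressWarnings(as.numeric(f[2:7])))) {
      abort(sprintf("malformed branch row at line %d of '%s'.", i, path),
            class = "nbsfam_parse_error")
    }
    tibble(branch = f[1], t = as.numeric(f[2]), N = as.numeric(f[3]),
           S = as.numeric(f[4]), omega = as.numeric(f[5]),
           ka = as.numeric(f[6]), ks = as.numeric(f[7]))
  })
  bind_rows(rows)
}
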