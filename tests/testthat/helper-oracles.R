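# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations (enumeration, brute force) kept separate
# from the package's implementations.

# --- NG86 by explicit enumeration ------------------------------------------

oracle_gc <- Biostrings::GENETIC_CODE

oracle_syn_fraction <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (oracle_gc[[alt]] == oracle_gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oracle_pathways <- function(pos) {
  if (length(pos) == 1) return(list(pos))
  out <- list()
  for (i in seq_along(pos)) {
    for (rest in oracle_pathways(pos[-i])) {
      out[[length(out) + 1]] <- c(pos[i], rest)
    }
  }
  out
}

oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  counts <- list()
  for (path in oracle_pathways(pos)) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_gc[[nxt]] == "*") { blocked <- TRUE; break }
      if (oracle_gc[[nxt]] == oracle_gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) counts[[length(counts) + 1]] <- c(sd, nd)
  }
  if (length(counts) == 0) {
    for (path in oracle_pathways(pos)) {
      cur <- c1
      sd <- 0; nd <- 0
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (oracle_gc[[nxt]] != "*" && oracle_gc[[nxt]] == oracle_gc[[cur]])
          sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      counts[[length(counts) + 1]] <- c(sd, nd)
    }
  }
  colMeans(do.call(rbind, counts))
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_fraction, numeric(1))) +
        sum(vapply(codons_b, oracle_syn_fraction, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  d <- rowSums(mapply(oracle_pair_diffs, codons_a, codons_b))
  ps <- d[1] / S
  pn <- d[2] / N
  jc <- function(p) if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], ks = jc(ps), ka = jc(pn))
}

random_sense_codons <- function(n) {
  sc <- names(oracle_gc)[oracle_gc != "*"]
  sample(sc, n, replace = TRUE)
}

# mutate each codon at one random position with probability p, keeping the
# result a sense codon
mutate_codons <- function(codons, p = 0.3) {
  nts <- c("A", "C", "G", "T")
  vapply(codons, function(cod) {
    if (runif(1) > p) return(cod)
    repeat {
      pos <- sample(3, 1)
      alt <- cod
      substr(alt, pos, pos) <- sample(setdiff(nts, substr(cod, pos, pos)), 1)
      if (oracle_gc[[alt]] != "*") return(alt)
    }
  }, character(1), USE.NAMES = FALSE)
}

# --- cluster calling by brute-force connected components --------------------

oracle_clusters <- function(genes, window = 8L) {
  fam <- genes[genes$is_family, , drop = FALSE]
  if (nrow(fam) < 2) return(list())
  out <- list()
  for (chr in unique(fam$chromosome)) {
    g <- fam[fam$chromosome == chr, , drop = FALSE]
    n <- nrow(g)
    adj <- abs(outer(g$rank, g$rank, "-")) - 1 <= window & diag(n) == 0
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      members <- sort(g$gene_id[comp == cc])
      if (length(members) >= 2) out[[length(out) + 1]] <- members
    }
  }
  out[order(vapply(out, `[`, character(1), 1))]
}

# --- maximum monotone chain by exhaustive subset enumeration ----------------

oracle_max_chain_score <- function(anchors, anchor_score = 10,
                                   gap_penalty = 1, max_gap = 25L) {
  n <- nrow(anchors)
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) == 0) next
    sub <- anchors[idx, , drop = FALSE]
    sub <- sub[order(sub$rank_a), , drop = FALSE]
    for (dir in c(1, -1)) {
      da <- diff(sub$rank_a)
      db <- dir * diff(sub$rank_b)
      if (nrow(sub) > 1 &&
          (any(da <= 0) || any(db <= 0) ||
           any(da > max_gap + 1) || any(db > max_gap + 1))) next
      score <- nrow(sub) * anchor_score -
        gap_penalty * (sum(pmax(da - 1, 0)) + sum(pmax(db - 1, 0)))
      if (score > best) best <- score
      if (nrow(sub) == 1) break
    }
  }
  best
}

# --- Mann-Whitney exact p by full enumeration -------------------------------

oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
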