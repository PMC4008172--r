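# Synthetic multi-species genome generator: an ancestral genome with planted
# NBS-family domain architectures and tandem arrays, triplicated into
# descendant lineages with controlled retention/loss, codon-level divergence
# at set dN/dS, and simulated tissue expression.

#' Built-in domain signature set
#'
#' Fixed literal amino-acid signatures planted by the simulator and detected
#' exactly by [scan_domains()]. The CC entry is an ideal four-heptad leucine
#' zipper recognised by the sliding-window scorer rather than by literal
#' matching.
#'
#' @return Named character vector with elements `NBS`, `TIR`, `LRR`, `CC`.
#' @export
domain_signatures <- function() {
  c(NBS = "GMGGVGKTTLAQLVYND",
    TIR = "FLSFRGEDTRKTFVSHL",
    LRR = "LDLSGNKLSGEIPASLG",
    CC  = strrep("LEELKEK", 4))
}

# Spacer residues placed between planted domains. Excludes the strongly
# hydrophobic set so spacers can never satisfy the heptad a/d pattern the
# coiled-coil scorer requires (mimics disordered linker composition).
LINKER_ALPHABET <- setdiff(AA_ALPHABET20, AA_HYDROPHOBIC)

random_aa <- function(n_chars, alphabet = AA_ALPHABET20) {
  paste(sample(alphabet, n_chars, replace = TRUE), collapse = "")
}

# A family protein is linker + domain signature + linker + ... in token order.
build_family_protein <- function(architecture) {
  sig <- domain_signatures()
  tok <- strsplit(architecture, "")[[1]]
  dom <- c(T = "TIR", C = "CC", N = "NBS", L = "LRR")[tok]
  parts <- character(2L * length(dom) + 1L)
  parts[1] <- random_aa(sample(8:20, 1), LINKER_ALPHABET)
  for (i in seq_along(dom)) {
    parts[2L * i] <- sig[[dom[i]]]
    parts[2L * i + 1L] <- random_aa(sample(8:20, 1), LINKER_ALPHABET)
  }
  paste(parts, collapse = "")
}

build_background_protein <- function(len) {
  sig <- domain_signatures()
  repeat {
    p <- random_aa(len)
    if (!any(vapply(sig[c("NBS", "TIR", "LRR")],
                    function(s) grepl(s, p, fixed = TRUE), logical(1)))) {
      return(p)
    }
  }
}

# Reverse-translate a batch of proteins into CDS with uniformly drawn
# synonymous codons (sense codons only, so no internal stops by construction).
reverse_translate <- function(proteins) {
  gc <- genetic_code()
  by_aa <- split(names(gc)[gc != "*"], gc[gc != "*"])
  aa_all <- strsplit(proteins, "")
  lens <- lengths(aa_all)
  flat <- unlist(aa_all, use.names = FALSE)
  cod <- character(length(flat))
  for (a in unique(flat)) {
    idx <- which(flat == a)
    cod[idx] <- sample(by_aa[[a]], length(idx), replace = TRUE)
  }
  out <- vapply(split(cod, rep(seq_along(lens), lens)), paste,
                character(1), collapse = "")
  setNames(unname(out), names(proteins))
}

place_coordinates <- function(n_aa) {
  gaps <- sample(200:2000, length(n_aa), replace = TRUE)
  len_nt <- 3L * n_aa
  start <- cumsum(c(1L, head(len_nt, -1))) + cumsum(gaps) - gaps[1]
  tibble(start = as.integer(start), end = as.integer(start + len_nt - 1L))
}

# Truth-side cluster call: simple independent window loop over ranks.
truth_clusters <- function(genes, window = 8L) {
  fam <- genes %>% filter(.data$family %in% "NBS") %>%
    arrange(.data$chromosome, .data$rank)
  out <- fam %>%
    group_by(.data$chromosome) %>%
    mutate(new_run = c(TRUE, diff(.data$rank) - 1L > window),
           run = cumsum(.data$new_run)) %>%
    group_by(.data$chromosome, .data$run) %>%
    filter(n() >= 2) %>%
    ungroup()
  if (nrow(out) == 0) {
    return(tibble(cluster_id = character(), chromosome = character(),
                  gene_id = character()))
  }
  out %>%
    mutate(cluster_id = paste0("truth_cl", match(
      paste(.data$chromosome, .data$run),
      unique(paste(.data$chromosome, .data$run))))) %>%
    select("cluster_id", "chromosome", "gene_id")
}

#' Generate the ancestral synthetic genome
#'
#' Lays out genes on chromosomes with consecutive ranks, plants NBS-family
#' domain architectures according to the configured mix, plants pre-split
#' tandem arrays (near-identical adjacent copies of one family gene), and
#' reverse-translates every protein into a codon-clean CDS.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `genes` (tibble: `gene_id`, `species`,
#'   `chromosome`, `strand`, `start`, `end`, `rank` (0-based), `family`,
#'   `architecture`), `cds` and `proteins` (named character vectors), and
#'   `truth` (list of `tandem_arrays` and `clusters` tibbles).
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "ancestor", {
    n_chr <- config$n_chromosomes
    n_per <- config$n_genes_per_chromosome
    n <- n_chr * n_per
    genes <- tibble(
      species = "ancestor",
      chromosome = rep(sprintf("chr%02d", seq_len(n_chr)), each = n_per),
      rank = rep(seq_len(n_per) - 1L, times = n_chr),
      gene_id = sprintf("ANC_g%05d", seq_len(n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      family = NA_character_,
      architecture = NA_character_
    )
    is_fam <- runif(n) < config$nbs_fraction
    archs <- names(config$architecture_mix)
    genes$architecture[is_fam] <- sample(archs, sum(is_fam), replace = TRUE,
                                         prob = config$architecture_mix)

    # Plant pre-split tandem arrays: runs of adjacent copies of a fresh family
    # gene, kept >= 3 ranks apart so planted arrays never abut.
    spec <- config$tandem_array_spec
    pre <- spec[spec$epoch == "pre_split", , drop = FALSE]
    arrays <- list()
    taken <- rep(FALSE, n)
    if (nrow(pre) > 0) {
      for (i in seq_len(nrow(pre))) {
        len <- pre$len[i]
        ok <- FALSE
        for (try in 1:200) {
          chr <- sample(n_chr, 1)
          pos <- sample(n_per - len + 1L, 1)
          idx <- (chr - 1L) * n_per + pos:(pos + len - 1L)
          guard <- (chr - 1L) * n_per +
            max(1L, pos - 3L):min(n_per, pos + len + 2L)
          if (!any(taken[guard])) { ok <- TRUE; break }
        }
        if (!ok) abort("could not place pre-split tandem arrays; genome too small.")
        taken[idx] <- TRUE
        arch <- sample(archs[grepl("N", archs)], 1,
                       prob = config$architecture_mix[grepl("N", archs)])
        genes$architecture[idx] <- arch
        arrays[[length(arrays) + 1L]] <- tibble(
          array_id = sprintf("truth_ta%02d", i),
          epoch = "pre_split", lineage = NA_character_,
          gene_id = genes$gene_id[idx], seed_of = genes$gene_id[idx[1]])
      }
    }
    genes$family <- dplyr::case_when(
      is.na(genes$architecture) ~ NA_character_,
      grepl("N", genes$architecture) ~ "NBS",
      TRUE ~ "TIR-X")

    # Proteins: family members from their architecture; tandem members copy
    # their array seed; background genes are random non-signature sequences.
    prot <- character(n)
    seed_prot <- new.env(parent = emptyenv())
    arr_tbl <- if (length(arrays)) bind_rows(arrays) else
      tibble(array_id = character(), epoch = character(),
             lineage = character(), gene_id = character(),
             seed_of = character())
    in_array <- setNames(arr_tbl$seed_of, arr_tbl$gene_id)
    for (i in seq_len(n)) {
      gid <- genes$gene_id[i]
      if (!is.na(genes$architecture[i])) {
        sd_of <- in_array[gid]
        if (!is.na(sd_of) && !is.null(seed_prot[[sd_of]])) {
          prot[i] <- seed_prot[[sd_of]]
        } else {
          prot[i] <- build_family_protein(genes$architecture[i])
          if (!is.na(sd_of)) seed_prot[[sd_of]] <- prot[i]
        }
      } else {
        prot[i] <- build_background_protein(
          sample(config$protein_len_range[1]:config$protein_len_range[2], 1))
      }
    }
    names(prot) <- genes$gene_id
    cds <- reverse_translate(prot)
    genes <- bind_rows(lapply(split(genes, genes$chromosome), function(g) {
      bind_cols(g, place_coordinates(nchar(prot[g$gene_id])))
    })) %>% arrange(.data$chromosome, .data$rank)

    list(genes = genes %>%
           select("gene_id", "species", "chromosome", "strand",
                  "start", "end", "rank", "family", "architecture"),
         cds = cds, proteins = prot,
         truth = list(tandem_arrays = arr_tbl,
                      clusters = truth_clusters(genes)))
  })
}

#' Triplicate an ancestral genome and fractionate one descendant lineage
#'
#' Each ancestral gene is copied onto three subgenomes, then lost entirely
#' with probability `loss_prob` or retained as 1-3 copies per
#' `retention_probs`. Surviving copies preserve ancestral gene order within
#' each subgenome. Species-specific tandem arrays assigned to this lineage
#' are planted afterwards by duplicating a surviving family copy in place.
#'
#' @param ancestor Result of [generate_ancestor()].
#' @param config A [simulation_config()].
#' @param lineage Lineage name (must appear in `config$omega_per_lineage`).
#' @return A list with `genes` (tibble incl. `ancestor_gene`, `subgenome`,
#'   `origin`), `cds`, `proteins`, and `truth` (tibbles `copy_map`,
#'   `tandem_arrays`, `clusters`).
#' @export
triplicate_and_fractionate <- function(ancestor, config, lineage) {
  stopifnot(inherits(config, "sim_config"),
            lineage %in% names(config$omega_per_lineage))
  with_stage_seed(config$seed, paste0("fractionate_", lineage), {
    anc <- ancestor$genes
    n <- nrow(anc)
    keep_ids <- if (config$keep_tandem_arrays)
      ancestor$truth$tandem_arrays$gene_id else character(0)
    lost <- runif(n) < config$loss_prob
    ncopy <- ifelse(lost, 0L,
                    sample(1:3, n, replace = TRUE,
                           prob = config$retention_probs))
    forced <- anc$gene_id %in% keep_ids
    ncopy[forced] <- pmax(ncopy[forced], 1L)
    sub_sets <- lapply(seq_len(n), function(i) {
      k <- ncopy[i]
      if (k == 0L) return(integer(0))
      s <- sort(sample(1:3, k))
      if (forced[i] && !(1L %in% s)) s <- sort(c(1L, s[-1]))
      s
    })

    copies <- tibble(
      ancestor_gene = rep(anc$gene_id, lengths(sub_sets)),
      anc_chromosome = rep(anc$chromosome, lengths(sub_sets)),
      anc_rank = rep(anc$rank, lengths(sub_sets)),
      strand = rep(anc$strand, lengths(sub_sets)),
      family = rep(anc$family, lengths(sub_sets)),
      architecture = rep(anc$architecture, lengths(sub_sets)),
      subgenome = unlist(sub_sets),
      origin = "wgt"
    ) %>%
      mutate(chromosome = sprintf("%s.s%d",
                                  sub("chr", paste0(lineage, "_chr"),
                                      .data$anc_chromosome),
                                  .data$subgenome)) %>%
      arrange(.data$chromosome, .data$anc_rank)

    # Plant species-specific arrays for this lineage by duplicating a
    # surviving family copy in place (round-robin assignment over lineages).
    spec <- config$tandem_array_spec
    sp <- spec[spec$epoch == "species_specific", , drop = FALSE]
    lineages <- names(config$omega_per_lineage)
    if (nrow(sp) > 0) {
      sp$lineage <- lineages[((seq_len(nrow(sp)) - 1L) %% length(lineages)) + 1L]
      sp <- sp[sp$lineage == lineage, , drop = FALSE]
    }
    arr_rows <- list()
    if (nrow(sp) > 0) {
      fam_idx <- which(copies$family %in% "NBS" &
                         !(copies$ancestor_gene %in% keep_ids))
      if (length(fam_idx) < nrow(sp)) {
        # revive lost family genes as single retained copies so every
        # configured array has an eligible seed
        lost_fam <- anc %>%
          filter(.data$family %in% "NBS",
                 !(.data$gene_id %in% copies$ancestor_gene),
                 !(.data$gene_id %in% keep_ids))
        need <- nrow(sp) - length(fam_idx)
        if (nrow(lost_fam) < need) {
          abort("not enough family genes to plant species-specific arrays.")
        }
        revived <- lost_fam[sample.int(nrow(lost_fam), need), ] %>%
          transmute(ancestor_gene = .data$gene_id,
                    anc_chromosome = .data$chromosome,
                    anc_rank = .data$rank, strand = .data$strand,
                    family = .data$family, architecture = .data$architecture,
                    subgenome = 1L, origin = "wgt") %>%
          mutate(chromosome = sprintf("%s.s%d",
                                      sub("chr", paste0(lineage, "_chr"),
                                          .data$anc_chromosome),
                                      .data$subgenome))
        copies <- bind_rows(copies, revived) %>%
          arrange(.data$chromosome, .data$anc_rank)
        fam_idx <- which(copies$family %in% "NBS" &
                           !(copies$ancestor_gene %in% keep_ids))
      }
      seeds <- sample(fam_idx, nrow(sp))
      extra <- list()
      for (j in seq_len(nrow(sp))) {
        s <- copies[seeds[j], ]
        k <- sp$len[j] - 1L
        dup <- s[rep(1L, k), ]
        dup$origin <- "tandem"
        # fractional ranks slot the duplicates immediately after their seed
        dup$anc_rank <- s$anc_rank + seq_len(k) / (k + 2)
        extra[[j]] <- dup
        arr_rows[[j]] <- tibble(
          array_id = sprintf("truth_%s_ta%02d", lineage, j),
          epoch = "species_specific", lineage = lineage,
          seed_of = s$ancestor_gene, n_members = k + 1L)
      }
      copies <- bind_rows(copies, bind_rows(extra)) %>%
        arrange(.data$chromosome, .data$anc_rank)
    }

    copies <- copies %>%
      group_by(.data$chromosome) %>%
      mutate(rank = row_number() - 1L) %>%
      ungroup() %>%
      mutate(gene_id = sprintf("%s_g%05d", toupper(lineage), row_number()),
             species = lineage)

    prot <- setNames(ancestor$proteins[copies$ancestor_gene], copies$gene_id)
    cds <- setNames(ancestor$cds[copies$ancestor_gene], copies$gene_id)
    coords <- copies %>%
      group_by(.data$chromosome) %>%
      group_modify(~ bind_cols(.x, place_coordinates(nchar(prot[.x$gene_id])))) %>%
      ungroup()
    genes <- coords %>%
      select("gene_id", "species", "chromosome", "strand", "start", "end",
             "rank", "family", "architecture", "ancestor_gene", "subgenome",
             "origin")

    # Truth tandem arrays carried by this lineage: descendants of pre-split
    # arrays that kept >= 2 adjacent members on a subgenome, plus the planted
    # species-specific arrays.
    arr_anc <- ancestor$truth$tandem_arrays
    pre_rows <- list()
    if (nrow(arr_anc) > 0) {
      for (aid in unique(arr_anc$array_id)) {
        members <- arr_anc$gene_id[arr_anc$array_id == aid]
        for (s in 1:3) {
          got <- genes %>%
            filter(.data$ancestor_gene %in% members, .data$subgenome == s,
                   .data$origin == "wgt")
          if (nrow(got) >= 2) {
            pre_rows[[length(pre_rows) + 1L]] <- tibble(
              array_id = sprintf("%s_%s_s%d", aid, lineage, s),
              epoch = "pre_split", lineage = lineage,
              gene_id = got$gene_id, seed_of = members[1])
          }
        }
      }
    }
    sp_rows <- list()
    if (length(arr_rows) > 0) {
      for (j in seq_along(arr_rows)) {
        a <- arr_rows[[j]]
        got <- genes %>%
          filter(.data$ancestor_gene == a$seed_of) %>%
          group_by(.data$chromosome) %>% filter(n() >= 2) %>% ungroup()
        sp_rows[[j]] <- tibble(array_id = a$array_id, epoch = a$epoch,
                               lineage = a$lineage, gene_id = got$gene_id,
                               seed_of = a$seed_of)
      }
    }
    tandem_truth <- bind_rows(c(pre_rows, sp_rows))
    if (nrow(tandem_truth) == 0) {
      tandem_truth <- tibble(array_id = character(), epoch = character(),
                             lineage = character(), gene_id = character(),
                             seed_of = character())
    }

    list(genes = genes, cds = cds, proteins = prot,
         truth = list(
           copy_map = genes %>%
             filter(.data$origin == "wgt") %>%
             select("ancestor_gene", gene_id = "gene_id", "subgenome") %>%
             mutate(lineage = lineage),
           tandem_arrays = tandem_truth,
           clusters = truth_clusters(genes)))
  })
}

#' Evolve coding sequences at a set dN/dS and synonymous divergence
#'
#' Codon-wise proposal/acceptance scheme: single-nucleotide changes are
#' proposed at random positions; changes creating stop codons are rejected,
#' synonymous changes are always accepted, and nonsynonymous changes are
#' accepted with probability `omega`. Proposals continue until the accepted
#' synonymous count reaches `ks_target` times the sequence's synonymous site
#' count, so realized synonymous divergence approaches `ks_target`.
#'
#' @param cds Named character vector of codon-clean CDS.
#' @param omega Nonsynonymous acceptance probability (dN/dS), `>= 0`.
#' @param ks_target Expected synonymous substitutions per synonymous site.
#' @param seed Integer seed for this evolution stage.
#' @return Named character vector of diverged CDS (same names and lengths).
#' @export
evolve_sequences <- function(cds, omega, ks_target, seed = 1L) {
  if (!is.numeric(omega) || omega < 0) {
    abort("`omega` must be >= 0.", class = "nbsfam_config_error")
  }
  if (!is.numeric(ks_target) || ks_target < 0) {
    abort("`ks_target` must be >= 0.", class = "nbsfam_config_error")
  }
  if (ks_target == 0) return(cds)
  gc <- genetic_code()
  nts <- c("A", "C", "G", "T")
  with_stage_seed(seed, "evolve", {
    out <- cds
    for (k in seq_along(cds)) {
      cods <- check_codon_clean(cds[[k]], names(cds)[k] %||% "cds")
      s_sites <- sum(vapply(cods, codon_syn_sites, numeric(1)))
      target <- ks_target * s_sites
      syn_acc <- 0
      it <- 0L
      max_it <- as.integer(2000 + 400 * target)
      while (syn_acc < target && it < max_it) {
        it <- it + 1L
        ci <- sample.int(length(cods), 1)
        pos <- sample.int(3L, 1)
        old <- cods[[ci]]
        nt_old <- substr(old, pos, pos)
        nt_new <- sample(setdiff(nts, nt_old), 1)
        new <- old
        substr(new, pos, pos) <- nt_new
        if (gc[[new]] == "*") next
        if (gc[[new]] == gc[[old]]) {
          cods[[ci]] <- new
          syn_acc <- syn_acc + 1
        } else if (runif(1) < omega) {
          cods[[ci]] <- new
        }
      }
      out[[k]] <- paste(cods, collapse = "")
    }
    out
  })
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

# Fraction of the 9 single-nucleotide neighbours of a codon that are
# synonymous, expressed as synonymous site count (out of 3).
codon_syn_sites <- function(codon) {
  env <- nbsfam_cache()
  if (is.null(env$syn_sites)) {
    gc <- genetic_code()
    nts <- c("A", "C", "G", "T")
    sc <- sense_codons()
    v <- vapply(sc, function(cod) {
      s <- 0
      for (pos in 1:3) for (nt in setdiff(nts, substr(cod, pos, pos))) {
        new <- cod
        substr(new, pos, pos) <- nt
        if (gc[[new]] == gc[[cod]]) s <- s + 1 / 3
      }
      s
    }, numeric(1))
    env$syn_sites <- v
  }
  env$syn_sites[[codon]]
}

nbsfam_cache_env <- new.env(parent = emptyenv())
nbsfam_cache <- function() nbsfam_cache_env

#' Simulate tissue expression profiles with controlled pair divergence
#'
#' Builds log2-scale expression profiles pair by pair: the first unseen gene
#' of a pair receives a fresh random profile; its partner is constructed so
#' the within-pair `1 - Pearson` divergence of the noiseless profiles equals
#' the dial for the pair's relation exactly (the partner profile mixes the
#' built profile with an orthogonalised random component). Measurement noise
#' is then added and profiles are mapped to nonnegative FPKM.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`, `relation`
#'   (`"ortholog"` or `"paralog"`). Pairs are processed in order; a pair whose
#'   two genes both already have profiles contributes no new construction.
#' @param tissues Character vector of tissue names (>= 3 for exact dials).
#' @param divergence Named dials in `[0, 2]` per relation.
#' @param noise_sd Log2-scale iid noise added to every profile.
#' @param seed Integer seed.
#' @param extra_genes Genes to simulate independently of any pair.
#' @return Tibble: `gene_id` plus one FPKM column per tissue.
#' @export
simulate_expression <- function(pairs, tissues,
                                divergence = c(ortholog = 0.3, paralog = 0.8),
                                noise_sd = 0.25, seed = 1L,
                                extra_genes = character(0)) {
  if (any(divergence < 0)) {
    abort("divergence dials must be >= 0.", class = "nbsfam_config_error")
  }
  if (any(divergence > 2)) {
    abort("divergence dials must be <= 2.", class = "nbsfam_config_error")
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs) > 0) {
    stopifnot(all(c("gene_a", "gene_b", "relation") %in% names(pairs)),
              all(pairs$relation %in% names(divergence)))
  }
  nt <- length(tissues)
  build <- function() {
    prof <- new.env(parent = emptyenv())
    fresh <- function() rnorm(nt, mean = 4, sd = 2)
    mix_from <- function(x, d) {
      rho <- 1 - d
      z <- rnorm(nt)
      xc <- x - mean(x)
      if (sum(xc^2) < 1e-12) return(x + z * 0)  # degenerate flat profile
      zo <- z - sum(z * xc) / sum(xc^2) * xc    # orthogonal to x
      zo <- zo - mean(zo)
      if (sum(zo^2) < 1e-12) zo <- xc[c(2:nt, 1)] - mean(xc[c(2:nt, 1)])
      mean(x) + rho * xc + sqrt(max(0, 1 - rho^2)) *
        sqrt(sum(xc^2) / sum(zo^2)) * zo
    }
    if (nrow(pairs) > 0) {
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
        d <- divergence[[pairs$relation[i]]]
        ha <- !is.null(prof[[a]]); hb <- !is.null(prof[[b]])
        if (!ha && !hb) { prof[[a]] <- fresh(); prof[[b]] <- mix_from(prof[[a]], d) }
        else if (ha && !hb) prof[[b]] <- mix_from(prof[[a]], d)
        else if (!ha && hb) prof[[a]] <- mix_from(prof[[b]], d)
        # both present: divergence is emergent, nothing to construct
      }
    }
    for (g in setdiff(extra_genes, ls(prof))) prof[[g]] <- fresh()
    ids <- ls(prof)
    if (length(ids) == 0) {
      out <- tibble(gene_id = character())
      for (t in tissues) out[[t]] <- numeric(0)
      return(out)
    }
    m <- t(vapply(ids, function(g) prof[[g]], numeric(nt)))
    if (noise_sd > 0) m <- m + matrix(rnorm(length(m), sd = noise_sd), nrow(m))
    fpkm <- pmax(2^m - 1, 0)
    colnames(fpkm) <- tissues
    bind_cols(tibble(gene_id = ids), as_tibble(fpkm))
  }
  with_stage_seed(seed, "expression", build())
}

#' Generate a complete synthetic genome set
#'
#' Drives the full simulation: ancestor generation, triplication and
#' fractionation into each configured lineage, codon divergence at the
#' lineage dN/dS and Ks dials, and tissue expression for all family genes
#' (ortholog pairs diverge by the `ortholog` dial, within-lineage paralog
#' pairs by the `paralog` dial).
#'
#' @param config A [simulation_config()].
#' @return A list with `config`, `species` (named list of genomes: `ancestor`
#'   plus one per lineage, each with `genes`, `cds`, `proteins`), `expression`
#'   (FPKM tibble over all simulated genes), and `truth` (list of tibbles:
#'   `genes`, `tandem_arrays`, `clusters`, `copy_map`, `ortholog_pairs`,
#'   `paralog_pairs`, `lineage_omega`).
#' @export
generate_genome_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  anc <- generate_ancestor(config)
  lineages <- names(config$omega_per_lineage)
  desc <- lapply(lineages, function(ln) {
    d <- triplicate_and_fractionate(anc, config, ln)
    d$cds <- evolve_sequences(d$cds, config$omega_per_lineage[[ln]],
                              config$ks_target_per_lineage[[ln]],
                              seed = stage_seed(config$seed, ln))
    # tandem duplicates are young: re-derive them from their (already
    # diverged) seed copy with a small extra synonymous distance
    tand <- d$genes %>% filter(.data$origin == "tandem")
    if (nrow(tand) > 0) {
      seeds <- d$genes %>%
        filter(.data$origin == "wgt") %>%
        select("ancestor_gene", "chromosome", seed_id = "gene_id")
      tand <- tand %>%
        left_join(seeds, by = c("ancestor_gene", "chromosome")) %>%
        filter(!is.na(.data$seed_id))
      fresh <- evolve_sequences(
        setNames(d$cds[tand$seed_id], tand$gene_id),
        config$omega_per_lineage[[ln]], config$tandem_ks,
        seed = stage_seed(config$seed, paste0(ln, "_tandem")))
      d$cds[names(fresh)] <- fresh
    }
    d$proteins <- vapply(d$cds, translate_cds, character(1))
    d
  })
  names(desc) <- lineages

  copy_map <- bind_rows(lapply(desc, function(d) d$truth$copy_map))
  ortho <- copy_map %>%
    transmute(gene_a = .data$ancestor_gene, gene_b = .data$gene_id,
              relation = "ortholog", lineage = .data$lineage)
  para <- bind_rows(lapply(desc, function(d) {
    dup <- d$genes %>%
      filter(!is.na(.data$ancestor_gene), !is.na(.data$family)) %>%
      group_by(.data$ancestor_gene) %>%
      filter(n() >= 2) %>%
      ungroup()
    if (nrow(dup) == 0) {
      return(tibble(gene_a = character(), gene_b = character(),
                    relation = character(), lineage = character()))
    }
    dup %>%
      group_by(.data$ancestor_gene) %>%
      summarise(pairs = list({
        ids <- .data$gene_id
        cmb <- utils::combn(ids, 2)
        tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
      }), .groups = "drop") %>%
      tidyr::unnest("pairs") %>%
      mutate(relation = "paralog", lineage = d$genes$species[1]) %>%
      select("gene_a", "gene_b", "relation", "lineage")
  }))

  fam_anc <- anc$genes %>% filter(!is.na(.data$family)) %>% pull("gene_id")
  fam_desc <- unlist(lapply(desc, function(d)
    d$genes %>% filter(!is.na(.data$family)) %>% pull("gene_id")))
  pair_tbl <- bind_rows(
    ortho %>% filter(.data$gene_a %in% fam_anc | .data$gene_b %in% fam_desc),
    para)
  expr <- simulate_expression(
    pair_tbl %>% select("gene_a", "gene_b", "relation"),
    config$expression_tissues, config$expression_divergence,
    config$expression_noise_sd, seed = config$seed,
    extra_genes = setdiff(c(fam_anc, fam_desc),
                          c(pair_tbl$gene_a, pair_tbl$gene_b)))

  genes_all <- bind_rows(c(list(ancestor = anc$genes),
                           lapply(desc, function(d) d$genes)))
  list(config = config,
       species = c(list(ancestor = list(genes = anc$genes, cds = anc$cds,
                                        proteins = anc$proteins)),
                   lapply(desc, function(d)
                     list(genes = d$genes, cds = d$cds,
                          proteins = d$proteins))),
       expression = expr,
       truth = list(
         genes = genes_all,
         tandem_arrays = bind_rows(c(
           list(anc$truth$tandem_arrays %>% mutate(lineage = "ancestor")),
           lapply(desc, function(d) d$truth$tandem_arrays))),
         clusters = bind_rows(c(
           list(anc$truth$clusters %>% mutate(species = "ancestor")),
           lapply(desc, function(d)
             d$truth$clusters %>% mutate(species = d$genes$species[1])))),
         copy_map = copy_map,
         ortholog_pairs = ortho,
         paralog_pairs = para,
         lineage_omega = tibble(lineage = lineages,
                                omega = unname(config$omega_per_lineage),
                                ks_target = unname(
                                  config$ks_target_per_lineage))))
}
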