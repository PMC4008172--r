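# Pipeline orchestration: staged execution over a working directory with
# explicit dependency checks, atomic stage outputs, a deterministic
# line-oriented log, and a consolidated report.

PIPELINE_STAGES <- c("simulate", "identify", "classify", "clusters",
                     "tandem", "synteny", "retention", "kaks",
                     "expression", "report")

#' Pipeline configuration
#'
#' Aggregates every stage threshold behind one object: similarity E-value
#' cutoff 1e-20, 8-ORF cluster window, one intervening gene per tandem gap,
#' minimum 5 anchors per synteny block, coiled-coil consensus thresholds
#' 0.025 (P-score) / 0.90 (probability), pseudocount 1, and the master seed.
#'
#' @param seed Master seed (also seeds the simulation config unless one is
#'   supplied).
#' @param sim A [simulation_config()]; defaults to one built from `seed`.
#' @param evalue_max Similarity E-value cutoff for imported tables.
#' @param min_identity Percent-identity proxy threshold for the built-in
#'   similarity search.
#' @param cluster_window Maximum intervening ORFs within a cluster.
#' @param tandem_gap Maximum unrelated genes between tandem members.
#' @param min_anchors,max_gap Synteny chaining parameters.
#' @param cc_pscore,cc_prob Coiled-coil consensus thresholds.
#' @param pseudocount Expression log-transform pseudocount.
#' @param reference Species acting as the non-triplicated reference genome.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, evalue_max = 1e-20,
                            min_identity = 50, cluster_window = 8L,
                            tandem_gap = 1L, min_anchors = 5L, max_gap = 25L,
                            cc_pscore = 0.025, cc_prob = 0.90,
                            pseudocount = 1, reference = "ancestor") {
  stopifnot(evalue_max > 0, cluster_window >= 1, tandem_gap >= 0,
            min_anchors >= 1, max_gap >= 1, pseudocount > 0,
            cc_pscore > 0, cc_prob > 0)
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  structure(list(seed = as.integer(seed), sim = sim,
                 evalue_max = evalue_max, min_identity = min_identity,
                 cluster_window = as.integer(cluster_window),
                 tandem_gap = as.integer(tandem_gap),
                 min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 cc_pscore = cc_pscore, cc_prob = cc_prob,
                 pseudocount = pseudocount, reference = reference),
            class = "pipeline_config")
}

pipeline_log <- function(dir, stage, ...) {
  kv <- c(...)
  line <- paste0("stage=", stage,
                 if (length(kv)) paste0("\t", paste(names(kv), "=", kv,
                                                    sep = "", collapse = "\t")))
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

stage_species <- function(dir) {
  sims <- list.dirs(file.path(dir, "simulate"), recursive = FALSE)
  sp <- basename(sims)
  sp[sp != "truth"]
}

require_upstream <- function(dir, paths, stage) {
  missing <- paths[!file.exists(file.path(dir, paths))]
  if (length(missing) > 0) {
    abort(sprintf("stage '%s' is missing upstream output(s): %s (run the earlier stages first).",
                  stage, paste(missing, collapse = ", ")),
          class = "nbsfam_dependency_error")
  }
}

# Stage outputs are assembled in a scratch directory and renamed into place,
# so a failed stage never leaves a partial output directory behind.
with_atomic_stage_dir <- function(dir, stage, code) {
  final <- file.path(dir, stage)
  tmp <- file.path(dir, paste0(".tmp_", stage))
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch(code(tmp), error = function(e) {
    unlink(tmp, recursive = TRUE)
    stop(e)
  })
  unlink(final, recursive = TRUE)
  file.rename(tmp, final)
  res
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `identify`, `classify`, `clusters`, `tandem`,
#' `synteny`, `retention`, `kaks`, `expression`, `report`. Each stage reads
#' the outputs of its upstream stages from `dir`, writes its own outputs
#' atomically under `dir/<stage>/`, and appends structured lines to
#' `dir/pipeline.log`.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param dir Pipeline working directory.
#' @return Invisibly, the stage's primary output (varies by stage).
#' @export
run_stage <- function(stage, config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!stage %in% PIPELINE_STAGES) {
    abort(sprintf("unknown stage '%s'; available stages: %s",
                  stage, paste(PIPELINE_STAGES, collapse = ", ")),
          class = "nbsfam_usage_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- get(paste0("stage_", stage), mode = "function")
  invisible(fn(config, dir))
}

#' Run the full pipeline
#'
#' @inheritParams run_stage
#' @param stages Stages to run, in order (default: all).
#' @return Invisibly, the final [build_report()] when `report` is among the
#'   stages.
#' @export
run_pipeline <- function(config, dir, stages = PIPELINE_STAGES) {
  res <- NULL
  for (s in stages) res <- run_stage(s, config, dir)
  invisible(res)
}

stage_simulate <- function(config, dir) {
  sim <- generate_genome_set(config$sim)
  with_atomic_stage_dir(dir, "simulate", function(tmp) {
    write_genome_set(sim, tmp)
  })
  pipeline_log(dir, "simulate", seed = config$sim$seed,
               n_genes = nrow(sim$truth$genes))
  sim
}

stage_identify <- function(config, dir) {
  require_upstream(dir, "simulate", "identify")
  species <- stage_species(dir)
  require_upstream(dir, file.path("simulate", species, "proteins.fasta"),
                   "identify")
  hits_all <- with_atomic_stage_dir(dir, "identify", function(tmp) {
    out <- lapply(species, function(sp) {
      prot <- read_fasta(file.path(dir, "simulate", sp, "proteins.fasta"))
      hits <- scan_domains_two_pass(prot)
      cc <- builtin_cc_score(prot)
      cc_hits <- consensus_coiled_coil(cc, cc,
                                       cutoff_a = config$cc_prob,
                                       cutoff_b = config$cc_prob)
      all_hits <- bind_rows(hits, cc_hits) %>%
        arrange(.data$protein_id, .data$start)
      readr::write_tsv(all_hits, file.path(tmp, paste0(sp, "_hits.tsv")))
      all_hits
    })
    setNames(out, species)
  })
  for (sp in species) {
    pipeline_log(dir, "identify", species = sp,
                 n_hits = nrow(hits_all[[sp]]))
  }
  hits_all
}

stage_classify <- function(config, dir) {
  require_upstream(dir, "simulate", "classify")
  species <- stage_species(dir)
  require_upstream(dir, file.path("identify", paste0(species, "_hits.tsv")),
                   "classify")
  res <- with_atomic_stage_dir(dir, "classify", function(tmp) {
    cls <- lapply(species, function(sp) {
      hits <- readr::read_tsv(file.path(dir, "identify",
                                        paste0(sp, "_hits.tsv")),
                              show_col_types = FALSE)
      cl <- suppressWarnings(classify_genes(hits)) %>% mutate(species = sp)
      readr::write_tsv(cl, file.path(tmp, paste0(sp, "_classification.tsv")))
      cl
    })
    combined <- bind_rows(cls)
    summary <- summarize_counts(combined)
    readr::write_tsv(summary, file.path(tmp, "summary.tsv"))
    list(classification = combined, summary = summary)
  })
  pipeline_log(dir, "classify", n_classified = nrow(res$classification))
  res
}

read_stage_classification <- function(dir, sp) {
  readr::read_tsv(file.path(dir, "classify",
                            paste0(sp, "_classification.tsv")),
                  show_col_types = FALSE)
}

read_stage_genes <- function(dir, sp) {
  read_gene_gff3(file.path(dir, "simulate", sp, "genes.gff3"))
}

family_genes <- function(dir, sp) {
  cl <- read_stage_classification(dir, sp)
  fam_ids <- cl$gene_id[cl$category %in% NBS_CATEGORIES]
  read_stage_genes(dir, sp) %>%
    mutate(is_family = .data$gene_id %in% fam_ids)
}

stage_clusters <- function(config, dir) {
  require_upstream(dir, "simulate", "clusters")
  species <- stage_species(dir)
  require_upstream(dir, c(file.path("classify",
                                    paste0(species, "_classification.tsv"))),
                   "clusters")
  res <- with_atomic_stage_dir(dir, "clusters", function(tmp) {
    out <- lapply(species, function(sp) {
      genes <- family_genes(dir, sp)
      cl <- call_clusters(genes, window = config$cluster_window)
      hom <- label_homogeneity(cl, read_stage_classification(dir, sp))
      readr::write_tsv(cl, file.path(tmp, paste0(sp, "_clusters.tsv")))
      readr::write_tsv(hom, file.path(tmp, paste0(sp, "_homogeneity.tsv")))
      tibble(species = sp,
             genes_on_chromosomes = sum(genes$is_family),
             genes_in_clusters = nrow(cl),
             clusters = n_distinct(cl$cluster_id))
    })
    summary <- summarize_clusters(bind_rows(out))
    readr::write_tsv(summary, file.path(tmp, "summary.tsv"))
    summary
  })
  pipeline_log(dir, "clusters", n_species = length(species))
  res
}

stage_tandem <- function(config, dir) {
  require_upstream(dir, "simulate", "tandem")
  species <- stage_species(dir)
  require_upstream(dir, c(file.path("classify",
                                    paste0(species, "_classification.tsv"))),
                   "tandem")
  res <- with_atomic_stage_dir(dir, "tandem", function(tmp) {
    out <- lapply(species, function(sp) {
      genes <- family_genes(dir, sp)
      prot <- read_fasta(file.path(dir, "simulate", sp, "proteins.fasta"))
      sim <- builtin_similarity(prot, genes = genes,
                                min_identity = config$min_identity,
                                max_rank_gap = config$tandem_gap + 1L)
      arr <- detect_tandem_arrays(genes, sim,
                                  max_intervening = config$tandem_gap)
      readr::write_tsv(arr, file.path(tmp, paste0(sp, "_arrays.tsv")))
      arr %>% mutate(species = sp)
    })
    bind_rows(out)
  })
  pipeline_log(dir, "tandem", n_arrays = n_distinct(res$array_id))
  res
}

stage_synteny <- function(config, dir) {
  require_upstream(dir, "simulate", "synteny")
  species <- stage_species(dir)
  ref <- config$reference
  others <- setdiff(species, ref)
  require_upstream(dir, file.path("simulate", c(ref, others),
                                  "proteins.fasta"), "synteny")
  require_upstream(dir, file.path("classify",
                                  paste0(c(ref, others),
                                         "_classification.tsv")), "synteny")
  res <- with_atomic_stage_dir(dir, "synteny", function(tmp) {
    prot_ref <- read_fasta(file.path(dir, "simulate", ref, "proteins.fasta"))
    genes_ref <- read_stage_genes(dir, ref)
    out <- lapply(others, function(sp) {
      prot_sp <- read_fasta(file.path(dir, "simulate", sp, "proteins.fasta"))
      hom <- find_homolog_pairs(prot_ref, prot_sp,
                                min_identity = config$min_identity)
      anchors <- find_anchors(hom, genes_ref, read_stage_genes(dir, sp))
      blocks <- chain_blocks(anchors, min_anchors = config$min_anchors,
                             max_gap = config$max_gap)
      pairs <- extract_ortholog_pairs(blocks,
                                      read_stage_classification(dir, ref),
                                      read_stage_classification(dir, sp))
      readr::write_tsv(blocks, file.path(tmp, paste0(sp, "_blocks.tsv")))
      readr::write_tsv(pairs, file.path(tmp, paste0(sp, "_pairs.tsv")))
      list(blocks = blocks, pairs = pairs)
    })
    setNames(out, others)
  })
  pipeline_log(dir, "synteny", reference = ref,
               n_comparisons = length(others))
  res
}

stage_retention <- function(config, dir) {
  require_upstream(dir, "simulate", "retention")
  species <- setdiff(stage_species(dir), config$reference)
  require_upstream(dir, file.path("synteny", paste0(species, "_pairs.tsv")),
                   "retention")
  res <- with_atomic_stage_dir(dir, "retention", function(tmp) {
    recs <- lapply(species, function(sp) {
      pairs <- readr::read_tsv(file.path(dir, "synteny",
                                         paste0(sp, "_pairs.tsv")),
                               show_col_types = FALSE)
      rec <- retention_accounting(pairs)
      readr::write_tsv(rec$histogram,
                       file.path(tmp, paste0(sp, "_histogram.tsv")))
      readr::write_tsv(rec$records,
                       file.path(tmp, paste0(sp, "_records.tsv")))
      rec
    })
    names(recs) <- species
    if (length(recs) >= 2) {
      totals <- vapply(species, function(sp) {
        cl <- read_stage_classification(dir, sp)
        sum(cl$category %in% NBS_CATEGORIES)
      }, numeric(1))
      cross <- cross_comparison_sets(recs[[1]], recs[[2]],
                                     total_a = totals[1],
                                     total_b = totals[2])
      readr::write_tsv(cross, file.path(tmp, "cross_comparison.tsv"))
    }
    recs
  })
  pipeline_log(dir, "retention", n_comparisons = length(res))
  res
}

stage_kaks <- function(config, dir) {
  require_upstream(dir, "simulate", "kaks")
  species <- setdiff(stage_species(dir), config$reference)
  require_upstream(dir, file.path("synteny", paste0(species, "_pairs.tsv")),
                   "kaks")
  res <- with_atomic_stage_dir(dir, "kaks", function(tmp) {
    all_cds <- do.call(c, lapply(stage_species(dir), function(sp)
      read_fasta(file.path(dir, "simulate", sp, "cds.fasta"), type = "DNA")))
    tab <- bind_rows(lapply(species, function(sp) {
      pairs <- readr::read_tsv(file.path(dir, "synteny",
                                         paste0(sp, "_pairs.tsv")),
                               show_col_types = FALSE)
      if (nrow(pairs) == 0) return(NULL)
      ptab <- pairs %>%
        transmute(gene_a = .data$ref_gene, gene_b = .data$counterpart,
                  category = .data$ref_category, lineage = sp)
      suppressWarnings(compute_kaks_pairs(ptab, all_cds))
    }))
    readr::write_tsv(tab, file.path(tmp, "kaks.tsv"))
    if (nrow(tab) > 0 &&
        length(unique(tab$lineage[is.finite(tab$ka_ks)])) == 2) {
      cmp <- compare_lineages(tab, "lineage", "ka_ks")
      readr::write_tsv(bind_cols(tidy(cmp)[1, ], glance(cmp)),
                       file.path(tmp, "comparison.tsv"))
    }
    tab
  })
  pipeline_log(dir, "kaks", n_pairs = nrow(res))
  res
}

stage_expression <- function(config, dir) {
  require_upstream(dir, "simulate", "expression")
  require_upstream(dir, c("expression.tsv",
                          file.path("truth", "ortholog_pairs.tsv"),
                          file.path("truth", "paralog_pairs.tsv")) %>%
                     file.path("simulate", .), "expression")
  res <- with_atomic_stage_dir(dir, "expression", function(tmp) {
    fpkm <- read_fpkm_tsv(file.path(dir, "simulate", "expression.tsv"))
    logm <- log_transform(fpkm, pseudocount = config$pseudocount)
    readr::write_tsv(logm, file.path(tmp, "log2_matrix.tsv"))
    out <- list(matrix = logm)
    if (nrow(logm) >= 2) {
      cl <- suppressWarnings(hier_cluster(logm))
      export_heatmap(cl, file.path(tmp, "heatmap.tsv"))
      out$clustering <- cl
    }
    pairs <- bind_rows(
      readr::read_tsv(file.path(dir, "simulate", "truth",
                                "ortholog_pairs.tsv"),
                      show_col_types = FALSE),
      readr::read_tsv(file.path(dir, "simulate", "truth",
                                "paralog_pairs.tsv"),
                      show_col_types = FALSE))
    pairs <- pairs %>% filter(.data$gene_a %in% logm$gene_id,
                              .data$gene_b %in% logm$gene_id)
    if (nrow(pairs) > 0) {
      div <- pair_divergence(logm, pairs)
      readr::write_tsv(div$scores, file.path(tmp, "divergence.tsv"))
      readr::write_tsv(div$summary,
                       file.path(tmp, "divergence_summary.tsv"))
      out$divergence <- div
    }
    out
  })
  pipeline_log(dir, "expression", n_genes = nrow(res$matrix))
  res
}

stage_report <- function(config, dir) {
  report <- build_report(dir)
  with_atomic_stage_dir(dir, "report", function(tmp) {
    for (nm in names(report)) {
      if (is.data.frame(report[[nm]])) {
        readr::write_tsv(report[[nm]], file.path(tmp, paste0(nm, ".tsv")))
      }
    }
    TRUE
  })
  pipeline_log(dir, "report", sections = length(report))
  report
}

read_tsv_if <- function(path) {
  if (file.exists(path)) readr::read_tsv(path, show_col_types = FALSE)
  else NULL
}

#' Build the consolidated pipeline report
#'
#' Collects every completed stage's summary into one object: classification
#' census, cluster and tandem statistics with percentages, retention
#' histograms and the cross-comparison overlap/union, and the lineage Ka/Ks
#' comparison. Every percentage is recomputed from the report's own counts.
#'
#' @param dir Pipeline working directory.
#' @return Object of class `nbsfam_report` (a named list of tibbles).
#' @export
build_report <- function(dir) {
  species <- stage_species(dir)
  rep <- list()
  rep$classification <- read_tsv_if(file.path(dir, "classify", "summary.tsv"))
  rep$clusters <- read_tsv_if(file.path(dir, "clusters", "summary.tsv"))
  tand <- lapply(species, function(sp) {
    arr <- read_tsv_if(file.path(dir, "tandem", paste0(sp, "_arrays.tsv")))
    if (is.null(arr)) return(NULL)
    cls <- read_tsv_if(file.path(dir, "classify",
                                 paste0(sp, "_classification.tsv")))
    total <- if (is.null(cls)) NA_integer_
             else sum(cls$category %in% NBS_CATEGORIES)
    tibble(species = sp, total_nbs = total, tandem_genes = nrow(arr),
           tandem_arrays = n_distinct(arr$array_id))
  })
  tand <- bind_rows(tand)
  if (nrow(tand) > 0) rep$tandem <- summarize_tandem(tand)
  hist <- lapply(species, function(sp) {
    h <- read_tsv_if(file.path(dir, "retention",
                               paste0(sp, "_histogram.tsv")))
    if (is.null(h) || nrow(h) == 0) NULL
    else h %>% mutate(copies = as.integer(.data$copies),
                      n_ref_genes = as.integer(.data$n_ref_genes),
                      species = sp)
  })
  hist <- bind_rows(hist)
  if (nrow(hist) > 0) rep$retention <- hist
  rep$cross_comparison <- read_tsv_if(file.path(dir, "retention",
                                                "cross_comparison.tsv"))
  rep$kaks_comparison <- read_tsv_if(file.path(dir, "kaks",
                                               "comparison.tsv"))
  rep$divergence <- read_tsv_if(file.path(dir, "expression",
                                          "divergence_summary.tsv"))
  rep <- purrr::compact(rep)
  class(rep) <- c("nbsfam_report", class(rep))
  rep
}

#' @export
print.nbsfam_report <- function(x, ...) {
  cat("<nbsfam_report>\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(as_tibble(x[[nm]]))
  }
  invisible(x)
}
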