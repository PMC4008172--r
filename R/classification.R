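# Architecture collapsing and family-category assignment (TNL, CNL,
# NBS-LRR, TIR-NBS, CC-NBS, NBS, TIR-X), plus census-style summaries.

TOKEN_MAP <- c(TIR = "T", CC = "C", NBS = "N", LRR = "L")
NBS_CATEGORIES <- c("TNL", "CNL", "NBS-LRR", "TIR-NBS", "CC-NBS", "NBS")
ALL_CATEGORIES <- c(NBS_CATEGORIES, "TIR-X")

#' Collapse ordered domain hits into an architecture string
#'
#' Tokens follow hit start order: TIR -> `T`, CC -> `C`, NBS -> `N`,
#' LRR -> `L`. For example hits ordered TIR, NBS, LRR collapse to `"TNL"`
#' and TIR, NBS, NBS, LRR to `"TNNL"`.
#'
#' @param hits Domain-hit tibble for one protein (see [scan_domains()]).
#' @return Single architecture string.
#' @export
collapse_architecture <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    abort("no domain hits: gene is not a family member.",
          class = "nbsfam_classify_error")
  }
  if (length(unique(hits$protein_id)) != 1) {
    abort("hits must belong to a single protein.",
          class = "nbsfam_input_error")
  }
  hits <- hits %>% arrange(.data$start, .data$end)
  bad <- setdiff(unique(hits$domain), names(TOKEN_MAP))
  if (length(bad) > 0) {
    abort(sprintf("unknown domain label(s): %s", paste(bad, collapse = ", ")),
          class = "nbsfam_input_error")
  }
  paste(TOKEN_MAP[hits$domain], collapse = "")
}

#' Assign the family category of an architecture
#'
#' Presence-based rules evaluated in order: no `N` with `T` gives TIR-X
#' (TIR-only genes, excluded from the NBS-encoding set); with `N`:
#' `T` and `L` give TNL, `C` and `L` (no `T`) CNL, `L` alone NBS-LRR, `T`
#' TIR-NBS, `C` CC-NBS, otherwise NBS. `T` takes precedence over `C` when
#' both are present (a TIR-CC-NBS-LRR architecture is a TNL).
#'
#' @param architecture Architecture string over tokens `T`, `C`, `N`, `L`
#'   (vectorised).
#' @return Character vector of categories.
#' @export
assign_category <- function(architecture) {
  vapply(architecture, function(a) {
    tok <- strsplit(a, "")[[1]]
    if (!all(tok %in% c("T", "C", "N", "L"))) {
      abort(sprintf("invalid architecture string '%s'.", a),
            class = "nbsfam_input_error")
    }
    has <- function(x) x %in% tok
    if (!has("N")) {
      if (has("T")) return("TIR-X")
      abort(sprintf("architecture '%s' has neither NBS nor TIR: not a family member.",
                    a), class = "nbsfam_classify_error")
    }
    if (has("T") && has("L")) return("TNL")
    if (has("C") && has("L")) return("CNL")
    if (has("L")) return("NBS-LRR")
    if (has("T")) return("TIR-NBS")
    if (has("C")) return("CC-NBS")
    "NBS"
  }, character(1), USE.NAMES = FALSE)
}

#' Classify all genes from their domain hits
#'
#' Collapses hits per protein into architecture strings and assigns
#' categories; proteins whose architecture carries neither an NBS nor a TIR
#' token are dropped with a warning (not family members).
#'
#' @param hits Domain-hit tibble for many proteins.
#' @return Tibble: `gene_id`, `architecture`, `category`.
#' @export
classify_genes <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), architecture = character(),
                  category = character()))
  }
  arch <- hits %>%
    arrange(.data$protein_id, .data$start, .data$end) %>%
    group_by(gene_id = .data$protein_id) %>%
    summarise(architecture = paste(TOKEN_MAP[.data$domain], collapse = ""),
              .groups = "drop")
  tok_ok <- grepl("N", arch$architecture) | grepl("T", arch$architecture)
  if (any(!tok_ok)) {
    warn(sprintf("%d gene(s) with neither NBS nor TIR evidence dropped.",
                 sum(!tok_ok)))
    arch <- arch[tok_ok, , drop = FALSE]
  }
  arch %>% mutate(category = assign_category(.data$architecture))
}

#' Census-style category summary
#'
#' Counts genes per category and species and derives the census totals:
#' `Total NBS` (the six NBS-containing categories), `Total TIR-NBS`
#' (TNL + TIR-NBS), `Total CC-NBS` (CNL + CC-NBS), and `Total`
#' (Total NBS + TIR-X).
#'
#' @param classified Tibble with columns `species` and `category` (one row
#'   per gene), e.g. [classify_genes()] output plus a species column, or a
#'   pre-counted table with a `count` column.
#' @return Tibble: `species`, one column per category, `total_nbs`,
#'   `total_tir_nbs`, `total_cc_nbs`, `total`.
#' @export
summarize_counts <- function(classified) {
  classified <- as_tibble(classified)
  if (nrow(classified) == 0) {
    out <- tibble(species = character())
    for (cat in ALL_CATEGORIES) out[[cat]] <- integer()
    return(out %>% mutate(total_nbs = integer(), total_tir_nbs = integer(),
                          total_cc_nbs = integer(), total = integer()))
  }
  bad <- setdiff(unique(classified$category), ALL_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown category: %s", paste(bad, collapse = ", ")),
          class = "nbsfam_input_error")
  }
  counts <- if ("count" %in% names(classified)) {
    classified %>% group_by(.data$species, .data$category) %>%
      summarise(n = sum(.data$count), .groups = "drop")
  } else {
    classified %>% count(.data$species, .data$category, name = "n")
  }
  counts %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L) %>%
    (function(df) {
      for (cat in setdiff(ALL_CATEGORIES, names(df))) df[[cat]] <- 0L
      df
    }) %>%
    select("species", dplyr::all_of(ALL_CATEGORIES)) %>%
    mutate(total_nbs = rowSums(across(dplyr::all_of(NBS_CATEGORIES))),
           total_tir_nbs = .data$TNL + .data$`TIR-NBS`,
           total_cc_nbs = .data$CNL + .data$`CC-NBS`,
           total = .data$total_nbs + .data$`TIR-X`)
}
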