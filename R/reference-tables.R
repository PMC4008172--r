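# Bundled reference tables: published census counts, ortholog pair tables
# and duplication statistics for the three crucifer genomes. They serve as
# worked-example inputs for the summary operations.

#' Path to a bundled reference table
#'
#' @param file File name under the package's `extdata`; with no argument,
#'   lists the available files.
#' @return File path (or vector of file names).
#' @export
nbs_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "nbsfam")))
  }
  path <- system.file("extdata", file, package = "nbsfam")
  if (path == "") abort(sprintf("no bundled file '%s'.", file))
  path
}

#' Published family census counts
#'
#' Per-species, per-category NBS gene counts for *B. oleracea*, *B. rapa*
#' and *A. thaliana*.
#'
#' @return Tibble: `species`, `category`, `count`.
#' @export
load_census_counts <- function() {
  readr::read_tsv(nbs_example("table1_category_counts.tsv"),
                  show_col_types = FALSE)
}

#' Published ortholog pair tables
#'
#' The printed ortholog gene pairs of NBS-encoding genes between the
#' *A. thaliana* reference and one *Brassica* genome, with domain types
#' mapped onto the package's category scheme (via the architecture rules, so
#' e.g. a TIR-CC-NBS-LRR row classifies as TNL).
#'
#' @param species `"boleracea"` or `"brapa"`.
#' @return Tibble: `ref_gene`, `ref_category`, `counterpart`,
#'   `counterpart_category` plus the printed location/ORF-length/exon
#'   columns.
#' @export
load_ortholog_pairs <- function(species = c("boleracea", "brapa")) {
  species <- match.arg(species)
  f <- if (species == "boleracea") "ortholog_pairs_at_bo.tsv"
       else "ortholog_pairs_at_br.tsv"
  x <- readr::read_tsv(nbs_example(f), show_col_types = FALSE)
  x %>%
    mutate(ref_category = assign_category(type_to_architecture(.data$ref_type)),
           counterpart_category =
             assign_category(type_to_architecture(.data$counterpart_type)))
}

# "TIR-NBS-LRR" -> "TNL" etc.: dash-separated domain names to token strings.
type_to_architecture <- function(type) {
  vapply(strsplit(type, "-(?=(TIR|CC|NBS|LRR))", perl = TRUE), function(parts) {
    paste(c(TIR = "T", CC = "C", NBS = "N", LRR = "L")[parts], collapse = "")
  }, character(1))
}

#' Published tandem duplication statistics
#'
#' @return Tibble with per-species totals, tandem gene/array counts,
#'   pre-split (common) tandem counts and anchoring columns.
#' @export
load_tandem_statistics <- function() {
  readr::read_tsv(nbs_example("tandem_statistics.tsv"),
                  show_col_types = FALSE)
}

#' Published cluster statistics
#'
#' @return Tibble: `species`, `genes_on_chromosomes`, `genes_in_clusters`,
#'   `clusters`.
#' @export
load_cluster_statistics <- function() {
  readr::read_tsv(nbs_example("cluster_statistics.tsv"),
                  show_col_types = FALSE)
}
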