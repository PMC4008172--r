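# Reading and writing the simulator's exchange formats: FASTA, GFF3 (one
# `gene` feature per locus), FPKM TSV, and truth tables.

#' Write a synthetic genome set to disk
#'
#' Emits, per species, `<species>/cds.fasta`, `<species>/proteins.fasta` and
#' `<species>/genes.gff3`; plus `expression.tsv` (FPKM, header row of tissue
#' names) and the truth tables as TSV under `truth/`.
#'
#' @param sim Result of [generate_genome_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$species)) {
    sdir <- file.path(dir, sp)
    dir.create(sdir, showWarnings = FALSE)
    g <- sim$species[[sp]]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$cds),
                                file.path(sdir, "cds.fasta"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(g$proteins),
                                file.path(sdir, "proteins.fasta"))
    write_gene_gff3(g$genes, file.path(sdir, "genes.gff3"))
  }
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], file.path(tdir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' One `gene` feature per locus, 1-based closed coordinates, `ID` attribute.
#'
#' @param genes Tibble with `gene_id`, `chromosome`, `strand`, `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tnbsfam_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chromosome, genes$start, genes$end,
                     genes$strand, genes$gene_id))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` features (1-based closed coordinates, `ID` attribute) and
#' assigns 0-based ranks by start position within each chromosome.
#'
#' @param path GFF3 file.
#' @return Tibble: `gene_id`, `chromosome`, `strand`, `start`, `end`, `rank`.
#' @export
read_gene_gff3 <- function(path) {
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- stringr::str_split_fixed(ln, "\t", 9)
  if (ncol(f) < 9) abort("malformed GFF3: expected 9 tab-separated columns.",
                         class = "nbsfam_input_error")
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  id <- stringr::str_match(f[, 9], "ID=([^;]+)")[, 2]
  if (anyNA(id)) abort("gene feature without ID attribute.",
                       class = "nbsfam_input_error")
  tibble(gene_id = id, chromosome = f[, 1], strand = f[, 7],
         start = as.integer(f[, 4]), end = as.integer(f[, 5])) %>%
    arrange(.data$chromosome, .data$start) %>%
    group_by(.data$chromosome) %>%
    mutate(rank = row_number() - 1L) %>%
    ungroup()
}

#' Read a protein or CDS FASTA as a named character vector
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read an FPKM expression matrix TSV
#'
#' First column is the gene id, remaining columns are tissues.
#'
#' @param path TSV file.
#' @return Tibble with `gene_id` plus one numeric column per tissue.
#' @export
read_fpkm_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "gene_id"
  x
}
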