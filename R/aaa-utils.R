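# Shared internal helpers: seed streams, input checks, codon bookkeeping.

# The 20 standard amino acids, and the subset treated as strongly hydrophobic
# by the heptad coiled-coil scorer.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_HYDROPHOBIC <- c("L", "I", "V", "M", "F")

# Stage-derived pseudo-random streams: every module stage draws from its own
# seed deduced from the master seed plus the stage name, so re-running one
# stage reproduces its output regardless of what ran before.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((abs(seed) * 7919 + h) %% 2147483399)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}

check_probability <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be probabilities in [0, 1].", what),
          class = "nbsfam_config_error")
  }
  invisible(x)
}

check_prob_vector <- function(x, what, tol = 1e-9) {
  check_probability(x, what)
  if (abs(sum(x) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (observed %.12f).", what, sum(x)),
          class = "nbsfam_config_error")
  }
  invisible(x)
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min),
          class = "nbsfam_config_error")
  }
  invisible(as.integer(x))
}

# Accept either a named character vector of sequences or a tibble with
# id/sequence columns; return the canonical two-column tibble.
as_seq_tbl <- function(x, id_col = "protein_id") {
  if (is.character(x)) {
    if (length(x) == 0) return(tibble(!!id_col := character(),
                                      sequence = character()))
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      abort("sequence vectors must be named by record id.")
    }
    return(tibble(!!id_col := names(x), sequence = unname(x)))
  }
  if (inherits(x, "XStringSet")) {
    return(tibble(!!id_col := names(x), sequence = as.character(x)))
  }
  x <- as_tibble(x)
  if (!all(c(id_col, "sequence") %in% names(x))) {
    abort(sprintf("expected columns `%s` and `sequence`.", id_col))
  }
  x[, c(id_col, "sequence")]
}

check_amino_acid <- function(seqs, ids) {
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]*$"), seqs)
  if (any(bad)) {
    abort(sprintf("non-amino-acid characters in record(s): %s",
                  paste(head(ids[bad], 5), collapse = ", ")),
          class = "nbsfam_input_error")
  }
  invisible(TRUE)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort(sprintf("sequence length %d is not a multiple of 3.", n),
          class = "nbsfam_input_error")
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

check_codon_clean <- function(seq, id = "sequence") {
  if (nchar(seq) == 0L) {
    abort(sprintf("`%s` is empty.", id), class = "nbsfam_input_error")
  }
  cods <- split_codons(seq)
  gc <- genetic_code()
  aa <- gc[cods]
  if (anyNA(aa)) {
    abort(sprintf("`%s` contains non-ACGT codon(s).", id),
          class = "nbsfam_input_error")
  }
  if (any(aa == "*")) {
    abort(sprintf("`%s` contains internal stop codon(s).", id),
          class = "nbsfam_input_error")
  }
  invisible(cods)
}

translate_cds <- function(seq) {
  paste(genetic_code()[split_codons(seq)], collapse = "")
}
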