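# Domain evidence: literal signature scanning, two-pass profile refinement,
# heptad coiled-coil scoring, consensus CC calls, and external hit import.

new_domain_hits <- function(protein_id = character(), domain = character(),
                            start = integer(), end = integer(),
                            score = numeric(), source = character()) {
  tibble(protein_id = protein_id, domain = domain,
         start = as.integer(start), end = as.integer(end),
         score = score, source = source)
}

assert_hit_coords <- function(hits, proteins) {
  if (nrow(hits) == 0) return(invisible(hits))
  lens <- setNames(nchar(proteins$sequence), proteins$protein_id)
  stopifnot(all(hits$start >= 1L), all(hits$start <= hits$end),
            all(hits$end <= lens[hits$protein_id]))
  invisible(hits)
}

# Sliding-window scores of one protein against a column-frequency matrix;
# returns best-window hits after merging overlap groups.
window_scan_one <- function(seq, freq, L, threshold) {
  n <- nchar(seq)
  if (n < L) return(NULL)
  ch <- strsplit(seq, "")[[1]]
  nw <- n - L + 1L
  idx <- matrix(match(ch[outer(seq_len(nw), 0:(L - 1L), "+")],
                      AA_ALPHABET20), nrow = nw)
  sc <- rowMeans(matrix(freq[cbind(as.vector(idx),
                                   rep(seq_len(L), each = nw))], nrow = nw))
  ok <- which(sc >= threshold)
  if (length(ok) == 0) return(NULL)
  grp <- cumsum(c(TRUE, diff(ok) >= L))
  best <- vapply(split(ok, grp), function(w) w[which.max(sc[w])], integer(1))
  list(start = best, score = sc[best])
}

signature_freq <- function(sig) {
  ch <- strsplit(sig, "")[[1]]
  freq <- matrix(0, length(AA_ALPHABET20), length(ch),
                 dimnames = list(AA_ALPHABET20, NULL))
  freq[cbind(match(ch, AA_ALPHABET20), seq_along(ch))] <- 1
  freq
}

#' Scan proteins for domain signatures
#'
#' Slides each signature along each protein and scores windows by identity
#' fraction; windows at or above `min_identity` are reported (overlapping
#' windows merged, best window kept), so a planted signature is found at its
#' exact coordinates with score 1 while moderately diverged copies are still
#' detected. This is the first pass of the two-pass search;
#' [refine_profile()] builds a position-frequency profile from the hits for
#' the second pass.
#'
#' @param proteins Named character vector, `AAStringSet`, or tibble with
#'   `protein_id` and `sequence`.
#' @param signatures Named character vector of signatures (names are domain
#'   labels, e.g. `NBS`, `TIR`, `LRR`); defaults to the built-in set minus
#'   `CC`, which is handled by the coiled-coil scorer.
#' @param min_identity Identity threshold in `[0, 1]` (default 0.6,
#'   calibrated so planted signatures score above it and shuffled sequence
#'   far below).
#' @return Domain-hit tibble: `protein_id`, `domain`, `start`, `end`,
#'   `score` (identity fraction), `source = "builtin_scan"`, ordered by
#'   protein and start.
#' @export
scan_domains <- function(proteins,
                         signatures = domain_signatures()[c("TIR", "NBS", "LRR")],
                         min_identity = 0.6) {
  prot <- as_seq_tbl(proteins)
  if (nrow(prot) == 0) return(new_domain_hits())
  check_amino_acid(prot$sequence, prot$protein_id)
  hits <- purrr::imap(signatures, function(sig, dom) {
    freq <- signature_freq(sig)
    L <- nchar(sig)
    purrr::map(seq_len(nrow(prot)), function(i) {
      h <- window_scan_one(prot$sequence[i], freq, L, min_identity)
      if (is.null(h)) return(NULL)
      new_domain_hits(protein_id = prot$protein_id[i], domain = dom,
                      start = h$start, end = h$start + L - 1L,
                      score = h$score, source = "builtin_scan")
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (nrow(hits) == 0) return(new_domain_hits())
  hits <- hits %>% arrange(.data$protein_id, .data$start, .data$domain)
  assert_hit_coords(hits, prot)
  hits
}

#' Refine a domain profile from first-pass hits
#'
#' Builds a position-wise residue-frequency model over the (equal-length)
#' subsequences of the seed hits, following the second-pass strategy of
#' rebuilding a genome-specific profile from first-pass matches. Only "high
#' quality" seeds -- score at or above the median first-pass score -- enter
#' the model. The rescanning threshold is set to the minimum profile score of
#' the retained seeds themselves, which guarantees the second pass recovers
#' every seed hit.
#'
#' @param seed_hits Domain-hit tibble for one domain (from [scan_domains()]
#'   or imported evidence).
#' @param proteins Protein sequences containing the hits.
#' @return An object of class `domain_profile`: list with the frequency
#'   `matrix` (20 x L), `consensus` string, `domain` label and scan
#'   `threshold`.
#' @export
refine_profile <- function(seed_hits, proteins) {
  prot <- as_seq_tbl(proteins)
  seed_hits <- as_tibble(seed_hits)
  if (nrow(seed_hits) < 2) {
    abort("profile refinement needs >= 2 seed hits.",
          class = "nbsfam_input_error")
  }
  if (length(unique(seed_hits$domain)) != 1) {
    abort("seed hits must all belong to one domain.",
          class = "nbsfam_input_error")
  }
  all_seqs <- setNames(prot$sequence, prot$protein_id)[seed_hits$protein_id]
  all_sub <- substr(all_seqs, seed_hits$start, seed_hits$end)
  L <- unique(nchar(all_sub))
  if (length(L) != 1) {
    abort("seed subsequences must share one length for columnwise alignment.",
          class = "nbsfam_input_error")
  }
  keep <- seed_hits$score >= stats::median(seed_hits$score)
  sub <- all_sub[keep]
  chars <- do.call(rbind, strsplit(sub, ""))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = AA_ALPHABET20))
    as.numeric(tab) / nrow(chars)
  }, numeric(length(AA_ALPHABET20)))
  rownames(freq) <- AA_ALPHABET20
  consensus <- paste(AA_ALPHABET20[apply(freq, 2, which.max)], collapse = "")
  # threshold at the weakest seed's own profile score so the second pass
  # recovers every first-pass hit
  self_scores <- vapply(all_sub, function(s) {
    mean(freq[cbind(match(strsplit(s, "")[[1]], AA_ALPHABET20), seq_len(L))])
  }, numeric(1))
  structure(list(matrix = freq, consensus = consensus,
                 domain = seed_hits$domain[1], width = L,
                 threshold = min(self_scores)),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %s, width %d, threshold %.3f\n  consensus: %s\n",
              x$domain, x$width, x$threshold, x$consensus))
  invisible(x)
}

#' Scan proteins with a refined profile
#'
#' Slides the profile across each protein; a window scores the mean column
#' frequency of its residues. Windows at or above the profile threshold are
#' reported; overlapping windows are merged and the best-scoring window of
#' each overlap group is emitted.
#'
#' @param proteins Protein sequences.
#' @param profile A [refine_profile()] result.
#' @param threshold Scan threshold; defaults to the profile's own.
#' @return Domain-hit tibble with `source = "profile_scan"`.
#' @export
scan_profile <- function(proteins, profile, threshold = profile$threshold) {
  stopifnot(inherits(profile, "domain_profile"))
  prot <- as_seq_tbl(proteins)
  if (nrow(prot) == 0) return(new_domain_hits())
  check_amino_acid(prot$sequence, prot$protein_id)
  L <- profile$width
  hits <- purrr::map(seq_len(nrow(prot)), function(i) {
    h <- window_scan_one(prot$sequence[i], profile$matrix, L, threshold)
    if (is.null(h)) return(NULL)
    new_domain_hits(protein_id = prot$protein_id[i], domain = profile$domain,
                    start = h$start, end = h$start + L - 1L, score = h$score,
                    source = "profile_scan")
  }) %>% bind_rows()
  if (nrow(hits) == 0) return(new_domain_hits())
  hits <- hits %>% arrange(.data$protein_id, .data$start)
  assert_hit_coords(hits, prot)
  hits
}

#' Two-pass domain search
#'
#' First pass: literal signature scan. Second pass: profile refined from the
#' first-pass hits, rescanned over all proteins. The second-pass hit set is a
#' superset of the first on the same input.
#'
#' @inheritParams scan_domains
#' @return Domain-hit tibble from the second pass (first pass if a domain has
#'   fewer than 2 seeds).
#' @export
scan_domains_two_pass <- function(proteins,
                                  signatures = domain_signatures()[c("TIR", "NBS", "LRR")]) {
  first <- scan_domains(proteins, signatures)
  out <- purrr::map(names(signatures), function(dom) {
    seeds <- first %>% filter(.data$domain == dom)
    if (nrow(seeds) < 2) return(seeds)
    scan_profile(proteins, refine_profile(seeds, proteins))
  }) %>% bind_rows()
  if (nrow(out) == 0) return(new_domain_hits())
  out %>% arrange(.data$protein_id, .data$start, .data$domain)
}

#' Heptad-periodicity coiled-coil score
#'
#' Slides a 28-residue window over the protein; for each of the 7 heptad
#' frames the window is scored as the fraction of `a`/`d` positions occupied
#' by strongly hydrophobic residues (L, I, V, M, F) minus the hydrophobic
#' fraction elsewhere in the window. The best frame's score, clamped to
#' `[0, 1]`, is the window's pseudo-probability. Windows at or above
#' `emit_floor` are merged into segments.
#'
#' @param proteins Protein sequences.
#' @param window Window width in residues (default 28 = four heptads).
#' @param emit_floor Minimum window probability for a segment to be emitted.
#' @param predictor Label recorded on the prediction.
#' @return A `cc_prediction` tibble: `protein_id`, `start`, `end`,
#'   `probability`, `predictor`, with attribute `scale = "probability"`.
#' @export
builtin_cc_score <- function(proteins, window = 28L, emit_floor = 0.5,
                             predictor = "builtin_heptad") {
  prot <- as_seq_tbl(proteins)
  if (nrow(prot) > 0) check_amino_acid(prot$sequence, prot$protein_id)
  segs <- purrr::map(seq_len(nrow(prot)), function(i) {
    s <- prot$sequence[i]
    n <- nchar(s)
    if (n < window) return(NULL)
    hyd <- as.integer(strsplit(s, "")[[1]] %in% AA_HYDROPHOBIC)
    nw <- n - window + 1L
    probs <- vapply(seq_len(nw), function(w) {
      win <- hyd[w:(w + window - 1L)]
      best <- 0
      for (f in 0:6) {
        hep <- (seq_len(window) - 1L + f) %% 7L
        ad <- hep == 0L | hep == 3L
        sc <- mean(win[ad]) - mean(win[!ad])
        if (sc > best) best <- sc
      }
      min(1, max(0, best))
    }, numeric(1))
    ok <- which(probs >= emit_floor)
    if (length(ok) == 0) return(NULL)
    grp <- cumsum(c(TRUE, diff(ok) > 1L))
    purrr::map(split(ok, grp), function(w) {
      tibble(protein_id = prot$protein_id[i], start = min(w),
             end = max(w) + window - 1L, probability = max(probs[w]),
             predictor = predictor)
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (nrow(segs) == 0) {
    segs <- tibble(protein_id = character(), start = integer(),
                   end = integer(), probability = numeric(),
                   predictor = character())
  }
  structure(segs, scale = "probability", class = c("cc_prediction",
                                                   class(segs)))
}

#' Read external coiled-coil predictions
#'
#' TSV with columns `protein_id`, `start`, `end`, `probability`, `predictor`.
#' `scale = "pscore"` marks predictors whose scores are P-values (lower is
#' better, e.g. a 0.025 cutoff); `"probability"` marks higher-is-better
#' probabilities (e.g. a 0.90 cutoff).
#'
#' @param path TSV file.
#' @param scale `"probability"` or `"pscore"`.
#' @return A `cc_prediction` tibble.
#' @export
read_cc_predictions <- function(path, scale = c("probability", "pscore")) {
  scale <- match.arg(scale)
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         protein_id = "c", start = "i", end = "i",
                         probability = "d", predictor = "c"))
  check_probability(x$probability, "probability")
  structure(x, scale = scale, class = c("cc_prediction", class(x)))
}

cc_pass <- function(pred, cutoff) {
  scale <- attr(pred, "scale") %||% "probability"
  if (is.null(cutoff)) cutoff <- if (scale == "pscore") 0.025 else 0.90
  if (scale == "pscore") pred[pred$probability <= cutoff, , drop = FALSE]
  else pred[pred$probability >= cutoff, , drop = FALSE]
}

#' Consensus coiled-coil call from two predictors
#'
#' Emits a CC domain hit for each region where a segment passing the first
#' predictor's threshold overlaps (by at least one residue) a segment passing
#' the second predictor's threshold; the emitted interval is the
#' intersection. The operation is symmetric in its two arguments.
#'
#' @param pred_a,pred_b `cc_prediction` tibbles (see [builtin_cc_score()],
#'   [read_cc_predictions()]). Each prediction carries its own score scale;
#'   P-score scales use `<= cutoff`, probability scales `>= cutoff`.
#' @param cutoff_a,cutoff_b Optional threshold overrides; defaults are 0.025
#'   for P-score scales and 0.90 for probability scales.
#' @return Domain-hit tibble with `domain = "CC"`,
#'   `source = "cc_consensus"`; score is the mean of the two segment scores
#'   mapped to a probability scale.
#' @export
consensus_coiled_coil <- function(pred_a, pred_b, cutoff_a = NULL,
                                  cutoff_b = NULL) {
  a <- cc_pass(pred_a, cutoff_a)
  b <- cc_pass(pred_b, cutoff_b)
  if (nrow(a) == 0 || nrow(b) == 0) return(new_domain_hits())
  ids_a <- unique(pred_a$protein_id)
  ids_b <- unique(pred_b$protein_id)
  if (length(intersect(ids_a, ids_b)) == 0 &&
      length(ids_a) > 0 && length(ids_b) > 0) {
    abort("predictions refer to disjoint protein sets; check protein IDs.",
          class = "nbsfam_input_error")
  }
  pa <- if (identical(attr(pred_a, "scale"), "pscore"))
    1 - a$probability else a$probability
  pb <- if (identical(attr(pred_b, "scale"), "pscore"))
    1 - b$probability else b$probability
  a$p_ <- pa; b$p_ <- pb
  j <- inner_join(as_tibble(a), as_tibble(b), by = "protein_id",
                  suffix = c("_a", "_b"), relationship = "many-to-many") %>%
    mutate(start = pmax(.data$start_a, .data$start_b),
           end = pmin(.data$end_a, .data$end_b)) %>%
    filter(.data$start <= .data$end)
  if (nrow(j) == 0) return(new_domain_hits())
  j %>%
    transmute(protein_id = .data$protein_id, domain = "CC",
              start = as.integer(.data$start), end = as.integer(.data$end),
              score = (.data$p__a + .data$p__b) / 2,
              source = "cc_consensus") %>%
    distinct() %>%
    arrange(.data$protein_id, .data$start)
}

#' Import domain hits from an HMMER3 domtblout table
#'
#' Whitespace-delimited per-domain hit table with `#` comment lines; columns
#' follow the HMMER3 `--domtblout` layout (target name in column 1, query
#' profile name in column 4, bit score in column 14, envelope coordinates in
#' columns 20-21).
#'
#' @param path File path.
#' @param domain_map Named vector translating query profile names to domain
#'   labels (e.g. `c(PF00931 = "NBS", PF01582 = "TIR")`); profiles not in the
#'   map keep their own name.
#' @return Domain-hit tibble with `source = "imported"`.
#' @export
read_domtblout <- function(path, domain_map = c(PF00931 = "NBS",
                                                PF01582 = "TIR")) {
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0) return(new_domain_hits())
  f <- strsplit(trimws(ln), "\\s+")
  bad <- which(lengths(f) < 21)
  if (length(bad) > 0) {
    abort(sprintf("domtblout line %d has fewer than 21 fields.", bad[1]),
          class = "nbsfam_input_error")
  }
  f <- do.call(rbind, lapply(f, `[`, 1:23))
  dom <- f[, 4]
  mapped <- ifelse(dom %in% names(domain_map), domain_map[dom], dom)
  new_domain_hits(protein_id = f[, 1], domain = unname(mapped),
                  start = as.integer(f[, 20]), end = as.integer(f[, 21]),
                  score = as.numeric(f[, 14]), source = "imported") %>%
    arrange(.data$protein_id, .data$start)
}
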