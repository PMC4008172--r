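# Simulation configuration for the synthetic multi-species genome generator.

#' Configure a synthetic genome simulation
#'
#' Builds a validated configuration for [generate_genome_set()] and the lower
#' level generator stages. The defaults emulate the study system the package
#' targets: an ancestral crucifer-like genome whose NBS-encoding gene family
#' follows the *B. oleracea* census proportions, a whole-genome triplication
#' into two descendant lineages with heavy fractionation, codon divergence at
#' the synonymous distance separating *Arabidopsis* from *Brassica*, and
#' lineage dN/dS set to the printed CNL lineage means.
#'
#' @param seed Master seed; every stage derives its own stream from it, so a
#'   fixed seed makes all outputs bit-identical across runs.
#' @param n_chromosomes,n_genes_per_chromosome Ancestral genome shape.
#' @param nbs_fraction Probability that a background gene is an NBS-family
#'   gene (planted tandem arrays add further family genes).
#' @param architecture_mix Named probabilities over architecture strings built
#'   from tokens `T` (TIR), `C` (CC), `N` (NBS), `L` (LRR); must sum to 1.
#' @param tandem_array_spec Tibble or data frame with columns `len` (array
#'   size, >= 2) and `epoch` (`"pre_split"` arrays are planted in the
#'   ancestor before triplication; `"species_specific"` arrays are planted in
#'   one descendant after fractionation).
#' @param retention_probs Length-3 probabilities of keeping 1, 2 or 3
#'   triplicated copies, conditional on the gene not being lost; sums to 1.
#' @param loss_prob Probability a triplicated gene leaves no descendant copy.
#' @param keep_tandem_arrays If `TRUE` (default), members of pre-split planted
#'   arrays always retain at least the first-subgenome copy so planted arrays
#'   survive into every descendant.
#' @param omega_per_lineage Named dN/dS acceptance ratios, one per descendant
#'   lineage; the names define the lineages simulated.
#' @param ks_target_per_lineage Expected synonymous divergence per lineage
#'   (substitutions per synonymous site); names must match
#'   `omega_per_lineage`.
#' @param expression_tissues Tissue names for the simulated FPKM matrix.
#' @param expression_divergence Named dials in `[0, 2]` for `ortholog` and
#'   `paralog` pairs: the expected `1 - Pearson` divergence built into each
#'   pair's profiles.
#' @param expression_noise_sd Per-tissue log2-scale measurement noise.
#' @param protein_len_range Length range (amino acids) for background,
#'   non-family proteins.
#' @param tandem_ks Extra synonymous divergence applied to tandem-duplicate
#'   copies relative to their seed copy (tandem duplicates are young, so
#'   this is small; default 0.05).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_chromosomes = 2,
#'                          n_genes_per_chromosome = 30)
#' cfg$retention_probs
simulation_config <- function(seed = 1L,
                              n_chromosomes = 5L,
                              n_genes_per_chromosome = 120L,
                              nbs_fraction = 0.12,
                              architecture_mix = c(TNL = 0.17, CNL = 0.03,
                                                   NL = 0.10, TN = 0.12,
                                                   CN = 0.02, N = 0.22,
                                                   T = 0.34),
                              tandem_array_spec = tibble(
                                len = c(3L, 2L, 2L, 4L, 2L),
                                epoch = c("pre_split", "pre_split",
                                          "species_specific",
                                          "species_specific",
                                          "species_specific")),
                              retention_probs = c(0.80, 0.15, 0.05),
                              loss_prob = 0.65,
                              keep_tandem_arrays = TRUE,
                              omega_per_lineage = c(lineage_a = 0.497,
                                                    lineage_b = 0.235),
                              ks_target_per_lineage = c(lineage_a = 0.45,
                                                        lineage_b = 0.45),
                              expression_tissues = c("root", "stalk", "leaf",
                                                     "flower", "silique",
                                                     "callus"),
                              expression_divergence = c(ortholog = 0.3,
                                                        paralog = 0.8),
                              expression_noise_sd = 0.25,
                              protein_len_range = c(150L, 450L),
                              tandem_ks = 0.05) {
  check_count(seed, "seed", min = 0L)
  check_count(n_chromosomes, "n_chromosomes")
  check_count(n_genes_per_chromosome, "n_genes_per_chromosome")
  check_probability(nbs_fraction, "nbs_fraction")
  if (is.null(names(architecture_mix)) || any(names(architecture_mix) == "")) {
    abort("`architecture_mix` must be a named probability vector.",
          class = "nbsfam_config_error")
  }
  if (any(!strsplit(paste(names(architecture_mix), collapse = ""), "")[[1]] %in%
          c("T", "C", "N", "L"))) {
    abort("architecture strings may only use tokens T, C, N, L.",
          class = "nbsfam_config_error")
  }
  check_prob_vector(architecture_mix, "architecture_mix")
  tandem_array_spec <- as_tibble(tandem_array_spec)
  if (nrow(tandem_array_spec) > 0) {
    stopifnot(all(c("len", "epoch") %in% names(tandem_array_spec)))
    if (any(tandem_array_spec$len < 2)) {
      abort("tandem arrays must have length >= 2.",
            class = "nbsfam_config_error")
    }
    if (!all(tandem_array_spec$epoch %in% c("pre_split", "species_specific"))) {
      abort("tandem epoch must be 'pre_split' or 'species_specific'.",
            class = "nbsfam_config_error")
    }
  }
  if (length(retention_probs) != 3L) {
    abort("`retention_probs` must have length 3 (P(1), P(2), P(3) copies).",
          class = "nbsfam_config_error")
  }
  check_prob_vector(retention_probs, "retention_probs")
  check_probability(loss_prob, "loss_prob")
  if (is.null(names(omega_per_lineage)) || length(omega_per_lineage) < 1L) {
    abort("`omega_per_lineage` must be a named vector.",
          class = "nbsfam_config_error")
  }
  if (any(omega_per_lineage < 0)) {
    abort("omega must be >= 0.", class = "nbsfam_config_error")
  }
  if (!setequal(names(omega_per_lineage), names(ks_target_per_lineage))) {
    abort("lineage names of omega and ks_target must match.",
          class = "nbsfam_config_error")
  }
  if (any(ks_target_per_lineage < 0)) {
    abort("ks_target must be >= 0.", class = "nbsfam_config_error")
  }
  if (!all(names(expression_divergence) %in% c("ortholog", "paralog")) ||
      any(expression_divergence < 0) || any(expression_divergence > 2)) {
    abort("`expression_divergence` must name ortholog/paralog dials in [0, 2].",
          class = "nbsfam_config_error")
  }
  stopifnot(length(expression_tissues) >= 2, expression_noise_sd >= 0,
            length(protein_len_range) == 2, protein_len_range[1] >= 30,
            tandem_ks >= 0)

  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    n_genes_per_chromosome = as.integer(n_genes_per_chromosome),
    nbs_fraction = nbs_fraction,
    architecture_mix = architecture_mix,
    tandem_array_spec = tandem_array_spec,
    retention_probs = retention_probs,
    loss_prob = loss_prob,
    keep_tandem_arrays = isTRUE(keep_tandem_arrays),
    omega_per_lineage = omega_per_lineage,
    ks_target_per_lineage = ks_target_per_lineage[names(omega_per_lineage)],
    expression_tissues = expression_tissues,
    expression_divergence = expression_divergence,
    expression_noise_sd = expression_noise_sd,
    protein_len_range = as.integer(protein_len_range),
    tandem_ks = tandem_ks
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %d genes, NBS fraction %.2f\n",
              x$n_chromosomes, x$n_genes_per_chromosome, x$nbs_fraction))
  cat(sprintf("  lineages: %s\n",
              paste(sprintf("%s (omega %.3g, Ks %.3g)",
                            names(x$omega_per_lineage), x$omega_per_lineage,
                            x$ks_target_per_lineage), collapse = ", ")))
  cat(sprintf("  retention: loss %.2f, copy probs (%s)\n", x$loss_prob,
              paste(format(x$retention_probs), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
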