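# Domain evidence: signature scanning, profile refinement, coiled-coil
# scoring and consensus, external table import.

sig <- domain_signatures()
spacer <- function(n) substr(strrep("GS", ceiling(n / 2)), 1, n)

test_that("signature scanning finds planted signatures at their coordinates", {
  expect_equal(nrow(scan_domains(character(0))), 0)

  p1 <- paste0(spacer(20), sig[["NBS"]], spacer(15))
  hits <- scan_domains(c(prot1 = p1))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$domain, "NBS")
  expect_equal(hits$start, 21L)
  expect_equal(hits$end, 20L + nchar(sig[["NBS"]]))
  expect_equal(hits$score, 1)

  p2 <- paste0(spacer(10), sig[["TIR"]], spacer(12), sig[["NBS"]], spacer(8))
  hits2 <- scan_domains(c(prot2 = p2))
  expect_equal(hits2$domain, c("TIR", "NBS"))
  expect_true(hits2$start[1] < hits2$start[2])

  expect_error(scan_domains(c(bad = "MKV123")),
               class = "nbsfam_input_error")
  expect_error(scan_domains(c(bad = "MKVX")), "bad")
})

test_that("all emitted hit coordinates lie within their protein", {
  sim <- noiseless_sim()
  prot <- sim$species$lineage_a$proteins
  hits <- scan_domains_two_pass(prot)
  lens <- setNames(nchar(prot), names(prot))
  expect_true(all(hits$start >= 1))
  expect_true(all(hits$start <= hits$end))
  expect_true(all(hits$end <= lens[hits$protein_id]))
})

test_that("profile refinement is consensus-forming, superset-safe and idempotent", {
  prot <- c(a = paste0(spacer(10), sig[["NBS"]], spacer(10)),
            b = paste0(spacer(24), sig[["NBS"]], spacer(6)))
  seeds <- scan_domains(prot)
  expect_error(refine_profile(seeds[1, ], prot), class = "nbsfam_input_error")

  prof <- refine_profile(seeds, prot)
  expect_s3_class(prof, "domain_profile")
  expect_equal(prof$consensus, sig[["NBS"]])

  # a divergent decoy still leaves the consensus at >= 90% of majority columns
  decoy <- sig[["NBS"]]
  substr(decoy, 3, 6) <- "WWWW"
  prot_d <- c(prot, d = paste0(spacer(8), decoy, spacer(8)))
  seeds_d <- scan_domains(prot_d)
  expect_equal(nrow(seeds_d), 3)
  prof_d <- refine_profile(seeds_d, prot_d)
  agree <- mean(strsplit(prof_d$consensus, "")[[1]] ==
                  strsplit(sig[["NBS"]], "")[[1]])
  expect_gte(agree, 0.9)

  # on the synthetic genome: pass 2 is a superset of pass 1, pass 3 = pass 2
  sim <- noiseless_sim()
  p <- sim$species$ancestor$proteins
  first <- scan_domains(p)
  for (dom in unique(first$domain)) {
    seeds1 <- dplyr::filter(first, domain == dom)
    second <- scan_profile(p, refine_profile(seeds1, p))
    expect_gte(nrow(second), nrow(seeds1))
    missed <- dplyr::anti_join(seeds1, second,
                               by = c("protein_id", "start", "end"))
    expect_equal(nrow(missed), 0)
    third <- scan_profile(p, refine_profile(second, p))
    expect_equal(third[, c("protein_id", "start", "end")],
                 second[, c("protein_id", "start", "end")])
  }
})

test_that("heptad scorer flags ideal coiled coils and nothing else", {
  expect_equal(nrow(builtin_cc_score(c(x = ""))), 0)
  expect_equal(nrow(builtin_cc_score(c(x = strrep("P", 100)))), 0)

  ideal <- strrep("LEELKEK", 8)  # 56 residues
  ccp <- builtin_cc_score(c(x = ideal))
  expect_equal(nrow(ccp), 1)
  expect_gte(ccp$end - ccp$start + 1, 28)
  expect_gte(ccp$probability, 0.9)
})

test_that("coiled-coil consensus is an interval intersection and symmetric", {
  mk <- function(start, end, p, scale = "probability") {
    structure(tibble::tibble(protein_id = "p1", start = start, end = end,
                             probability = p, predictor = "t"),
              scale = scale, class = c("cc_prediction", "tbl_df", "tbl",
                                       "data.frame"))
  }
  a <- mk(10L, 40L, 0.95)
  b <- mk(30L, 60L, 0.97)
  hit <- consensus_coiled_coil(a, b)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(30L, 40L))
  expect_equal(hit$domain, "CC")

  # consensus requires both predictors
  none <- mk(30L, 60L, 0.2)
  expect_equal(nrow(consensus_coiled_coil(a, none)), 0)

  # symmetry
  h1 <- consensus_coiled_coil(a, b)
  h2 <- consensus_coiled_coil(b, a)
  expect_equal(h1[, c("start", "end", "score")],
               h2[, c("start", "end", "score")])

  # P-score predictors pass with <= threshold
  ap <- mk(10L, 40L, 0.01, scale = "pscore")
  expect_equal(nrow(consensus_coiled_coil(ap, b)), 1)
  ap_fail <- mk(10L, 40L, 0.5, scale = "pscore")
  expect_equal(nrow(consensus_coiled_coil(ap_fail, b)), 0)

  # disjoint protein sets are an input error
  b_other <- mk(30L, 60L, 0.97)
  b_other$protein_id <- "p2"
  expect_error(consensus_coiled_coil(a, b_other),
               class = "nbsfam_input_error")

  # end-to-end positive control: the heptad scorer on an ideal repeat as
  # both predictors yields one CC hit covering the repeat
  ideal <- paste0(spacer(12), strrep("LEELKEK", 4), spacer(12))
  pred <- builtin_cc_score(c(cc1 = ideal))
  hit2 <- consensus_coiled_coil(pred, pred)
  expect_equal(nrow(hit2), 1)
  expect_gte(hit2$end - hit2$start + 1, 28)
})

test_that("external evidence tables import correctly", {
  f <- tempfile(fileext = ".domtblout")
  writeLines(c(
    "# comment line",
    paste("geneA - 500 PF00931 - 120 1e-30 80.5 0.1 1 1 1e-28 1e-30 75.2",
          "0.1 1 120 22 118 20 120 0.95 -"),
    paste("geneB - 300 PF01582 - 90 1e-12 40.1 0.1 1 1 1e-11 1e-12 39.0",
          "0.1 1 90 14 98 12 100 0.90 -")), f)
  hits <- read_domtblout(f)
  expect_equal(hits$protein_id, c("geneA", "geneB"))
  expect_equal(hits$domain, c("NBS", "TIR"))
  expect_equal(hits$start, c(20L, 12L))
  expect_equal(hits$end, c(120L, 100L))
  expect_equal(hits$source, c("imported", "imported"))

  bad <- tempfile()
  writeLines("geneA PF00931 10", bad)
  expect_error(read_domtblout(bad), class = "nbsfam_input_error")

  # CC prediction TSV round-trip
  cc_f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(protein_id = "p1", start = 5L, end = 40L,
                                  probability = 0.02, predictor = "ext"),
                   cc_f)
  cc <- read_cc_predictions(cc_f, scale = "pscore")
  expect_equal(attr(cc, "scale"), "pscore")
  expect_equal(nrow(cc), 1)
})
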