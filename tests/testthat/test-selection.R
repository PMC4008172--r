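# Codon alignment, NG86 Ka/Ks, Mann-Whitney comparison, branch-result import.

test_that("codon alignment back-maps protein alignments to codons", {
  al <- align_codons("TTTGCTAAA", "TTTGCTAAA")
  expect_equal(al$codons_a, c("TTT", "GCT", "AAA"))
  expect_equal(al$codons_b, al$codons_a)

  # one inserted codon produces exactly one 3-nt gap
  a <- "ATGGATTGGCCTAAGCGTGAA"        # M D W P K R E
  b <- "ATGGATTGGTACCCTAAGCGTGAA"     # M D W Y P K R E
  al2 <- align_codons(a, b)
  expect_equal(sum(al2$codons_a == "---"), 1)
  expect_equal(sum(al2$codons_b == "---"), 0)
  expect_equal(length(al2$codons_b), 8)

  expect_error(align_codons("", "ATG"), class = "nbsfam_input_error")
  expect_error(align_codons("ATGTAAGCT", "ATGGCTGCT"),
               class = "nbsfam_input_error")  # internal stop, named
  expect_error(align_codons("ATGT", "ATG"), class = "nbsfam_input_error")
})

test_that("NG86 reproduces the hand-counted examples", {
  r0 <- compute_kaks_ng86(align_codons("TTTGCTAAA", "TTTGCTAAA"))
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(is.na(r0$ka_ks))

  # TTT GCT AAA vs TTC GCT AAA: one synonymous third-position change;
  # per-codon synonymous sites 1/3 + 1 + 1/3
  r1 <- compute_kaks_ng86(align_codons("TTTGCTAAA", "TTCGCTAAA"))
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$S, 5 / 3, tolerance = 1e-12)
  expect_equal(r1$ka, 0)
  expect_equal(r1$ks, -0.75 * log(1 - (4 / 3) * (3 / 5)), tolerance = 1e-12)
  expect_equal(r1$S + r1$N, 9, tolerance = 1e-6)

  # TTT -> TTA (Phe -> Leu): nonsynonymous
  r2 <- compute_kaks_ng86(align_codons("TTTGCTAAA", "TTAGCTAAA"))
  expect_equal(r2$Nd, 1)
  expect_equal(r2$Sd, 0)
  expect_equal(r2$ks, 0)
  expect_gt(r2$ka, 0)
})

test_that("NG86 equals the pathway-enumeration oracle on random codon pairs", {
  set.seed(11)
  n_done <- 0
  while (n_done < 100) {
    ca <- random_sense_codons(10)
    cb <- mutate_codons(ca, p = 0.4)
    o <- oracle_ng86(ca, cb)
    if (!is.finite(o$ks) || !is.finite(o$ka)) next
    r <- compute_kaks_ng86(list(codons_a = ca, codons_b = cb))
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
    expect_equal(r$ka, o$ka, tolerance = 1e-9)
    expect_equal(r$ks, o$ks, tolerance = 1e-9)
    n_done <- n_done + 1
  }
})

test_that("saturated alignments raise a saturation error", {
  # force ps >= 0.75: many synonymous third-position differences in
  # four-fold codons
  ca <- rep("GGT", 12)
  cb <- rep(c("GGA", "GGC", "GGG"), 4)
  expect_error(compute_kaks_ng86(list(codons_a = ca, codons_b = cb)),
               class = "nbsfam_saturation_error")
  expect_error(compute_kaks_ng86(list(codons_a = "---", codons_b = "GGT")),
               class = "nbsfam_input_error")
})

test_that("the Mann-Whitney comparison matches enumeration and the printed contrast", {
  cmp <- compare_lineages(
    tibble::tibble(g = rep(c("x", "y"), each = 3), v = c(1, 2, 3, 4, 5, 6)),
    "g", "v")
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_value, 0.1)

  same <- compare_lineages(
    tibble::tibble(g = c("x", "y"), v = c(5, 5)), "g", "v")
  expect_equal(same$p_value, 1)

  expect_error(compare_lineages(
    tibble::tibble(g = c("x", "x"), v = c(1, 2)), "g", "v"),
    class = "nbsfam_input_error")

  # exact p equals full enumeration for all group sizes <= 6
  set.seed(5)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    vals <- sample(seq(0.1, 9.9, by = 0.1), nx + ny)  # no ties
    dat <- tibble::tibble(g = rep(c("x", "y"), c(nx, ny)), v = vals)
    cmp <- compare_lineages(dat, "g", "v")
    expect_equal(cmp$p_value, oracle_mw_p(vals[1:nx], vals[-(1:nx)]),
                 tolerance = 1e-12)
  }

  # printed group means: relative excess of 0.497 over 0.235
  expect_equal(round(relative_excess_pct(0.497, 0.235), 2), 52.72)
})

test_that("tidy, glance and autoplot expose the comparison", {
  dat <- tibble::tibble(g = rep(c("x", "y"), each = 5),
                        v = c(rnorm(5, 1), rnorm(5, 2)))
  cmp <- compare_lineages(dat, "g", "v")
  td <- tidy(cmp)
  expect_equal(td$group, c("x", "y"))
  gl <- glance(cmp)
  expect_true(all(c("U", "p_value", "relative_excess_pct") %in% names(gl)))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("external branch-model results round-trip", {
  f <- tempfile()
  writeLines(c(
    " branch          t       N       S   dN/dS      dN      dS",
    "  6..7       0.102   501.2   145.8  0.2510  0.0121  0.0482",
    "  7..1       0.201   501.2   145.8  0.4970  0.0300  0.0604",
    "  7..2       0.150   501.2   145.8  0.2350  0.0140  0.0596"), f)
  br <- read_branch_results(f)
  expect_equal(nrow(br), 3)
  expect_equal(br$omega, c(0.2510, 0.4970, 0.2350))
  expect_equal(br$branch[1], "6..7")

  f1 <- tempfile()
  writeLines("  9..3  0.1  10  5  1.0  0.01  0.01", f1)
  expect_equal(nrow(read_branch_results(f1)), 1)

  f2 <- tempfile()
  writeLines("", f2)
  expect_error(read_branch_results(f2), class = "nbsfam_parse_error")

  f3 <- tempfile()
  writeLines(c("  6..7  0.1  10  5  1.0  0.01  0.01",
               "  6..8  oops"), f3)
  expect_error(read_branch_results(f3), "line 2",
               class = "nbsfam_parse_error")
})

test_that("kaks over pair tables carries annotations and drops failures", {
  cds <- c(g1 = "ATGGCTAAGGGTTTGCGTACTGAAGATCCA",
           g2 = "ATGGCTAAAGGTTTGCGTACTGAAGATCCA",
           g3 = "ATGTCTGCTGCTAAGCGTGAAGGTATCACT")
  pairs <- tibble::tibble(gene_a = c("g1", "g1"), gene_b = c("g2", "gX"),
                          lineage = "l1")
  expect_warning(res <- compute_kaks_pairs(pairs, cds), "dropped")
  expect_equal(nrow(res), 1)
  expect_equal(res$lineage, "l1")
  expect_true(res$Sd > 0 || res$Nd > 0)
})
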