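test_that("codon counting pools complete codons and tallies stops apart", {
  cu <- codon_counts(c(g1 = "ATGTTTTTTTAA"))
  expect_identical(cu$codon_counts[["ATG"]], 1L)
  expect_identical(cu$codon_counts[["TTT"]], 2L)
  expect_identical(cu$codon_counts[["TAA"]], 0L)  # stop kept separate
  expect_identical(cu$stop_counts[["TAA"]], 1L)
  # trailing T excluded from codon counts, recorded as incomplete stop
  cu2 <- codon_counts(c(g1 = "ATGAAAT"))
  expect_identical(sum(cu2$codon_counts), 2L)
  expect_identical(cu2$incomplete[["g1"]], "T-")
  # additivity over CDSs
  a <- codon_counts(c(x = "ATGTTTTAA"))
  b <- codon_counts(c(y = "ATGCCCTAA"))
  both <- codon_counts(c(x = "ATGTTTTAA", y = "ATGCCCTAA"))
  expect_identical(both$codon_counts, a$codon_counts + b$codon_counts)
  # internal stop: gene skipped, error collected, run continues
  cu3 <- codon_counts(c(bad = "ATGTAATTTAAA", ok = "ATGTTTTAA"))
  expect_match(cu3$errors[["bad"]], "internal stop")
  expect_identical(cu3$codon_counts[["TTT"]], 1L)
})

test_that("RSCU equals count x family size / family total", {
  cu <- codon_counts(c(g = "ATGTTTTTTTTTTTCTAA"))  # TTT x3, TTC x1
  r <- rscu(cu)
  expect_equal(r[["TTT"]], 1.5)
  expect_equal(r[["TTC"]], 0.5)
  # uniform usage in the 4-fold Val family -> all 1
  cu2 <- codon_counts(c(g = "ATGGTTGTCGTAGTGTAA"))
  expect_equal(unname(rscu(cu2)[c("GTT", "GTC", "GTA", "GTG")]),
               rep(1, 4))
  # 2-fold family used 100% one codon -> 2 and 0
  cu3 <- codon_counts(c(g = "ATGTTTTTTTAA"))
  expect_equal(rscu(cu3)[["TTT"]], 2)
  expect_equal(rscu(cu3)[["TTC"]], 0)
})

test_that("RSCU sums to family size and is scale-invariant", {
  fx <- get_fixture()
  cu <- codon_counts(fx$genomes[[2]])
  r <- rscu(cu)
  fam <- cu$families
  for (f in unique(fam)) {
    members <- names(fam)[fam == f]
    if (cu$aa_counts[[f]] > 0)
      expect_equal(sum(r[members]), length(members), tolerance = 1e-12)
  }
  # scaling all counts leaves RSCU unchanged
  cu5 <- cu
  cu5$codon_counts <- cu5$codon_counts * 5L
  expect_equal(rscu(cu5), r)
  # family bookkeeping: aa_counts total = sense codon total
  expect_identical(sum(cu$aa_counts),
                   sum(cu$codon_counts[names(cu$families)]))
})

test_that("Leu and Ser are split into two synonymous families", {
  code <- genetic_code(5)
  expect_identical(unname(code$families[c("CTT", "CTA")]),
                   c("Leu1", "Leu1"))
  expect_identical(unname(code$families[c("TTA", "TTG")]),
                   c("Leu2", "Leu2"))
  expect_identical(unname(code$families[c("AGA", "AGC")]),
                   c("Ser1", "Ser1"))
  expect_identical(unname(code$families[["TCT"]]), "Ser2")
  expect_identical(length(unique(code$families)), 22L)
})

test_that("start/stop classification covers ATN, TTG and incomplete stops", {
  g <- toy_genome()
  ss <- start_stop_table(list(g))
  expect_identical(ss$start_class, "ATN")
  expect_identical(ss$stop_class, "TAA")
  fx <- get_fixture()
  ss <- start_stop_table(fx$genomes)
  # the generator writes ATN starts; drift along the tree may turn a few
  # into the alternative starts seen in real insect mitogenomes
  expect_gt(mean(ss$start_class == "ATN"), 0.9)
  # stop codons are conserved by construction (TAA <-> TAG only)
  expect_true(all(ss$stop_class %in% c("TAA", "TAG")))
  expect_false(any(ss$flagged))
})

test_that("cross-species usage summary has exact SE behaviour", {
  fx <- get_fixture()
  g <- fx$genomes[[1]]
  us2 <- usage_summary(list(g, g))
  expect_true(all(us2$codons$se_rscu[!is.na(us2$codons$se_rscu)] == 0))
  expect_true(all(us2$families$se_count == 0))
  us1 <- usage_summary(list(g))
  expect_true(all(is.na(us1$codons$se_rscu)))
  us <- usage_summary(fx$genomes)
  expect_identical(nrow(us$codons), 62L)
  expect_identical(nrow(us$families), 22L)
})
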