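test_that("global alignment is optimal against brute-force enumeration", {
  al <- global_align("ACGT", "ACGT")
  expect_identical(al$a, "ACGT")
  expect_identical(al$score, 4)
  al2 <- global_align("ACGT", "AGT")
  expect_identical(gsub("-", "", al2$a), "ACGT")
  expect_identical(gsub("-", "", al2$b), "AGT")
  expect_identical(nchar(al2$a), nchar(al2$b))
  set.seed(13)
  for (i in 1:30) {
    a <- paste(sample(c("A", "C", "G"), sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G"), sample(1:6, 1), TRUE), collapse = "")
    expect_identical(global_align(a, b)$score, brute_align_score(a, b),
                     info = paste(a, b))
  }
})

test_that("progressive MSA handles identity, insertions and width", {
  same <- c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC")
  al <- progressive_msa(same)
  expect_identical(unname(al$seqs), unname(same))
  seqs <- c(x = "ACGTACGTACGT", y = "ACGTACGTACGT", z = "ACGTACGTTTACGT")
  al2 <- progressive_msa(seqs)
  expect_identical(nchar(al2$seqs[["x"]]), 14L)
  expect_identical(gsub("-", "", al2$seqs[["z"]]), seqs[["z"]])
  # the inserted block shows as a gap in the two short rows
  expect_identical(lengths(regmatches(al2$seqs[["x"]],
                                      gregexpr("-+", al2$seqs[["x"]]))), 1L)
  expect_gte(nchar(al2$seqs[[1]]), max(nchar(seqs)))
})

test_that("codon-aware alignment preserves frame", {
  cds <- c(p = "ATGAAATTTGGGTAA", q = "ATGTTTGGGTAA")
  al <- codon_aware_align(cds)
  expect_identical(al$seqs[["q"]], "ATG---TTTGGG")
  # every gap run is a multiple of 3
  for (s in al$seqs) {
    runs <- nchar(regmatches(s, gregexpr("-+", s))[[1]])
    expect_true(all(runs %% 3 == 0))
  }
  # no-gap case round-trips (stop codon trimmed)
  cds2 <- c(p = "ATGAAATTTTAA", q = "ATGAAATTCTAA")
  al2 <- codon_aware_align(cds2)
  expect_identical(unname(al2$seqs), c("ATGAAATTT", "ATGAAATTC"))
  expect_error(codon_aware_align(c(a = "ATGTAAAAATAG", b = "ATGTAA")),
               "cannot translate")
})

test_that("supermatrix concatenates per-gene alignments with partitions", {
  fx <- get_fixture()
  genomes <- fx$genomes[1:4]
  sm <- build_supermatrix(genomes)
  expect_identical(nrow(sm$partitions), 37L)
  widths <- sm$partitions$end - sm$partitions$start
  expect_identical(sum(widths), nchar(sm$seqs[[1]]))
  expect_true(all(nchar(sm$seqs) == nchar(sm$seqs[[1]])))
  # column count invariant to genome input order
  sm2 <- build_supermatrix(rev(genomes))
  expect_identical(nchar(sm2$seqs[[1]]), nchar(sm$seqs[[1]]))
  # a supermatrix partition equals the stand-alone per-gene alignment
  part <- sm$partitions[sm$partitions$gene == "trnM", ]
  block <- vapply(sm$seqs, substr, "", part$start + 1, part$end)
  solo <- progressive_msa(stats::setNames(
    vapply(genomes, extract_gene, "", "trnM"),
    vapply(genomes, `[[`, "", "id")))
  expect_identical(unname(block), unname(solo$seqs))
  # PCG-only subset
  smp <- build_supermatrix(genomes, include = "PCG")
  expect_identical(nrow(smp$partitions), 13L)
  # a genome missing a gene gets a gap row
  g4 <- genomes[[4]]
  g4$features <- g4$features[g4$features$gene != "trnM", ]
  sm3 <- build_supermatrix(c(genomes[1:3], list(g4)), include = "tRNA")
  p <- sm3$partitions[sm3$partitions$gene == "trnM", ]
  expect_match(substr(sm3$seqs[[g4$id]], p$start + 1, p$end), "^-+$")
  expect_identical(attr(sm3, "missing")$gene, "trnM")
})

test_that("NJ recovers additive and ultrametric matrices", {
  # additive matrix from ((A:1,B:2):3,(C:4,D:5))
  D <- matrix(c(0, 3, 8, 9,
                3, 0, 9, 10,
                8, 9, 0, 9,
                9, 10, 9, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  # the AB|CD split is recovered with internal edge length 3
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, D, tolerance = 1e-9)
  # brute force: of the three 4-taxon topologies, NJ picked the best fit
  fits <- vapply(list(c("A", "B"), c("A", "C"), c("A", "D")), function(pr) {
    t0 <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));", pr[1], pr[2],
      setdiff(LETTERS[1:4], pr)[1], setdiff(LETTERS[1:4], pr)[2]))
    t0 <- ape::compute.brlen(t0, 1)
    sum((nnls_fit(t0, D) - D)^2)
  }, numeric(1))
  expect_identical(which.min(fits), 1L)
  # three taxa: closed-form star lengths
  D3 <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  pd3 <- ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(pd3, D3, tolerance = 1e-9)
  # saturated entries are refused with the pair named
  Dna <- D; Dna["A", "C"] <- Dna["C", "A"] <- NA
  expect_error(neighbor_joining(Dna), "A-C")
})

test_that("bootstrap supports are deterministic and bounded", {
  fx <- get_fixture()
  sm <- build_supermatrix(fx$genomes[1:4], include = "PCG")
  t1 <- bootstrap_support(sm, n_replicates = 25, seed = 99)
  t2 <- bootstrap_support(sm, n_replicates = 25, seed = 99)
  expect_identical(t1$node.label, t2$node.label)
  sup <- as.numeric(t1$node.label)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  t0 <- bootstrap_support(sm, n_replicates = 0)
  expect_null(t0$node.label)
})

test_that("gene order comparison is rotation-invariant and counts breakpoints", {
  ord <- c("g1", "g2", "g3", "g4", "g5", "g6")
  self <- gene_order_compare(ord, ord)
  expect_true(self$identical)
  expect_identical(self$breakpoint_count, 0L)
  rot <- gene_order_compare(ord, c(ord[4:6], ord[1:3]))
  expect_true(rot$identical)
  expect_identical(rot$breakpoint_count, 0L)
  # transposing one gene to a new position breaks 3 adjacencies
  moved <- c("g1", "g3", "g4", "g2", "g5", "g6")
  tr <- gene_order_compare(ord, moved)
  expect_false(tr$identical)
  expect_identical(tr$breakpoint_count, 3L)
  expect_error(gene_order_compare(ord, c(ord[-1], "g9")), "differ")
})
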