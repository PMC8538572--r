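test_that("K2P matches the closed form and handles edge cases", {
  r <- kimura2p("ACGTACGT", "ACGTACGT")
  expect_identical(c(r$d, r$P, r$Q), c(0, 0, 0))
  # engineered P = 0.1, Q = 0.05 over 20 sites: 2 transitions, 1 transversion
  a <- strrep("A", 20)
  b <- paste0("GG", "T", strrep("A", 17))
  r <- kimura2p(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(round(r$d, 4), 0.1702)
  expect_equal(r$d, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 0.1))
  # pure transversion case
  b2 <- paste0("T", strrep("A", 19))
  r2 <- kimura2p(a, b2)
  expect_equal(r2$P, 0)
  expect_equal(r2$d, -0.25 * log(0.9) - 0.5 * log(0.95))
  # gaps and ambiguity excluded pairwise
  r3 <- kimura2p("AC-GN", "ACTGA")
  expect_identical(r3$n_sites, 3L)
  # saturation yields a marker, not an exception
  r4 <- kimura2p("AAAA", "GGGG")
  expect_true(r4$saturated)
  expect_true(is.na(r4$d))
  expect_error(kimura2p("----", "ACGT"), "no comparable sites")
  expect_error(kimura2p("AC", "ACG"), "length")
})

test_that("K2P is symmetric and approaches JC at low divergence", {
  set.seed(5)
  for (i in 1:10) {
    n <- 500
    a <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    b <- evolve_sequence(a, 0.05, kappa = 2)
    expect_identical(kimura2p(a, b)$d, kimura2p(b, a)$d)
  }
  # at p <= 0.01 with the JC transition:transversion mix (1:2),
  # |d_K2P - d_JC| vanishes
  for (p in c(0.002, 0.006, 0.01)) {
    P <- p / 3; Q <- 2 * p / 3
    d_k2p <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    d_jc <- -0.75 * log(1 - 4 * p / 3)
    expect_lt(abs(d_k2p - d_jc), 1e-5)
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- c(t1 = "ACGTACGTAC", t2 = "ACGTACGTAC", t3 = "TTTTACGAAC")
  D <- distance_matrix(seqs)
  expect_identical(D["t1", "t2"], 0)
  expect_identical(unname(diag(D)), rep(0, 3))
  expect_identical(D["t1", "t3"], D["t3", "t1"])
  expect_gt(D["t1", "t3"], 0)
})

test_that("NG86 site counts agree with the exhaustive neighbour oracle", {
  code <- genetic_code(5)
  sense <- names(code$codons)[code$codons != "*"]
  expect_length(sense, 62L)  # table 5: only TAA/TAG are stops
  for (cod in sense) {
    got <- ng86_sites(cod, code)
    want_s <- oracle_ng86_sites(cod, as.list(code$codons))
    expect_equal(got[["s"]], want_s, info = cod)
    expect_equal(got[["s"]] + got[["n"]], 3, info = cod)
  }
  # anchors evaluated by hand from the code table
  expect_equal(ng86_sites("TTT")[["s"]], 1 / 3)
  expect_equal(ng86_sites("ATA")[["s"]], 1 / 3)
  expect_equal(ng86_sites("GTT")[["s"]], 1)
  expect_error(ng86_sites("TAA"), "stop")
})

test_that("NG86 pairs conserve sites and average pathways correctly", {
  code <- genetic_code(5)
  # identical CDSs
  r0 <- ng86_pair("ATGTTTAAA", "ATGTTTAAA")
  expect_identical(c(r0$Sd, r0$Nd, r0$Ka, r0$Ks), c(0, 0, 0, 0))
  expect_equal(r0$S + r0$N, 9)
  # one synonymous difference in 10 codons
  a <- paste0("ATG", strrep("GGA", 8), "TTT")
  b <- paste0("ATG", strrep("GGA", 8), "TTC")
  r1 <- ng86_pair(a, b)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$Ka, 0)
  expect_gt(r1$Ks, 0)
  # two-position difference: pathway averaging vs explicit enumeration
  for (pair in list(c("TTT", "CTC"), c("AAA", "ACG"), c("GAT", "TCT"),
                    c("ATG", "CCC"))) {
    got <- mitocomp:::ng86_diffs(pair[1], pair[2], code)
    want <- oracle_ng86_diffs(pair[1], pair[2], as.list(code$codons))
    expect_equal(unname(got), unname(want),
                 info = paste(pair, collapse = "-"))
    expect_equal(sum(got), length(which(strsplit(pair[1], "")[[1]] !=
                                          strsplit(pair[2], "")[[1]])))
  }
  # swapping input order changes nothing
  set.seed(9)
  sense <- names(code$codons)[code$codons != "*"]
  a <- paste(sample(sense, 30, TRUE), collapse = "")
  b <- mitocomp:::evolve_cds_seq(a, 0.1, 2, 0.5, code)
  rab <- ng86_pair(a, b)
  rba <- ng86_pair(b, a)
  expect_equal(rab[c("S", "N", "Sd", "Nd", "Ka", "Ks")],
               rba[c("S", "N", "Sd", "Nd", "Ka", "Ks")])
  expect_equal(rab$S + rab$N, 3 * rab$codons)
})

test_that("per-gene Ka/Ks tracks the generator's omega", {
  fx <- get_fixture()
  genomes <- fx$genomes[1:4]
  low <- per_gene_kaks(genomes, "COI")   # omega = 0.05
  high <- per_gene_kaks(genomes, "ATP8") # omega = 0.50
  expect_lt(low$mean_ratio, 0.3)
  expect_gt(high$mean_ratio, low$mean_ratio)
  expect_identical(low$n_pairs + low$n_excluded, 6L)
  expect_error(per_gene_kaks(genomes[1], "COI"), "< 2 genomes")
})

test_that("simulated pairs recover the true K2P distance", {
  set.seed(21)
  root <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                       c(0.47, 0.16, 0.10, 0.27)), collapse = "")
  a <- evolve_sequence(root, 0.1, kappa = 2)
  b <- evolve_sequence(root, 0.1, kappa = 2)
  expect_lt(abs(kimura2p(a, b)$d - 0.2), 0.02)
})

test_that("K2P distances agree with an independent implementation", {
  set.seed(33)
  seqs <- character(4)
  root <- sample(c("a", "c", "g", "t"), 800, TRUE)
  for (i in 1:4) {
    s <- root
    idx <- sample(800, 60)
    s[idx] <- sample(c("a", "c", "g", "t"), 60, TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- paste0("t", 1:4)
  D <- distance_matrix(toupper(seqs))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(seqs, "")))
  rownames(bin) <- names(seqs)
  Dref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(as.vector(D), as.vector(Dref[names(seqs), names(seqs)]),
               tolerance = 1e-10)
})
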