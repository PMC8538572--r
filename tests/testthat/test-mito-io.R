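test_that("reverse complement identities hold", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAC"), "GTT")
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(5:60, 1),
                      replace = TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("GenBank parsing maps coordinates, strands and synonyms", {
  g <- parse_genbank(toy_genbank_text())
  expect_s3_class(g, "mitogenome")
  expect_identical(g$id, "TOY2")
  expect_true(g$circular)
  expect_identical(nchar(g$sequence), 40L)
  nd2 <- g$features[g$features$gene == "ND2", ]
  expect_identical(c(nd2$start, nd2$end, nd2$strand), c("0", "9", "J"))
  coi <- g$features[g$features$gene == "COI", ]
  expect_identical(coi$strand, "N")
  expect_identical(c(coi$start, coi$end), c(9L, 21L))
  # tRNA-Leu resolved to trnL1 via the CUN anticodon
  expect_true("trnL1" %in% g$features$gene)
  expect_identical(g$features$anticodon[g$features$gene == "trnL1"], "TAG")
})

test_that("GenBank write -> parse round-trips coordinates and sequence", {
  fx <- get_fixture()
  g <- fx$genomes[[1]]
  path <- tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- parse_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features$gene, g$features$gene)
  expect_identical(g2$features$start, g$features$start)
  expect_identical(g2$features$end, g$features$end)
  expect_identical(g2$features$strand, g$features$strand)
})

test_that("malformed records and duplicate genes are rejected", {
  expect_error(parse_genbank(c("FEATURES", "ORIGIN", "//")), "LOCUS")
  txt <- toy_genbank_text()
  dup <- append(txt, c("     CDS             1..9",
                       "                     /gene=\"ND2\""), after = 8)
  expect_error(parse_genbank(dup), "duplicate")
})

test_that("unresolvable features are kept with a warning flag", {
  txt <- toy_genbank_text()
  txt <- append(txt, c("     CDS             22..24",
                       "                     /gene=\"mystery7\""), after = 13)
  g <- parse_genbank(txt)
  expect_true(any(g$features$warn))
  expect_true("mystery7" %in% g$features$gene)
})

test_that("extract_gene returns coding-sense sequence on both strands", {
  g <- toy_genome()
  expect_identical(extract_gene(g, "ND2"), "ATGAAATTTTAA")
  expect_identical(extract_gene(g, "trnM"),
                   revcomp(substr(g$sequence, 13, 20)))
  expect_error(extract_gene(g, "COI"), "not annotated")
  # J and N extractions of one interval are reverse complements
  fx <- get_fixture()
  gn <- fx$genomes[[1]]
  f <- gn$features[gn$features$gene == "ND1", ]
  expect_identical(f$strand, "N")
  raw_slice <- substr(gn$sequence, f$start + 1, f$end)
  expect_identical(extract_gene(gn, "ND1"), revcomp(raw_slice))
})

test_that("translation follows table 5 and reports incomplete stops", {
  code <- genetic_code(5)
  # table-5 departures from the standard code (published table)
  expect_identical(unname(code$codons[c("AGA", "AGG", "ATA", "TGA")]),
                   c("S", "S", "M", "W"))
  expect_identical(code$stops, c("TAA", "TAG"))
  tr <- translate_cds("ATGTTTTAA")
  expect_identical(tr$protein, "MF")
  expect_identical(tr$stop, "TAA")
  expect_identical(translate_cds("ATATGAAAATAA")$protein, "MWK")
  # 3k + 1 nt ending in T -> incomplete stop descriptor
  tr2 <- translate_cds("ATGAAAT")
  expect_identical(tr2$protein, "MK")
  expect_identical(tr2$stop, "T-")
  expect_identical(translate_cds("ATGAAATA")$stop, "TA-")
  expect_error(translate_cds("ATGTAATTT"), "internal stop")
  expect_error(translate_cds("AT!GGG"), "non-IUPAC")
})

test_that("gene order is rotation-normalized with strand signs", {
  fx <- get_fixture()
  g <- fx$genomes[[1]]
  go <- gene_order(g)
  expect_identical(go, mitocomp:::ANCESTRAL_ORDER)
  pcg <- gene_order(g, pcg_only = TRUE)
  expect_identical(sub("^-", "", pcg),
                   c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII", "ND3",
                     "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1"))
  # rotating the annotation does not change the normalized order
  rot <- g
  n <- nchar(g$sequence)
  cut <- min(g$features$start[g$features$start >= 5000L])  # feature boundary
  keep <- rot$features$start >= cut
  rot$features$start <- rot$features$start - cut +
    ifelse(keep, 0L, n)
  rot$features$end <- rot$features$end - cut + ifelse(keep, 0L, n)
  rot$sequence <- paste0(substr(g$sequence, cut + 1, n),
                         substr(g$sequence, 1, cut))
  expect_identical(gene_order(rot), go)
})

test_that("FASTA and Newick round-trip losslessly", {
  seqs <- c(one = "ACGTACGT", two = "AC-TA--T", three = "TTTT")
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  expect_error(write_fasta(c(a = "A", a = "C"), f), "duplicate")
  tr <- ape::rtree(6)
  nf <- tempfile(fileext = ".nwk")
  write_newick(tr, nf)
  tr2 <- read_newick(nf)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr))
})

test_that("PHYLIP and NEXUS exports are well-formed", {
  seqs <- c(sp_one = "ACGTAC", sp_two = "ACTTAC", sp_three = "GCGTAC")
  pf <- tempfile(fileext = ".phy")
  write_phylip(seqs, pf)
  ln <- readLines(pf)
  expect_match(ln[1], "^\\s*3 6$")
  expect_length(ln, 4L)
  expect_error(write_phylip(c(a = "AC", b = "ACG"), pf), "not aligned")
  nx <- tempfile(fileext = ".nex")
  write_nexus(seqs, nx,
              partitions = data.frame(gene = c("g1", "g2"),
                                      start = c(0L, 3L), end = c(3L, 6L)))
  ln <- readLines(nx)
  expect_true(any(grepl("charset g2 = 4-6;", ln)))
  expect_true(any(grepl("#NEXUS", ln)))
})
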