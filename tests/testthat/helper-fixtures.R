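# Shared fixtures and independent oracles, built once per test run.

# seeded 8-leaf fixture clade, cached across test files
fixture_cache <- new.env()

get_fixture <- function() {
  if (is.null(fixture_cache$fs)) {
    dir <- file.path(tempdir(), "mitocomp-test-fixtures")
    fixture_cache$fs <- fixture_suite(dir, seed = 42)
    fixture_cache$dir <- dir
    fixture_cache$genomes <- lapply(
      file.path(dir, paste0("S", 1:8, ".gb")), parse_genbank)
  }
  list(fs = fixture_cache$fs, dir = fixture_cache$dir,
       genomes = fixture_cache$genomes)
}

# a tiny hand-annotated genome for I/O tests: ND2 CDS on J, trnM-like
# feature on N
toy_genome <- function() {
  #          0         1         2
  #          0123456789012345678901234
  sequence <- "ATGAAATTTTAAGGCCTTAACCGGT"
  feats <- data.frame(
    gene = c("ND2", "trnM"), class = c("CDS", "tRNA"),
    start = c(0L, 12L), end = c(12L, 20L), strand = c("J", "N"),
    codon_start = c(1L, 1L), stringsAsFactors = FALSE)
  mitogenome("TOY1", sequence, feats, organism = "Toyus exampli",
             circular = FALSE)
}

# minimal GenBank record text exercising locations, qualifiers, synonyms
toy_genbank_text <- function() {
  c("LOCUS       TOY2             40 bp    DNA     circular   INV",
    "DEFINITION  toy record.",
    "  ORGANISM  Toyus secundus",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             1..9",
    "                     /gene=\"nad2\"",
    "                     /codon_start=1",
    "     CDS             complement(10..21)",
    "                     /gene=\"cox1\"",
    "     tRNA            25..32",
    "                     /product=\"tRNA-Leu\"",
    "                     /anticodon=\"(pos:28..30,aa:Leu,seq:tag)\"",
    "ORIGIN",
    "        1 atgaaatttt aaggccttaa ccggtacgta cgtacgtacg",
    "//")
}

# independent oracle: brute-force affine-gap global alignment score by
# exhaustive enumeration of all alignments (move sequences)
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  score_alignment <- function(ra, rb) {
    s <- 0
    prev <- "M"
    for (k in seq_along(ra)) {
      if (ra[k] == "-" ) {
        s <- s + if (prev == "A") gap_extend else gap_open
        prev <- "A"
      } else if (rb[k] == "-") {
        s <- s + if (prev == "B") gap_extend else gap_open
        prev <- "B"
      } else {
        s <- s + if (ra[k] == rb[k]) match else mismatch
        prev <- "M"
      }
    }
    s
  }
  xa <- strsplit(a, "")[[1]]
  xb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(xa) && j > length(xb)) {
      best <<- max(best, score_alignment(ra, rb))
      return(invisible())
    }
    if (i <= length(xa) && j <= length(xb))
      rec(i + 1, j + 1, c(ra, xa[i]), c(rb, xb[j]))
    if (i <= length(xa)) rec(i + 1, j, c(ra, xa[i]), c(rb, "-"))
    if (j <= length(xb)) rec(i, j + 1, c(ra, "-"), c(rb, xb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# independent oracle: NG86 site counts by explicit neighbour enumeration
# (written separately from the package's implementation)
oracle_ng86_sites <- function(codon, codons_map) {
  aa <- codons_map[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (codons_map[[mut]] == "*") next
      valid <- valid + 1
      if (codons_map[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# independent oracle: pathway-averaged syn/nonsyn differences between two
# codons, enumerating position orderings explicitly
oracle_ng86_diffs <- function(ca, cb, codons_map) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  orders <- if (length(pos) == 1) list(pos)
  else if (length(pos) == 2) list(pos, rev(pos))
  else {
    p <- pos
    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
  }
  res <- NULL
  for (o in orders) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (p in o) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (codons_map[[nxt]] == "*") { ok <- FALSE; break }
      if (codons_map[[nxt]] == codons_map[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res <- rbind(res, c(sd, nd))
  }
  colMeans(res)
}

# least-squares branch lengths for a fixed topology (test-local helper)
nnls_fit <- function(tree, D) {
  tre <- ape::unroot(tree)
  X <- sapply(seq_len(nrow(tre$edge)), function(e) {
    tr2 <- tre
    tr2$edge.length <- rep(0, nrow(tre$edge))
    tr2$edge.length[e] <- 1
    pd <- ape::cophenetic.phylo(tr2)
    pd[rownames(D), colnames(D)][upper.tri(D)]
  })
  y <- D[upper.tri(D)]
  beta <- stats::coef(stats::lm(y ~ X - 1))
  beta[is.na(beta) | beta < 0] <- 0
  fit <- as.vector(X %*% beta)
  out <- D
  out[upper.tri(out)] <- fit
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

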