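## Canonical 37-gene vocabulary and the annotated-mitogenome container.
##
## Internal coordinates are 0-based half-open; the GenBank boundary converts
## to and from 1-based inclusive. Strands are labelled J (majority, "+") and
## N (minority, "-"), the convention used for insect mitogenomes.

PCG_SYMBOLS <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                 "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB")
RRNA_SYMBOLS <- c("12SRNA", "16SRNA")
TRNA_SYMBOLS <- paste0("trn", c("A", "R", "N", "D", "C", "Q", "E", "G",
                                "H", "I", "K", "M", "F", "P", "T", "W",
                                "Y", "V", "L1", "L2", "S1", "S2"))
ALL_SYMBOLS <- c(PCG_SYMBOLS, RRNA_SYMBOLS, TRNA_SYMBOLS)

## Ancestral insect (pancrustacean) mitochondrial gene arrangement, with the
## minority-strand genes marked "-". The 14 N-chain genes are the two rRNAs,
## ND1/ND4/ND4L/ND5 and eight tRNAs.
ANCESTRAL_ORDER <- c(
  "trnI", "-trnQ", "trnM", "ND2", "trnW", "-trnC", "-trnY",
  "COI", "trnL2", "COII", "trnK", "trnD", "ATP8", "ATP6", "COIII",
  "trnG", "ND3", "trnA", "trnR", "trnN", "trnS1", "trnE",
  "-trnF", "-ND5", "-trnH", "-ND4", "-ND4L", "trnT", "-trnP",
  "ND6", "CYTB", "trnS2", "-ND1", "-trnL1", "-16SRNA", "-trnV", "-12SRNA")

N_CHAIN_GENES <- c("12SRNA", "16SRNA", "ND1", "ND4", "ND4L", "ND5",
                   "trnV", "trnL1", "trnP", "trnH", "trnF", "trnY",
                   "trnC", "trnQ")

# amino-acid letter -> trn symbol (Leu/Ser need an index, handled separately)
TRNA_AA <- c(Ala = "trnA", Arg = "trnR", Asn = "trnN", Asp = "trnD",
             Cys = "trnC", Gln = "trnQ", Glu = "trnE", Gly = "trnG",
             His = "trnH", Ile = "trnI", Lys = "trnK", Met = "trnM",
             Phe = "trnF", Pro = "trnP", Thr = "trnT", Trp = "trnW",
             Tyr = "trnY", Val = "trnV")

#' Resolve a gene name to the canonical 37-symbol vocabulary
#'
#' Maps the many spellings found in GenBank records (`"COX1"`, `"nad2"`,
#' `"l-rRNA"`, `"tRNA-Ala"`, ...) onto the package's canonical symbols.
#' Leucine and serine tRNAs are disambiguated by anticodon when one is
#' supplied, otherwise by an explicit index in the name; the convention is
#' trnL1 = Leu(CUN), trnL2 = Leu(UUR), trnS1 = Ser(AGN), trnS2 = Ser(UCN).
#'
#' @param name Gene or product string.
#' @param anticodon Optional anticodon triplet (DNA or RNA alphabet) used to
#'   disambiguate Leu/Ser tRNAs.
#' @return Canonical symbol, or `NA_character_` if unresolvable.
#' @export
resolve_gene_symbol <- function(name, anticodon = NULL) {
  key <- tolower(gsub("[ _]", "", name))
  hit <- GENE_SYNONYMS[[key]]
  if (!is.null(hit)) {
    if (hit %in% c("trnL?", "trnS?")) {
      base <- substr(hit, 1, 4)
      if (!is.null(anticodon) && nzchar(anticodon)) {
        ac <- toupper(chartr("u", "t", tolower(anticodon)))
        codon_fam <- substr(revcomp(ac), 1, 2)  # codon block recognised
        if (base == "trnL") return(if (codon_fam == "CT") "trnL1" else "trnL2")
        return(if (codon_fam == "AG") "trnS1" else "trnS2")
      }
      # codon-family spelled in the name, e.g. "tRNA-Leu(CUN)"
      if (grepl("cun", key)) return("trnL1")
      if (grepl("uur|uua|uug", key)) return("trnL2")
      if (grepl("agn|aga|agg|agc|agu", key)) return("trnS1")
      if (grepl("ucn", key)) return("trnS2")
      return(NA_character_)
    }
    return(hit)
  }
  NA_character_
}

GENE_SYNONYMS <- local({
  syn <- list()
  add <- function(canon, ...) for (k in c(tolower(canon), ...)) syn[[k]] <<- canon
  add("ND1", "nad1", "nadh1", "nadhdehydrogenasesubunit1")
  add("ND2", "nad2", "nadh2", "nadhdehydrogenasesubunit2")
  add("ND3", "nad3", "nadh3", "nadhdehydrogenasesubunit3")
  add("ND4", "nad4", "nadh4", "nadhdehydrogenasesubunit4")
  add("ND4L", "nad4l", "nadhdehydrogenasesubunit4l")
  add("ND5", "nad5", "nadh5", "nadhdehydrogenasesubunit5")
  add("ND6", "nad6", "nadh6", "nadhdehydrogenasesubunit6")
  add("COI", "cox1", "co1", "coxi", "cytochromecoxidasesubunit1",
      "cytochromecoxidasesubuniti")
  add("COII", "cox2", "co2", "coxii", "cytochromecoxidasesubunit2",
      "cytochromecoxidasesubunitii")
  add("COIII", "cox3", "co3", "coxiii", "cytochromecoxidasesubunit3",
      "cytochromecoxidasesubunitiii")
  add("ATP6", "atpase6", "atpsynthasef0subunit6", "atpsynthasesubunit6")
  add("ATP8", "atpase8", "atpsynthasef0subunit8", "atpsynthasesubunit8")
  add("CYTB", "cob", "cytb", "cytochromeb", "cb")
  add("12SRNA", "rrns", "srrna", "s-rrna", "12s", "12srrna",
      "12sribosomalrna", "smallsubunitribosomalrna")
  add("16SRNA", "rrnl", "lrrna", "l-rrna", "16s", "16srrna",
      "16sribosomalrna", "largesubunitribosomalrna")
  for (aa in names(TRNA_AA)) {
    sym <- TRNA_AA[[aa]]
    letter <- substr(sym, 4, 4)
    syn[[tolower(sym)]] <- sym
    syn[[tolower(paste0("trna-", aa))]] <- sym
    syn[[tolower(paste0("trna", aa))]] <- sym
    syn[[tolower(paste0("trn", letter))]] <- sym
  }
  # Leu/Ser: ambiguous until an anticodon or index disambiguates
  for (k in c("trnl", "trna-leu", "trnaleu")) syn[[k]] <- "trnL?"
  for (k in c("trns", "trna-ser", "trnaser")) syn[[k]] <- "trnS?"
  for (idx in 1:2) {
    syn[[paste0("trnl", idx)]] <- paste0("trnL", idx)
    syn[[paste0("trns", idx)]] <- paste0("trnS", idx)
    syn[[tolower(paste0("trna-leu", idx))]] <- paste0("trnL", idx)
    syn[[tolower(paste0("trna-ser", idx))]] <- paste0("trnS", idx)
  }
  # anticodon-family spellings pass through resolve_gene_symbol's regexes
  for (k in c("trna-leu(cun)", "trnaleu(cun)", "trnl(cun)")) syn[[k]] <- "trnL?"
  for (k in c("trna-leu(uur)", "trnaleu(uur)", "trnl(uur)")) syn[[k]] <- "trnL?"
  for (k in c("trna-ser(agn)", "trnaser(agn)", "trns(agn)")) syn[[k]] <- "trnS?"
  for (k in c("trna-ser(ucn)", "trnaser(ucn)", "trns(ucn)")) syn[[k]] <- "trnS?"
  syn
})

feature_class_for <- function(gene) {
  ifelse(gene %in% PCG_SYMBOLS, "CDS",
         ifelse(gene %in% RRNA_SYMBOLS, "rRNA",
                ifelse(gene %in% TRNA_SYMBOLS, "tRNA", NA_character_)))
}

#' Construct an annotated mitogenome
#'
#' @param id Accession-style identifier.
#' @param sequence DNA string (IUPAC alphabet).
#' @param features `data.frame` with columns `gene`, `class` (CDS/tRNA/rRNA),
#'   `start`, `end` (0-based half-open), `strand` ("J" or "N"),
#'   `codon_start` (1-3), and optionally `start2`/`end2` (second interval of
#'   a feature wrapping the circular origin) and `warn` (logical flag for
#'   features whose name did not resolve to the canonical vocabulary).
#' @param organism Free-text organism name.
#' @param circular Is the molecule circular?
#' @return Object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, features, organism = "",
                       circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("start2", "end2")) {
    if (is.null(features[[col]])) features[[col]] <- NA_integer_
  }
  if (is.null(features$warn)) features$warn <- FALSE
  if (is.null(features$codon_start)) features$codon_start <- 1L
  if (is.null(features$anticodon)) features$anticodon <- NA_character_
  n <- nchar(sequence)
  ok <- features$start < features$end & features$start >= 0 & features$end <= n
  if (any(!ok))
    stop("feature interval out of bounds for: ",
         paste(features$gene[!ok], collapse = ", "))
  canon <- features$gene[!features$warn]
  if (anyDuplicated(canon))
    stop("duplicate canonical gene annotation: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  bad_class <- !features$warn &
    features$class != feature_class_for(features$gene)
  if (any(bad_class, na.rm = TRUE))
    stop("feature class inconsistent with gene symbol: ",
         paste(features$gene[which(bad_class)], collapse = ", "))
  structure(list(id = id, organism = organism, circular = circular,
                 sequence = toupper(sequence), features = features),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s%s: %s bp, %s, %d features\n", x$id,
              if (nzchar(x$organism)) paste0(" (", x$organism, ")") else "",
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  cls <- table(factor(x$features$class, c("CDS", "tRNA", "rRNA")))
  cat(sprintf("  %d CDS, %d tRNA, %d rRNA\n", cls["CDS"], cls["tRNA"],
              cls["rRNA"]))
  invisible(x)
}

## ---- GenBank flat-file reader/writer -------------------------------------

#' Parse a GenBank flat-file record into an annotated mitogenome
#'
#' A minimal reader for single-record GenBank flat files covering the fields
#' this package needs: LOCUS (length, circular/linear), ORGANISM, the
#' CDS/tRNA/rRNA features with their locations (including `complement()` and
#' origin-wrapping `join()`) and `/gene`, `/product`, `/codon_start` and
#' `/anticodon` qualifiers, and the ORIGIN sequence. Gene names are resolved
#' through [resolve_gene_symbol()]; unresolvable features are retained with
#' `warn = TRUE` rather than dropped.
#'
#' @param x Path to a GenBank file, or a character vector of record lines.
#' @return A [mitogenome()].
#' @export
parse_genbank <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]]
  else x

  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank record: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(grepl("circular", locus, ignore.case = TRUE))
  org_i <- grep("^\\s{2}ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^\\s*ORGANISM\\s*", "",
                                            lines[org_i[1]])) else ""

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i))
    stop("malformed GenBank record: no ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("malformed GenBank record: empty ORIGIN")

  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    # a feature starts at indent 5 with a key; continuation/qualifier lines
    # are indented 21
    starts <- grep("^ {5}\\S", block)
    bounds <- c(starts, length(block) + 1L)
    for (k in seq_along(starts)) {
      chunk <- block[starts[k]:(bounds[k + 1L] - 1L)]
      key <- sub("^\\s+", "", chunk[1])
      key <- strsplit(key, "\\s+")[[1]]
      fkey <- key[1]
      if (!fkey %in% c("CDS", "tRNA", "rRNA")) next
      loc <- paste0(key[-1], collapse = "")
      # location may continue on lines before the first qualifier
      qual_start <- grep("^\\s{21}/", chunk)
      extra <- setdiff(seq_along(chunk)[-1],
                       if (length(qual_start)) qual_start[1]:length(chunk)
                       else integer(0))
      if (length(extra)) loc <- paste0(loc, gsub("\\s", "", chunk[extra]))
      quals <- parse_qualifiers(chunk)
      li <- tryCatch(parse_location(loc), error = function(e)
        stop("malformed location near line ", locus_i[1] + feat_i[1] + starts[k],
             ": ", loc))
      name <- quals[["gene"]] %||% quals[["product"]] %||% ""
      ac <- anticodon_from_qual(quals[["anticodon"]], quals[["product"]])
      sym <- resolve_gene_symbol(name, anticodon = ac)
      warn <- is.na(sym)
      if (warn) sym <- name
      feats[[length(feats) + 1L]] <- data.frame(
        gene = sym, class = fkey,
        start = li$start, end = li$end,
        strand = if (li$complement) "N" else "J",
        codon_start = as.integer(quals[["codon_start"]] %||% "1"),
        start2 = li$start2, end2 = li$end2,
        anticodon = if (is.null(ac)) NA_character_ else ac,
        warn = warn, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats)
  else data.frame(gene = character(), class = character(),
                  start = integer(), end = integer(), strand = character(),
                  codon_start = integer(), start2 = integer(),
                  end2 = integer(), anticodon = character(),
                  warn = logical(), stringsAsFactors = FALSE)
  mitogenome(id = id, sequence = sequence, features = features,
             organism = organism, circular = circular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_qualifiers <- function(chunk) {
  qlines <- grep("^\\s{21}/", chunk, value = TRUE)
  out <- list()
  for (q in qlines) {
    q <- sub("^\\s+/", "", q)
    eq <- regexpr("=", q, fixed = TRUE)
    if (eq < 0) { out[[q]] <- ""; next }
    key <- substr(q, 1, eq - 1)
    val <- gsub('^"|"$', "", substr(q, eq + 1, nchar(q)))
    out[[key]] <- val
  }
  out
}

anticodon_from_qual <- function(anticodon_qual, product) {
  if (!is.null(anticodon_qual)) {
    m <- regmatches(anticodon_qual,
                    regexpr("seq:[acgtu]{3}", anticodon_qual, ignore.case = TRUE))
    if (length(m)) return(toupper(chartr("uU", "tT", sub("seq:", "", m))))
  }
  NULL
}

# "a..b", "complement(a..b)", "join(a..b,c..d)" (origin wrap),
# "complement(join(a..b,c..d))"; returns 0-based half-open intervals
parse_location <- function(loc) {
  complement <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|\\)$", "", loc)
  inner <- gsub("^join\\(|\\)$", "", inner)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  iv <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) != 3) stop("bad interval: ", p)
    c(as.integer(m[2]) - 1L, as.integer(m[3]))
  })
  if (length(iv) == 1L)
    list(start = iv[[1]][1], end = iv[[1]][2],
         start2 = NA_integer_, end2 = NA_integer_, complement = complement)
  else if (length(iv) == 2L)
    list(start = iv[[1]][1], end = iv[[1]][2],
         start2 = iv[[2]][1], end2 = iv[[2]][2], complement = complement)
  else stop("unsupported location: ", loc)
}

#' Write a mitogenome as a GenBank flat file
#'
#' @param genome A [mitogenome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   INV",
                   genome$id, n,
                   if (genome$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrion.",
                   if (nzchar(genome$organism)) genome$organism else genome$id),
           "FEATURES             Location/Qualifiers",
           "     source          1..%d" |> sprintf(n),
           sprintf("                     /organism=\"%s\"", genome$organism))
  fmt_loc <- function(f) {
    iv <- sprintf("%d..%d", f$start + 1L, f$end)
    if (!is.na(f$start2))
      iv <- sprintf("join(%s,%d..%d)", iv, f$start2 + 1L, f$end2)
    if (f$strand == "N") iv <- sprintf("complement(%s)", iv)
    iv
  }
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    out <- c(out,
             sprintf("     %-15s %s", f$class, fmt_loc(f)),
             sprintf("                     /gene=\"%s\"", f$gene))
    if (f$class == "CDS")
      out <- c(out,
               sprintf("                     /codon_start=%d", f$codon_start),
               "                     /transl_table=5")
    if (f$class == "tRNA" && !is.na(f$anticodon))
      out <- c(out, sprintf(
        "                     /anticodon=\"(pos:complement(0..0),aa:Xxx,seq:%s)\"",
        tolower(f$anticodon)))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ---- gene extraction and gene order --------------------------------------

#' Extract a gene's sequence in coding sense
#'
#' Returns the feature's subsequence; minority-strand (N) features are
#' reverse-complemented so the result always reads 5'->3' in coding sense.
#' Origin-wrapping features (stored as two intervals) are re-joined.
#'
#' @param genome A [mitogenome()].
#' @param gene Canonical gene symbol.
#' @return DNA string.
#' @export
extract_gene <- function(genome, gene) {
  i <- which(genome$features$gene == gene)
  if (!length(i)) stop("gene not annotated: ", gene)
  f <- genome$features[i[1], ]
  s <- substr(genome$sequence, f$start + 1L, f$end)
  if (!is.na(f$start2))
    s <- paste0(s, substr(genome$sequence, f$start2 + 1L, f$end2))
  if (f$strand == "N") s <- revcomp(s)
  s
}

#' Gene order of an annotated mitogenome
#'
#' Features sorted by start position, with circular rotation normalized so
#' that trnI (or, failing that, ND2) leads. Minority-strand genes carry a
#' leading `"-"`.
#'
#' @param genome A [mitogenome()].
#' @param pcg_only Keep only the 13 protein-coding genes.
#' @return Character vector of (signed) gene symbols.
#' @export
gene_order <- function(genome, pcg_only = FALSE) {
  f <- genome$features[!genome$features$warn, ]
  f <- f[order(f$start), ]
  sym <- ifelse(f$strand == "N", paste0("-", f$gene), f$gene)
  anchor <- match(TRUE, f$gene == "trnI")
  if (is.na(anchor)) anchor <- match(TRUE, f$gene == "ND2")
  if (!is.na(anchor) && anchor > 1L)
    sym <- c(sym[anchor:length(sym)], sym[seq_len(anchor - 1L)])
  if (pcg_only) sym <- sym[sub("^-", "", sym) %in% PCG_SYMBOLS]
  sym
}

## ---- standard serializations ---------------------------------------------

#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings] returning/accepting named character
#' vectors, so gapped alignment rows round-trip unchanged.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(70, nchar(s) + 69, 70), nchar(s))), con)
  }
  invisible(path)
}

#' Export an alignment in relaxed PHYLIP or NEXUS format
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param path Output path.
#' @export
write_phylip <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences not aligned")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(seqs), nchar(seqs[[1]])), con)
  writeLines(sprintf("%s  %s", names(seqs), unname(seqs)), con)
  invisible(path)
}

#' @rdname write_phylip
#' @param partitions Optional `data.frame` with columns `gene`, `start`,
#'   `end` (0-based half-open column ranges) written as NEXUS charsets.
#' @export
write_nexus <- function(seqs, path, partitions = NULL) {
  mat <- lapply(seqs, function(s) strsplit(tolower(s), "")[[1]])
  ape::write.nexus.data(mat, file = path, interleaved = FALSE,
                        datablock = FALSE)
  if (!is.null(partitions)) {
    sets <- c("begin sets;",
              sprintf("  charset %s = %d-%d;", partitions$gene,
                      partitions$start + 1L, partitions$end),
              "end;")
    cat(paste0(sets, "\n"), file = path, append = TRUE, sep = "")
  }
  invisible(path)
}

#' Read and write Newick trees
#'
#' @param x For `write_newick`, an [ape::phylo] tree.
#' @param path File path.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(x, path) {
  ape::write.tree(x, file = path)
  invisible(path)
}
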