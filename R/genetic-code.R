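#' Invertebrate mitochondrial genetic code (translation table 5)
#'
#' Returns the genetic code used throughout the package. The codon table is
#' taken from [Biostrings::getGeneticCode()]; the object adds the start- and
#' stop-codon sets and the synonymous-family partition used for RSCU, in
#' which leucine and serine are each split into two families
#' (Leu1 = CUN, Leu2 = UUR, Ser1 = AGN, Ser2 = UCN).
#'
#' Table 5 differs from the standard code at AGA/AGG (Ser, not Arg/stop),
#' ATA (Met, not Ile) and TGA (Trp, not stop). Its stop codons are TAA and
#' TAG only.
#'
#' @param id Translation table number. Only 5 (invertebrate mitochondrial)
#'   and 1 (standard, for completeness) are supported.
#' @return An object of class `genetic_code`: a list with elements
#'   `id`, `codons` (named character vector of 64 amino-acid letters,
#'   `"*"` for stop), `starts`, `stops`, and `families` (named character
#'   vector mapping each sense codon to its synonymous-family label).
#' @examples
#' gc5 <- genetic_code(5)
#' gc5$codons[c("AGA", "ATA", "TGA")]  # S, M, W
#' @export
genetic_code <- function(id = 5) {
  if (!id %in% c(1L, 5L)) stop("unsupported translation table: ", id)
  map <- Biostrings::getGeneticCode(as.character(id))
  codons <- stats::setNames(as.character(map), names(map))
  stops <- names(codons)[codons == "*"]
  starts <- if (id == 5) c("TTG", "ATT", "ATC", "ATA", "ATG", "GTG")
            else c("TTG", "CTG", "ATG")
  families <- codon_families(codons)
  structure(list(id = as.integer(id), codons = codons, starts = starts,
                 stops = stops, families = families),
            class = "genetic_code")
}

# Partition sense codons into synonymous families; Leu and Ser are split by
# codon block so that the two mitochondrial tRNA isoacceptor families
# (Leu1/Leu2, Ser1/Ser2) are kept apart.
codon_families <- function(codons) {
  sense <- codons[codons != "*"]
  fam <- vapply(names(sense), function(cd) {
    aa <- sense[[cd]]
    if (aa == "L") {
      if (substr(cd, 1, 1) == "C") "Leu1" else "Leu2"
    } else if (aa == "S") {
      if (substr(cd, 1, 2) == "AG") "Ser1" else "Ser2"
    } else {
      AA_THREE[[aa]]
    }
  }, character(1))
  fam
}

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              K = "Lys", M = "Met", F = "Phe", P = "Pro", T = "Thr",
              W = "Trp", Y = "Tyr", V = "Val", L = "Leu", S = "Ser")

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code, translation table", x$id, "\n")
  cat("  stops:", paste(x$stops, collapse = " "),
      "| starts:", paste(x$starts, collapse = " "), "\n")
  invisible(x)
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation honouring incomplete stop codons. A trailing
#' remainder of 1-2 nt beginning with T is reported as an incomplete stop
#' (`"T-"` or `"TA-"`) when `allow_incomplete_stop = TRUE`; such remainders
#' are common in metazoan mitochondrial CDSs and are completed to UAA by
#' polyadenylation of the transcript.
#'
#' @param cds DNA string (coding sense, frame starting at position 1).
#' @param code A [genetic_code()] object.
#' @param allow_incomplete_stop Report a trailing T/TA remainder as an
#'   incomplete stop instead of erroring.
#' @return A list with `protein` (amino-acid string, terminal stop not
#'   included), `stop` (one of `"TAA"`, `"TAG"`, `"T-"`, `"TA-"`, or `NA`
#'   when the CDS ends without any stop signal).
#' @examples
#' translate_cds("ATGTTTTAA")$protein  # "MF"
#' @export
translate_cds <- function(cds, code = genetic_code(5),
                          allow_incomplete_stop = TRUE) {
  cds <- toupper(chartr("u", "t", cds))
  n <- nchar(cds)
  if (n < 3) stop("CDS shorter than one codon")
  if (grepl("[^ACGTRYSWKMBDHVN]", cds)) stop("non-IUPAC symbol in CDS")
  nc <- n %/% 3L
  rem <- substr(cds, 3L * nc + 1L, n)
  cods <- substring(cds, seq(1L, by = 3L, length.out = nc),
                    seq(3L, by = 3L, length.out = nc))
  aa <- unname(code$codons[cods])
  aa[is.na(aa)] <- "X"  # ambiguity-containing codons
  stop_desc <- NA_character_
  if (length(aa) && aa[length(aa)] == "*") {
    stop_desc <- cods[length(cods)]
    aa <- aa[-length(aa)]
    cods <- cods[-length(cods)]
  } else if (nchar(rem) > 0 && substr(rem, 1, 1) == "T") {
    if (!allow_incomplete_stop)
      stop("CDS ends in incomplete codon '", rem, "'")
    stop_desc <- if (rem == "T") "T-" else if (rem == "TA") "TA-" else NA
  }
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon at codon ", internal[1])
  list(protein = paste(aa, collapse = ""), stop = stop_desc)
}
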