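#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented as usual; case is preserved.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAC")  # "GTT"
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# split a DNA string into a character vector of single bases (uppercased)
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# chop a string into codons, dropping any incomplete tail
codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, seq(1L, by = 3L, length.out = n),
            seq(3L, by = 3L, length.out = n))
}

# purine/pyrimidine transition partner
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}
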