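#' Base counts of a DNA string
#'
#' Case-insensitive tallies of A, T, G, C; U is counted as T; every other
#' symbol (IUPAC ambiguity codes, gaps) is excluded from the counts and
#' reported under `excluded`.
#'
#' @param seq DNA string.
#' @return Named integer vector `A`, `T`, `G`, `C`, `excluded`.
#' @examples
#' base_counts("AATTC")
#' @export
base_counts <- function(seq) {
  s <- chartr("uU", "tT", toupper(seq))
  tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                      levels = c("A", "T", "G", "C")))
  counts <- as.integer(tab)
  names(counts) <- c("A", "T", "G", "C")
  c(counts, excluded = nchar(s) - sum(counts))
}

#' AT and GC strand skews
#'
#' AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C). A zero denominator
#' yields `NA` (undefined), not an error.
#'
#' @param counts Named vector with elements `A`, `T`, `G`, `C`
#'   (as returned by [base_counts()]), or a DNA string.
#' @return Named numeric vector `AT_skew`, `GC_skew`.
#' @examples
#' skews("AAAT")  # AT skew 0.5
#' @export
skews <- function(counts) {
  if (is.character(counts)) counts <- base_counts(counts)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  c(AT_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    GC_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_)
}

#' Composition summary per genome region class
#'
#' One row for the whole genome plus one for the concatenation of each
#' region class (all PCGs, all tRNAs, all rRNAs, each gene strand-corrected
#' to coding sense before concatenation), and optionally one per gene.
#' The whole-genome row is computed on the J (majority) strand as annotated.
#' Genes overlapping on the molecule contribute once to each class they
#' belong to, matching concatenation semantics.
#'
#' @param genome A [mitogenome()].
#' @param per_gene Also emit one row per annotated gene.
#' @return `data.frame` with columns `region`, `length`, `A`, `T`, `G`, `C`,
#'   `n_excluded`, `AT_content`, `GC_content`, `AT_skew`, `GC_skew`.
#'   Contents are percentages rounded to 2 decimals; skews to 4.
#' @export
region_composition <- function(genome, per_gene = FALSE) {
  f <- genome$features[!genome$features$warn, ]
  concat <- function(genes) paste(vapply(genes, function(g)
    extract_gene(genome, g), character(1)), collapse = "")
  regions <- list(whole = genome$sequence,
                  PCG = concat(f$gene[f$class == "CDS"]),
                  tRNA = concat(f$gene[f$class == "tRNA"]),
                  rRNA = concat(f$gene[f$class == "rRNA"]))
  if (per_gene)
    regions <- c(regions,
                 stats::setNames(lapply(f$gene, concat), f$gene))
  rows <- lapply(names(regions), function(nm) {
    s <- regions[[nm]]
    cnt <- base_counts(s)
    tot <- sum(cnt[c("A", "T", "G", "C")])
    sk <- skews(cnt)
    data.frame(region = nm, length = nchar(s),
               A = cnt[["A"]], T = cnt[["T"]], G = cnt[["G"]], C = cnt[["C"]],
               n_excluded = cnt[["excluded"]],
               AT_content = if (tot > 0)
                 round(100 * (cnt[["A"]] + cnt[["T"]]) / tot, 2) else NA_real_,
               GC_content = if (tot > 0)
                 round(100 * (cnt[["G"]] + cnt[["C"]]) / tot, 2) else NA_real_,
               AT_skew = round(sk[["AT_skew"]], 4),
               GC_skew = round(sk[["GC_skew"]], 4),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
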