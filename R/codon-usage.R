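#' Codon usage of a mitogenome's protein-coding genes
#'
#' Pools complete codons over the 13 PCGs (reading frame taken from each
#' feature's `codon_start`). Terminal stop codons are tallied separately;
#' trailing incomplete codons (the T-/TA- incomplete stops) never enter the
#' codon counts but are recorded per gene. A CDS containing an internal stop
#' codon is skipped and reported in `errors`; the run continues.
#'
#' @param genome A [mitogenome()], or a named character vector of CDS
#'   sequences (coding sense, frame 1).
#' @param code A [genetic_code()].
#' @return Object of class `codon_usage`: list with `codon_counts`
#'   (named integer, 64 codons), `stop_counts`, `incomplete` (named
#'   character: per-gene incomplete-stop descriptor), `aa_counts`
#'   (per synonymous family), `families`, `errors`.
#' @export
codon_counts <- function(genome, code = genetic_code(5)) {
  cds <- if (inherits(genome, "mitogenome")) {
    f <- genome$features[genome$features$class == "CDS" & !genome$features$warn, ]
    seqs <- stats::setNames(
      mapply(function(g, off) {
        s <- extract_gene(genome, g)
        substr(s, off, nchar(s))
      }, f$gene, f$codon_start, SIMPLIFY = TRUE),
      f$gene)
    seqs
  } else genome
  counts <- stats::setNames(integer(64), names(code$codons))
  stop_counts <- stats::setNames(integer(length(code$stops)), code$stops)
  incomplete <- character(0)
  errors <- character(0)
  for (g in names(cds)) {
    s <- toupper(cds[[g]])
    cods <- codon_split(s)
    if (!length(cods)) next
    aa <- code$codons[cods]
    internal <- which(aa == "*")
    if (length(internal) && internal[1] < length(cods)) {
      errors[g] <- sprintf("internal stop codon at codon %d", internal[1])
      next
    }
    if (length(cods) && !is.na(aa[length(cods)]) && aa[length(cods)] == "*") {
      stop_counts[cods[length(cods)]] <- stop_counts[cods[length(cods)]] + 1L
      cods <- cods[-length(cods)]
    } else {
      rem <- substr(s, 3L * length(cods) + 1L, nchar(s))
      if (rem == "T") incomplete[g] <- "T-"
      else if (rem == "TA") incomplete[g] <- "TA-"
    }
    keep <- cods[!is.na(code$codons[cods])]  # drop ambiguity codons
    tab <- table(factor(keep, levels = names(counts)))
    counts <- counts + as.integer(tab)
  }
  fam_levels <- unique(unname(code$families))
  sense <- names(code$families)
  aa_counts <- tapply(counts[sense], factor(code$families[sense], fam_levels),
                      sum)
  structure(list(codon_counts = counts, stop_counts = stop_counts,
                 incomplete = incomplete,
                 aa_counts = stats::setNames(as.integer(aa_counts),
                                             fam_levels),
                 families = code$families, errors = errors),
            class = "codon_usage")
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = count(c) x family size / family total: the observed count
#' divided by the mean count of the codon's synonymous family. Families with
#' zero total get `NA`; stop codons are excluded. Leu and Ser are each split
#' into two families (Leu1 = CUN, Leu2 = UUR, Ser1 = AGN, Ser2 = UCN).
#'
#' @param table A `codon_usage` object from [codon_counts()].
#' @return Named numeric vector of RSCU values over the sense codons.
#' @examples
#' gc5 <- genetic_code(5)
#' cu <- codon_counts(c(gene = "ATGTTTTTTTTTTTCTAA"))
#' rscu(cu)[c("TTT", "TTC")]  # 1.5, 0.5
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  sense <- names(table$families)
  fam <- table$families[sense]
  cnt <- table$codon_counts[sense]
  fam_tot <- tapply(cnt, fam, sum)[fam]
  fam_size <- table(fam)[fam]
  out <- ifelse(fam_tot > 0, cnt * as.integer(fam_size) / fam_tot, NA_real_)
  stats::setNames(as.numeric(out), sense)
}

#' Start and stop codon classification over genomes
#'
#' The start codon is the first complete codon of each CDS, classified as
#' ATN, TTG, GTG or other; the stop is classified as TAA, TAG, or the
#' incomplete T-/TA-.
#'
#' @param genomes List of [mitogenome()] objects.
#' @param code A [genetic_code()].
#' @return `data.frame` with columns `genome`, `gene`, `start_codon`,
#'   `start_class`, `stop_codon`, `stop_class`, `flagged` (CDS shorter than
#'   6 nt).
#' @export
start_stop_table <- function(genomes, code = genetic_code(5)) {
  rows <- lapply(genomes, function(gn) {
    f <- gn$features[gn$features$class == "CDS" & !gn$features$warn, ]
    do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
      s <- extract_gene(gn, f$gene[i])
      s <- substr(s, f$codon_start[i], nchar(s))
      start <- substr(s, 1, 3)
      start_class <- if (grepl("^AT[ACGT]$", start)) "ATN"
        else if (start == "TTG") "TTG"
        else if (start == "GTG") "GTG" else "other"
      cods <- codon_split(s)
      last <- cods[length(cods)]
      rem <- substr(s, 3L * length(cods) + 1L, nchar(s))
      if (!is.na(code$codons[last]) && code$codons[last] == "*") {
        stop_codon <- last; stop_class <- last
      } else if (rem == "T") {
        stop_codon <- "T-"; stop_class <- "T-"
      } else if (rem == "TA") {
        stop_codon <- "TA-"; stop_class <- "TA-"
      } else {
        stop_codon <- NA_character_; stop_class <- "none"
      }
      data.frame(genome = gn$id, gene = f$gene[i], start_codon = start,
                 start_class = start_class, stop_codon = stop_codon,
                 stop_class = stop_class, flagged = nchar(s) < 6,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-species codon-usage summary
#'
#' Per-codon mean RSCU and per-family mean amino-acid count across genomes,
#' with standard errors (SE = sd / sqrt(n); `NA` for a single genome).
#'
#' @param genomes List of [mitogenome()] objects (>= 1).
#' @param code A [genetic_code()].
#' @return List with `codons` (`data.frame`: codon, family, mean_rscu,
#'   se_rscu) and `families` (`data.frame`: family, mean_count, se_count).
#' @export
usage_summary <- function(genomes, code = genetic_code(5)) {
  tabs <- lapply(genomes, codon_counts, code = code)
  rscus <- do.call(rbind, lapply(tabs, rscu))
  aas <- do.call(rbind, lapply(tabs, function(t) t$aa_counts))
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                    else NA_real_
  sense <- names(code$families)
  codons <- data.frame(
    codon = sense, family = unname(code$families[sense]),
    mean_rscu = colMeans(rscus, na.rm = TRUE),
    se_rscu = apply(rscus, 2, se), stringsAsFactors = FALSE)
  fams <- data.frame(
    family = colnames(aas),
    mean_count = colMeans(aas),
    se_count = apply(aas, 2, se), stringsAsFactors = FALSE)
  rownames(codons) <- rownames(fams) <- NULL
  list(codons = codons, families = fams)
}

#' Bar chart of mean RSCU values
#'
#' A plain [graphics::barplot()] of cross-species mean RSCU grouped by
#' synonymous family.
#'
#' @param summary Output of [usage_summary()].
#' @export
plot_rscu <- function(summary) {
  d <- summary$codons[order(summary$codons$family), ]
  graphics::barplot(d$mean_rscu, names.arg = d$codon, las = 2,
                    cex.names = 0.5, ylab = "RSCU",
                    col = factor(d$family))
  graphics::abline(h = 1, lty = 2)
}
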