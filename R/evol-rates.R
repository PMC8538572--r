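#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`, where P and Q are the
#' proportions of sites showing a transition and a transversion
#' respectively. Sites with a gap or ambiguity code in either sequence are
#' excluded pairwise. When the logarithm arguments are non-positive the
#' distance is saturated and `d` is `NA` with `saturated = TRUE` (no
#' exception is raised).
#'
#' @param a,b Aligned DNA strings of equal length.
#' @return List with `d`, `P`, `Q`, `n_sites` (retained sites),
#'   `saturated`.
#' @examples
#' kimura2p("ACGT", "ACGA")$P  # one transition in four sites
#' @export
kimura2p <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  x <- seq_chars(a); y <- seq_chars(b)
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  diff <- x != y
  ts <- diff & is_transition(x, y)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(list(d = NA_real_, P = P, Q = Q, n_sites = n, saturated = TRUE))
  list(d = -0.5 * log(a1) - 0.25 * log(a2), P = P, Q = Q, n_sites = n,
       saturated = FALSE)
}

#' Pairwise K2P distance matrix from an alignment
#'
#' All pairs via [kimura2p()] with pairwise deletion of gapped/ambiguous
#' sites. Saturated pairs get `NA` in the matrix and are listed in the
#' `saturated` attribute.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, or an `msa` object from [progressive_msa()] /
#'   [build_supermatrix()].
#' @return Symmetric numeric matrix with zero diagonal; attributes
#'   `P`, `Q` (matrices of transition/transversion proportions) and
#'   `saturated` (2-column matrix of label pairs).
#' @export
distance_matrix <- function(alignment) {
  seqs <- if (inherits(alignment, "msa")) alignment$seqs else alignment
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("alignment needs unique ids")
  k <- length(seqs)
  D <- P <- Q <- matrix(0, k, k, dimnames = list(ids, ids))
  sat <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- kimura2p(seqs[[i]], seqs[[j]])
    D[i, j] <- D[j, i] <- r$d
    P[i, j] <- P[j, i] <- r$P
    Q[i, j] <- Q[j, i] <- r$Q
    if (r$saturated) sat <- rbind(sat, c(ids[i], ids[j]))
  }
  attr(D, "P") <- P
  attr(D, "Q") <- Q
  attr(D, "saturated") <- sat
  D
}

## ---- Nei-Gojobori (1986) -------------------------------------------------

#' Synonymous and nonsynonymous site counts of a codon
#'
#' At each of the three positions the fraction of one-step neighbours that
#' are synonymous is counted; neighbours that are stop codons are excluded
#' from the denominator, so each position contributes exactly one site and
#' `s + n = 3`.
#'
#' @param codon Sense codon (3-letter DNA string).
#' @param code A [genetic_code()].
#' @return Named numeric vector `s`, `n`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3
#' @export
ng86_sites <- function(codon, code = genetic_code(5)) {
  codon <- toupper(codon)
  aa <- code$codons[codon]
  if (is.na(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon has no site counts: ", codon)
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    nb <- vapply(setdiff(c("A", "C", "G", "T"), base), function(x) {
      z <- codon; substr(z, pos, pos) <- x; z
    }, character(1))
    nb_aa <- code$codons[nb]
    valid <- nb_aa != "*"
    if (!any(valid)) next
    s <- s + sum(nb_aa[valid] == aa) / sum(valid)
  }
  c(s = s, n = 3 - s)
}

# precomputed site counts for all sense codons of a code (memoised per
# translation table)
ng86_site_table <- local({
  cache <- list()
  function(code) {
    key <- as.character(code$id)
    if (is.null(cache[[key]])) {
      sense <- names(code$codons)[code$codons != "*"]
      cache[[key]] <<- t(vapply(sense, ng86_sites, c(s = 0, n = 0),
                                code = code))
    }
    cache[[key]]
  }
})

# synonymous/nonsynonymous differences between two codons, averaged over
# all minimal substitution pathways; pathways through stop codons excluded
# (falling back to all pathways when every one is blocked)
ng86_diffs <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- perms(pos)
  tally <- matrix(NA_real_, nrow(paths), 2)
  for (p in seq_len(nrow(paths))) {
    cur <- ca
    sd <- nd <- 0
    ok <- TRUE
    for (step in paths[p, ]) {
      nxt <- cur
      substr(nxt, step, step) <- substr(cb, step, step)
      if (code$codons[nxt] == "*") { ok <- FALSE; break }
      if (code$codons[nxt] == code$codons[cur]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) tally[p, ] <- c(sd, nd)
  }
  valid <- !is.na(tally[, 1])
  if (!any(valid)) {
    # every pathway passes through a stop; average over all of them,
    # counting the blocked steps by their amino-acid effect
    for (p in seq_len(nrow(paths))) {
      cur <- ca; sd <- nd <- 0
      for (step in paths[p, ]) {
        nxt <- cur
        substr(nxt, step, step) <- substr(cb, step, step)
        if (code$codons[nxt] == code$codons[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      tally[p, ] <- c(sd, nd)
    }
    valid <- rep(TRUE, nrow(paths))
  }
  c(sd = mean(tally[valid, 1]), nd = mean(tally[valid, 2]))
}

perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned pair of CDSs
#'
#' Site counts S and N are averaged over the two sequences; codon
#' differences are resolved by averaging the synonymous/nonsynonymous split
#' over all minimal substitution pathways (pathways through stop codons
#' excluded). Proportions pS = Sd/S and pN = Nd/N are Jukes-Cantor
#' corrected, `x -> -3/4 log(1 - 4x/3)`. A proportion >= 3/4 yields a
#' saturation marker; Ks = 0 yields an `NA` ratio.
#'
#' @param cds_a,cds_b Codon-aligned CDS strings (equal length, multiple of
#'   3; gap or ambiguous codons are dropped pairwise). Terminal stop codons
#'   are trimmed.
#' @param code A [genetic_code()].
#' @return Object of class `kaks`: list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka`, `ratio`, `codons` (compared codons), `saturated`.
#' @export
ng86_pair <- function(cds_a, cds_b, code = genetic_code(5)) {
  if (nchar(cds_a) != nchar(cds_b)) stop("CDSs differ in length")
  if (nchar(cds_a) %% 3L != 0L) stop("CDS length not a multiple of 3")
  ca <- codon_split(toupper(cds_a))
  cb <- codon_split(toupper(cds_b))
  sense <- function(x) !is.na(code$codons[x]) & code$codons[x] != "*"
  # trim a terminal stop codon if both carry one
  nc <- length(ca)
  if (nc && (!sense(ca[nc]) || !sense(cb[nc]))) {
    ca <- ca[-nc]; cb <- cb[-nc]
  }
  keep <- sense(ca) & sense(cb) &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no comparable codons")
  st <- ng86_site_table(code)
  S <- (sum(st[ca, "s"]) + sum(st[cb, "s"])) / 2
  N <- (sum(st[ca, "n"]) + sum(st[cb, "n"])) / 2
  di <- which(ca != cb)
  Sd <- Nd <- 0
  for (i in di) {
    d <- ng86_diffs(ca[i], cb[i], code)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, codons = length(ca),
                 saturated = is.na(Ks) || is.na(Ka)),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf(paste0("<kaks> %d codons: S=%.1f N=%.1f Sd=%.2f Nd=%.2f ",
                     "Ka=%.4f Ks=%.4f Ka/Ks=%s\n"),
              x$codons, x$S, x$N, x$Sd, x$Nd, x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Mean Ka, Ks and Ka/Ks of one gene across genomes
#'
#' Extracts the gene from every genome, builds a codon-aware alignment per
#' pair and averages the defined NG86 estimates over all pairs. Pairs with
#' saturated or undefined values are excluded and counted.
#'
#' @param genomes List of [mitogenome()] objects (>= 2 carrying the gene).
#' @param gene PCG symbol.
#' @param code A [genetic_code()].
#' @return List with `gene`, `mean_ka`, `mean_ks`, `mean_ratio`, `n_pairs`,
#'   `n_excluded`. All-`NA` means become `NA` (gene-level undefined).
#' @export
per_gene_kaks <- function(genomes, gene, code = genetic_code(5)) {
  has <- vapply(genomes, function(g) gene %in% g$features$gene, logical(1))
  genomes <- genomes[has]
  if (length(genomes) < 2L) stop("gene ", gene, " present in < 2 genomes")
  cds <- lapply(genomes, function(g) {
    f <- g$features[g$features$gene == gene, ]
    s <- extract_gene(g, gene)
    substr(s, f$codon_start[1], nchar(s))
  })
  ids <- vapply(genomes, `[[`, "", "id")
  ka <- ks <- ratio <- numeric(0)
  n_excluded <- 0L
  for (i in seq_len(length(cds) - 1L)) for (j in (i + 1L):length(cds)) {
    aln <- codon_aware_align(stats::setNames(cds[c(i, j)], ids[c(i, j)]),
                             code = code)
    r <- ng86_pair(aln$seqs[[1]], aln$seqs[[2]], code = code)
    if (is.na(r$ratio)) n_excluded <- n_excluded + 1L
    else ratio <- c(ratio, r$ratio)
    if (!is.na(r$Ka)) ka <- c(ka, r$Ka)
    if (!is.na(r$Ks)) ks <- c(ks, r$Ks)
  }
  list(gene = gene,
       mean_ka = if (length(ka)) mean(ka) else NA_real_,
       mean_ks = if (length(ks)) mean(ks) else NA_real_,
       mean_ratio = if (length(ratio)) mean(ratio) else NA_real_,
       n_pairs = length(ratio), n_excluded = n_excluded)
}
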