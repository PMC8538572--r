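#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-Gotoh alignment. Deterministic: at equal score the
#' diagonal (match/mismatch) move is preferred over a gap, and a gap in the
#' first sequence over a gap in the second. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param a,b Sequences (DNA or protein).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   negative).
#' @return List with aligned strings `a`, `b` and the alignment `score`.
#' @examples
#' global_align("ACGT", "AGT")$a
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  align_global_cpp(a, b, match, mismatch, gap_open, gap_extend)
}

# majority-rule consensus of an alignment profile (character matrix rows =
# sequences); gaps ignored, ties broken alphabetically; all-gap column -> N
profile_consensus <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
}

# expand a profile with gap columns so it matches its aligned consensus
expand_profile <- function(mat, aligned_consensus) {
  ch <- strsplit(aligned_consensus, "", fixed = TRUE)[[1]]
  out <- matrix("-", nrow(mat), length(ch),
                dimnames = list(rownames(mat), NULL))
  out[, ch != "-"] <- mat
  out
}

#' Progressive multiple sequence alignment
#'
#' Desk-scale progressive aligner: a guide tree is built by average-linkage
#' clustering of k-mer distances, then profiles are merged in guide-tree
#' order by aligning their majority consensus sequences with
#' [global_align()]. Deterministic given the input order and parameters.
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param k k-mer size for the guide distance.
#' @param ... Scoring parameters passed to [global_align()].
#' @return Object of class `msa`: list with `seqs` (named character vector
#'   of equal-length rows, input order preserved) and `partitions` (NULL
#'   for a single-gene alignment).
#' @export
progressive_msa <- function(seqs, k = 3, ...) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences need unique names")
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  profiles <- lapply(seqs, function(s)
    matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1))
  for (i in seq_len(n)) rownames(profiles[[i]]) <- names(seqs)[i]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  node <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    pick <- function(x) if (x < 0) profiles[[-x]] else node[[x]]
    p1 <- pick(hc$merge[step, 1])
    p2 <- pick(hc$merge[step, 2])
    c1 <- paste(profile_consensus(p1), collapse = "")
    c2 <- paste(profile_consensus(p2), collapse = "")
    al <- global_align(c1, c2, ...)
    node[[step]] <- rbind(expand_profile(p1, al$a), expand_profile(p2, al$b))
  }
  final <- node[[n - 1]]
  rows <- apply(final, 1, paste, collapse = "")
  structure(list(seqs = rows[names(seqs)], partitions = NULL),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns", length(x$seqs),
              nchar(x$seqs[[1]])))
  if (!is.null(x$partitions))
    cat(sprintf(", %d partitions", nrow(x$partitions)))
  cat("\n")
  invisible(x)
}

#' Codon-aware alignment of coding sequences
#'
#' Translates each CDS (terminal stop and incomplete-stop remainders
#' trimmed), aligns the proteins, and back-threads the nucleotide codons so
#' gaps occur only in multiples of three and every row stays in frame.
#'
#' @param cds_list Named character vector of CDSs (coding sense, frame 1).
#' @param code A [genetic_code()].
#' @param ... Scoring parameters passed to the protein alignment.
#' @return An `msa` object over the nucleotide codons.
#' @export
codon_aware_align <- function(cds_list, code = genetic_code(5), ...) {
  if (length(cds_list) < 2L) stop("need at least two sequences")
  prots <- vapply(names(cds_list), function(id) {
    tryCatch(translate_cds(cds_list[[id]], code = code)$protein,
             error = function(e)
               stop("cannot translate '", id, "': ", conditionMessage(e)))
  }, character(1))
  pal <- if (length(prots) == 2L) {
    al <- global_align(prots[[1]], prots[[2]], ...)
    stats::setNames(c(al$a, al$b), names(prots))
  } else progressive_msa(prots, ...)$seqs
  rows <- vapply(names(cds_list), function(id) {
    cods <- codon_split(cds_list[[id]])
    aa <- code$codons[cods]
    cods <- cods[is.na(aa) | aa != "*"]  # drop terminal stop codon
    cods <- cods[seq_len(nchar(pal[[id]]) - lengths(
      regmatches(pal[[id]], gregexpr("-", pal[[id]]))))]
    out <- character(nchar(pal[[id]]))
    ch <- strsplit(pal[[id]], "", fixed = TRUE)[[1]]
    out[ch == "-"] <- "---"
    out[ch != "-"] <- cods
    paste(out, collapse = "")
  }, character(1))
  structure(list(seqs = rows, partitions = NULL), class = "msa")
}

#' Build a concatenated multi-gene supermatrix
#'
#' Aligns each included gene across genomes (codon-aware for PCGs by
#' default, plain nucleotide for rRNA/tRNA) and concatenates the per-gene
#' alignments with a partition table. Genomes missing a gene get an all-gap
#' row for that partition, and the omission is recorded.
#'
#' @param genomes List of [mitogenome()] objects.
#' @param include Region classes to include, subset of
#'   `c("PCG", "rRNA", "tRNA")`.
#' @param codon_aware Align PCG partitions codon-aware.
#' @param code A [genetic_code()].
#' @return An `msa` with `partitions` (`data.frame`: gene, start, end;
#'   0-based half-open column ranges) and attribute `missing` (data.frame
#'   genome/gene of gap-filled entries).
#' @export
build_supermatrix <- function(genomes, include = c("PCG", "rRNA", "tRNA"),
                              codon_aware = TRUE, code = genetic_code(5)) {
  include <- match.arg(include, c("PCG", "rRNA", "tRNA"), several.ok = TRUE)
  cls_map <- c(PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA")
  ids <- vapply(genomes, `[[`, "", "id")
  genes <- unique(unlist(lapply(genomes, function(g)
    g$features$gene[g$features$class %in% cls_map[include] &
                      !g$features$warn])))
  genes <- ALL_SYMBOLS[ALL_SYMBOLS %in% genes]  # canonical order
  if (!length(genes)) stop("no shared genes across genomes")
  blocks <- list()
  missing <- NULL
  for (gene in genes) {
    has <- vapply(genomes, function(g) gene %in% g$features$gene, logical(1))
    seqs <- stats::setNames(lapply(genomes[has], function(g) {
      s <- extract_gene(g, gene)
      if (gene %in% PCG_SYMBOLS) {
        f <- g$features[g$features$gene == gene, ]
        s <- substr(s, f$codon_start[1], nchar(s))
      }
      s
    }), ids[has])
    seqs <- unlist(seqs)
    aln <- if (length(seqs) == 1L) seqs
    else if (gene %in% PCG_SYMBOLS && codon_aware)
      codon_aware_align(seqs, code = code)$seqs
    else progressive_msa(seqs)$seqs
    width <- nchar(aln[[1]])
    rows <- stats::setNames(rep(strrep("-", width), length(ids)), ids)
    rows[names(aln)] <- aln
    if (any(!has))
      missing <- rbind(missing, data.frame(genome = ids[!has], gene = gene))
    blocks[[gene]] <- rows
  }
  widths <- vapply(blocks, function(b) nchar(b[[1]]), integer(1))
  ends <- cumsum(widths)
  partitions <- data.frame(gene = names(blocks),
                           start = ends - widths, end = ends,
                           stringsAsFactors = FALSE)
  seqs <- vapply(ids, function(id) paste(vapply(blocks, `[[`, "", id),
                                         collapse = ""), character(1))
  out <- structure(list(seqs = seqs, partitions = partitions),
                   class = "msa")
  attr(out, "missing") <- missing
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (via [ape::nj()]); negative branch lengths
#' are clamped to zero with a warning. `NA` entries (e.g. saturated K2P
#' pairs) are an error listing the offending pairs.
#'
#' @param D Symmetric distance matrix with labels (as from
#'   [distance_matrix()]).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("undefined (saturated) distances for pairs: ",
         paste(rownames(D)[bad[, 1]], colnames(D)[bad[, 2]],
               sep = "-", collapse = ", "))
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and maps split frequencies (x 100) onto the internal
#' edges of the full-data tree. Reproducible under a fixed seed.
#'
#' @param alignment An `msa` or named character vector of aligned
#'   sequences (>= 4 rows).
#' @param n_replicates Number of bootstrap replicates (0 = no supports).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree; supports (percent) in `node.label`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1) {
  seqs <- if (inherits(alignment, "msa")) alignment$seqs else alignment
  if (length(seqs) < 4L) stop("need at least 4 sequences")
  main <- neighbor_joining(distance_matrix(seqs))
  if (n_replicates == 0L) return(main)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  L <- ncol(mat)
  set.seed(seed)
  trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- mat[, idx, drop = FALSE]
    reps <- stats::setNames(apply(sub, 1, paste, collapse = ""),
                            rownames(mat))
    trees[[r]] <- neighbor_joining(distance_matrix(reps))
  }
  counts <- ape::prop.clades(main, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / n_replicates, 1)
  main
}

#' Compare two (circular) gene orders
#'
#' Rotation-invariant identity test plus the breakpoint count: the number
#' of circular gene adjacencies of `order_a` absent from `order_b`
#' (adjacency taken as an unordered pair, strand signs ignored).
#'
#' @param order_a,order_b Character vectors of signed gene symbols over the
#'   same gene set (as from [gene_order()]).
#' @return List with `identical` (rotation-invariant, signs respected) and
#'   `breakpoint_count`.
#' @export
gene_order_compare <- function(order_a, order_b) {
  strip <- function(x) sub("^-", "", x)
  if (!setequal(strip(order_a), strip(order_b)))
    stop("gene sets differ: ",
         paste(c(setdiff(strip(order_a), strip(order_b)),
                 setdiff(strip(order_b), strip(order_a))), collapse = ", "))
  n <- length(order_a)
  ident <- FALSE
  for (r in seq_len(n)) {
    rot <- c(order_b[r:n], if (r > 1) order_b[seq_len(r - 1)])
    if (identical(order_a, rot)) { ident <- TRUE; break }
  }
  adj <- function(x) {
    g <- strip(x)
    nxt <- c(g[-1], g[1])
    paste(pmin(g, nxt), pmax(g, nxt), sep = "|")
  }
  bp <- sum(!adj(order_a) %in% adj(order_b))
  list(identical = ident, breakpoint_count = bp)
}
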