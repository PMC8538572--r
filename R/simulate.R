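## Synthetic mitogenome generator: circular ~15.5 kb genomes carrying the
## canonical 37 genes in the ancestral insect arrangement (14 genes on the
## minority/N chain), AT-rich composition with positive AT skew and negative
## GC skew on the majority strand, and lineages diverged on a known tree
## under a two-rate (transition/transversion) substitution process with
## per-gene nonsynonymous acceptance thinning (omega).

# canonical anticodons (DNA alphabet) used for the simulated tRNAs
TRNA_ANTICODON <- c(
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnD = "GTC", trnC = "GCA",
  trnQ = "TTG", trnE = "TTC", trnG = "TCC", trnH = "GTG", trnI = "GAT",
  trnK = "CTT", trnM = "CAT", trnF = "GAA", trnP = "TGG", trnT = "TGT",
  trnW = "TCA", trnY = "GTA", trnV = "TAC", trnL1 = "TAG", trnL2 = "TAA",
  trnS1 = "GCT", trnS2 = "TGA")

# realistic default CDS lengths (nt, incl. terminal stop; COI longest)
SIM_GENE_LENGTHS <- c(
  ND2 = 1023, COI = 1536, COII = 684, ATP8 = 159, ATP6 = 672, COIII = 789,
  ND3 = 351, ND5 = 1716, ND4 = 1341, ND4L = 291, ND6 = 498, CYTB = 1140,
  ND1 = 939, `16SRNA` = 1280, `12SRNA` = 775)

# default per-PCG omega, spanning strong purifying selection (COI) to
# relaxed (ND2), the qualitative pattern seen in insect mitogenomes
SIM_OMEGA <- c(COI = 0.05, COII = 0.10, COIII = 0.10, CYTB = 0.10,
               ATP6 = 0.15, ND1 = 0.20, ND3 = 0.25, ND4 = 0.25,
               ND5 = 0.25, ND4L = 0.30, ND6 = 0.35, ND2 = 0.45,
               ATP8 = 0.50)

#' Simulation parameters
#'
#' @param tree Newick string or [ape::phylo] with branch lengths in
#'   expected substitutions/site.
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param base_frequencies Named numeric vector (`A`, `T`, `G`, `C`)
#'   summing to 1; controls AT content and skew of the generated sequence.
#' @param per_gene_rate Named relative rate multipliers (genes absent from
#'   the map get 1; `".intergenic"` scales non-genic regions).
#' @param per_gene_omega Named nonsynonymous/synonymous acceptance ratios
#'   for PCGs; defaults span 0.05 (COI) to 0.5 (ATP8).
#' @param trna_perturbations Stem substitutions to inject per species (a
#'   single count recycled, or a vector named by leaf).
#' @param target_length Total genome length (nt).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(tree = "((A:0.02,B:0.03):0.04,(C:0.05,D:0.04):0.03);",
                       kappa = 2,
                       base_frequencies = c(A = 0.47, T = 0.27,
                                            G = 0.10, C = 0.16),
                       per_gene_rate = NULL,
                       per_gene_omega = SIM_OMEGA,
                       trna_perturbations = 0L,
                       target_length = 15500L,
                       seed = 1L) {
  stopifnot(abs(sum(base_frequencies) - 1) < 1e-12,
            all(base_frequencies >= 0), kappa >= 0,
            all(per_gene_omega >= 0))
  if (!is.null(per_gene_rate) && any(per_gene_rate < 0))
    stop("rates must be >= 0")
  structure(list(tree = tree, kappa = kappa,
                 base_frequencies = base_frequencies[c("A", "T", "G", "C")],
                 per_gene_rate = per_gene_rate,
                 per_gene_omega = per_gene_omega,
                 trna_perturbations = trna_perturbations,
                 target_length = as.integer(target_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

random_bases <- function(n, freqs) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = freqs)
}

# Sense-codon sampling weights whose marginal base composition equals the
# requested frequencies. Independent per-base weights miss the target
# because the AT-rich stop codons are excluded; iterative proportional
# fitting on the per-position weights corrects for that.
codon_weights <- function(freqs, code) {
  sense <- names(code$codons)[code$codons != "*"]
  mat <- do.call(rbind, strsplit(sense, ""))
  q <- freqs
  for (it in 1:60) {
    w <- q[mat[, 1]] * q[mat[, 2]] * q[mat[, 3]]
    w <- w / sum(w)
    marg <- (tapply(w, mat[, 1], sum) + tapply(w, mat[, 2], sum) +
               tapply(w, mat[, 3], sum)) / 3
    q <- q * (freqs / marg[names(freqs)])^0.8
    q <- q / sum(q)
  }
  stats::setNames(as.numeric(w), sense)
}

# one PCG: ATN start, composition-calibrated sense codons, TAA/TAG stop
sim_cds <- function(len, freqs, code) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len %/% 3 - 2L
  w <- codon_weights(freqs, code)
  start <- paste0("AT", sample(c("A", "T", "G", "C"), 1,
                               prob = freqs[c("A", "T", "G", "C")]))
  body <- sample(names(w), ncod, replace = TRUE, prob = w)
  stop <- sample(c("TAA", "TAG"), 1, prob = c(0.8, 0.2))
  paste0(start, paste(body, collapse = ""), stop)
}

# One pair-perfect cloverleaf tRNA; returns sequence + its true layout.
# Rejection sampling guarantees the constructed layout is the fold's unique
# optimum with a margin of >= 2 score points over every alternative pairing
# (2 is the attainable maximum: a stem always has a sub-stem layout realizing
# the same pairs minus the terminal one, i.e. one WC pair = 2 points less).
# A single WC -> G:T wobble substitution costs only 1 point, and acceptor-stem
# perturbations hit every candidate layout equally, so the fold recovers the
# constructed pairing exactly under either kind of single perturbation used
# in the fixtures and tests.
sim_trna <- function(gene, freqs) {
  dhu_absent <- gene == "trnS1"
  for (try in 1:100) {
    layout <- list(s1 = 2L, d = if (dhu_absent) 0L else sample(3:4, 1),
                   ld = sample(6:8, 1), s2 = 1L, lv = sample(4:5, 1),
                   t = sample(3:4, 1), lt = 7L)
    if (dhu_absent) layout$ld <- sample(8:10, 1)
    n <- 32L + layout$s1 + 2L * layout$d + layout$ld + layout$s2 +
      layout$lv + 2L * layout$t + layout$lt
    b <- random_bases(n, freqs)
    # tRNA-Ser(AGN): purine-only DHU-replacement loop (as in real metazoan
    # mt-tRNAs), which also cannot base-pair into a spurious DHU stem
    if (dhu_absent)
      b[8L:(7L + layout$s1 + layout$ld + layout$s2)] <- "A"
    # anticodon at the centre of the anticodon loop
    ac_start <- 7L + layout$s1 + 2L * layout$d + layout$ld + layout$s2 + 8L
    b[ac_start:(ac_start + 2L)] <-
      strsplit(TRNA_ANTICODON[[gene]], "")[[1]]
    comp <- c(A = "T", T = "A", G = "C", C = "G")
    arms <- layout_arms(layout, n)
    for (a in arms) for (k in seq_len(nrow(a)))
      b[a$pos3[k]] <- comp[[b[a$pos5[k]]]]
    s <- paste(b, collapse = "")
    cl <- tryCatch(
      fold_cloverleaf(s, anticodon = TRNA_ANTICODON[[gene]],
                      allow_dhu_absent = dhu_absent),
      error = function(e) NULL)
    if (is.null(cl)) next
    # the fold must realize exactly the constructed pairing, all WC
    same_pairing <- identical(
      lapply(cl$arms, function(a) a[, c("pos5", "pos3")]),
      lapply(arms, function(a) a[, c("pos5", "pos3")]))
    if (!same_pairing) next
    if (any(vapply(cl$arms, function(a)
      nrow(a) > 0 && any(a$class != "WC"), logical(1)))) next
    # margin: every layout with a different pairing scores >= 2 below
    other <- cl$candidates[cl$candidates$sig != cl$candidates$sig[1], ]
    if (nrow(other) == 0L || max(other$score) <= cl$score - 2)
      return(list(seq = s, layout = layout, length = n))
  }
  stop("could not construct an unambiguous cloverleaf for ", gene)
}

#' Simulate a root mitogenome
#'
#' Builds a circular genome with the 37 canonical genes in the ancestral
#' arrangement and strand split, protein-coding genes as valid
#' translation-table-5 ORFs (ATN start, TAA/TAG stop, no internal stops),
#' tRNAs pair-perfect on the cloverleaf template, rRNAs and intergenic
#' spacers as composition-matched random sequence, and an AT-rich
#' control-region filler bringing the molecule to `target_length`.
#'
#' @param params A [sim_params()].
#' @param id,organism Identifier and organism label.
#' @return A [mitogenome()]; attribute `truth` holds the generated tRNA
#'   layouts.
#' @export
simulate_root_genome <- function(params = sim_params(), id = "SIM_ROOT",
                                 organism = "Synthetica exemplaris") {
  set.seed(params$seed)
  freqs <- params$base_frequencies
  code <- genetic_code(5)
  segments <- list()
  truth <- list()
  for (entry in ANCESTRAL_ORDER) {
    strand <- if (startsWith(entry, "-")) "N" else "J"
    gene <- sub("^-", "", entry)
    cls <- feature_class_for(gene)
    s <- if (cls == "CDS") sim_cds(SIM_GENE_LENGTHS[[gene]], freqs, code)
    else if (cls == "rRNA")
      paste(random_bases(SIM_GENE_LENGTHS[[gene]], freqs), collapse = "")
    else {
      tr <- sim_trna(gene, freqs)
      truth$trna[[gene]] <- tr$layout
      tr$seq
    }
    segments[[length(segments) + 1L]] <-
      list(type = "gene", gene = gene, class = cls, strand = strand,
           seq = s)
    spacer <- sample(0:5, 1)
    if (spacer > 0)
      segments[[length(segments) + 1L]] <-
        list(type = "spacer", seq = paste(random_bases(spacer, freqs),
                                          collapse = ""))
  }
  used <- sum(vapply(segments, function(s) nchar(s$seq), integer(1)))
  cr_len <- params$target_length - used
  if (cr_len < 0)
    stop("target_length ", params$target_length,
         " too short for the gene complement (needs >= ", used, ")")
  # AT-rich control-region stand-in at the end of the molecule
  # (between 12SRNA and trnI on the circle)
  cr_freqs <- c(A = 0.42, T = 0.38, G = 0.08, C = 0.12)
  if (cr_len > 0)
    segments[[length(segments) + 1L]] <-
      list(type = "control_region",
           seq = paste(random_bases(cr_len, cr_freqs), collapse = ""))
  assemble_genome(segments, id = id, organism = organism, truth = truth)
}

assemble_genome <- function(segments, id, organism, truth = NULL) {
  pos <- 0L
  feats <- list()
  chunks <- character(length(segments))
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    s <- if (!is.null(sg$strand) && sg$strand == "N") revcomp(sg$seq)
         else sg$seq
    chunks[i] <- s
    if (sg$type == "gene") {
      feats[[length(feats) + 1L]] <- data.frame(
        gene = sg$gene, class = sg$class, start = pos,
        end = pos + nchar(s), strand = sg$strand, codon_start = 1L,
        start2 = NA_integer_, end2 = NA_integer_,
        anticodon = if (sg$class == "tRNA") TRNA_ANTICODON[[sg$gene]]
                    else NA_character_,
        warn = FALSE, stringsAsFactors = FALSE)
    }
    pos <- pos + nchar(s)
  }
  g <- mitogenome(id = id, sequence = paste(chunks, collapse = ""),
                  features = do.call(rbind, feats), organism = organism,
                  circular = TRUE)
  attr(g, "truth") <- truth
  attr(g, "segments") <- segments
  g
}

#' Evolve a sequence under the two-rate substitution process
#'
#' Sites accumulate Poisson(`distance`) substitution events; each event is
#' a transition with probability kappa/(kappa + 2), otherwise one of the
#' two transversions. This is the neutral engine used for rRNA, tRNA and
#' intergenic sequence.
#'
#' @param seq DNA string.
#' @param distance Expected substitutions per site (branch length x rate).
#' @param kappa Transition/transversion rate ratio.
#' @return Evolved DNA string.
#' @export
evolve_sequence <- function(seq, distance, kappa = 2) {
  if (distance <= 0) return(seq)
  b <- seq_chars(seq)
  nev <- stats::rpois(length(b), distance)
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  while (any(nev > 0L)) {
    act <- which(nev > 0L)
    ts <- stats::runif(length(act)) < kappa / (kappa + 2)
    pick2 <- stats::runif(length(act)) < 0.5
    cur <- b[act]
    b[act] <- ifelse(ts, TRANSITION[cur],
                     ifelse(pick2, tv1[cur], tv2[cur]))
    nev[act] <- nev[act] - 1L
  }
  paste(b, collapse = "")
}

# Evolve a CDS with acceptance thinning of nonsynonymous events; the ORF is
# kept stop-free (events creating or destroying a stop codon are rejected).
# "Synonymous" here means preserving the synonymous codon family (the same
# partition used for RSCU, with Leu and Ser split): a Leu1 <-> Leu2 flip is
# thinned like a nonsynonymous event. Family-preserving changes only ever
# differ at the third codon position, so under omega = 0 every pathway
# between two evolved codons is synonymous and NG86 Ka is exactly zero.
evolve_cds_seq <- function(seq, distance, kappa, omega, code) {
  if (distance <= 0) return(seq)
  b <- seq_chars(seq)
  nev <- stats::rpois(length(b), distance)
  sites <- rep(which(nev > 0L), nev[nev > 0L])
  if (!length(sites)) return(seq)
  sites <- sample(sites)  # randomise event order across sites
  p_ts <- kappa / (kappa + 2)
  for (i in sites) {
    cur <- b[i]
    new <- if (stats::runif(1) < p_ts) TRANSITION[[cur]]
           else sample(TRANSVERSIONS[[cur]], 1)
    ci <- (i - 1L) %/% 3L
    idx <- (3L * ci + 1L):(3L * ci + 3L)
    cod_old <- paste(b[idx], collapse = "")
    cod_new <- cod_old
    substr(cod_new, i - 3L * ci, i - 3L * ci) <- new
    aa_old <- code$codons[[cod_old]]
    aa_new <- code$codons[[cod_new]]
    if (aa_old == "*") {
      if (aa_new != "*") next  # keep the stop codon a stop
    } else {
      if (aa_new == "*") next  # no premature stops
      if (code$families[[cod_new]] != code$families[[cod_old]] &&
          stats::runif(1) >= omega) next
    }
    b[i] <- new
  }
  paste(b, collapse = "")
}

#' Evolve a root mitogenome along a tree
#'
#' Every feature evolves on its coding-sense sequence: CDSs under the
#' omega-thinned codon process (so a gene with omega = 0 accumulates no
#' amino-acid changes), all other segments neutrally; per-gene rate
#' multipliers scale branch lengths. Annotations carry over unchanged
#' (the generator introduces no indels or rearrangements).
#'
#' @param root A genome from [simulate_root_genome()].
#' @param params The same [sim_params()].
#' @return Named list of leaf [mitogenome()]s (tree tip labels as ids).
#' @export
evolve_on_tree <- function(root, params) {
  tree <- if (inherits(params$tree, "phylo")) params$tree
          else ape::read.tree(text = params$tree)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  set.seed(params$seed + 1L)
  code <- genetic_code(5)
  segments <- attr(root, "segments")
  if (is.null(segments)) stop("root genome lacks generator segments")
  rate_for <- function(sg) {
    key <- if (sg$type == "gene") sg$gene else ".intergenic"
    r <- params$per_gene_rate[[key]]
    if (is.null(r)) 1 else r
  }
  evolve_segments <- function(segs, bl) {
    lapply(segs, function(sg) {
      d <- bl * rate_for(sg)
      sg$seq <- if (sg$type == "gene" && sg$class == "CDS") {
        om <- params$per_gene_omega[[sg$gene]]
        evolve_cds_seq(sg$seq, d, params$kappa,
                       if (is.null(om)) 1 else om, code)
      } else evolve_sequence(sg$seq, d, params$kappa)
      sg
    })
  }
  tree <- stats::reorder(tree, "cladewise")  # preorder edge traversal
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- segments  # root node
  ord <- seq_len(nrow(tree$edge))
  leaves <- list()
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    st <- evolve_segments(states[[parent]], tree$edge.length[e])
    if (child <= ntip) {
      lab <- tree$tip.label[child]
      leaves[[lab]] <- assemble_genome(st, id = lab,
                                       organism = paste("Synthetica", lab),
                                       truth = attr(root, "truth"))
    } else states[[child]] <- st
  }
  leaves[tree$tip.label]
}

#' Inject wobble perturbations into a genome's tRNA stems
#'
#' Replaces the 5' base of `k` Watson-Crick stem pairs (chosen across
#' tRNAs and arms, at most one per tRNA until all are used) so each becomes
#' a G-U wobble pair. Used by [fixture_suite()] to plant a known number of
#' non-WC pairs recoverable by [mismatch_profile()].
#'
#' @param genome A simulated [mitogenome()] carrying generator truth.
#' @param k Number of perturbations.
#' @return The modified genome; attribute `n_injected` records the count.
#' @export
inject_trna_wobbles <- function(genome, k) {
  truth <- attr(genome, "truth")
  if (is.null(truth)) stop("genome lacks generator truth")
  segments <- attr(genome, "segments")
  if (k == 0) { attr(genome, "n_injected") <- 0L; return(genome) }
  f <- genome$features[genome$features$class == "tRNA", ]
  # candidate pairs: (gene, arm row) whose 3' base is T or G, so replacing
  # the 5' base yields G:T or T:G
  cands <- list()
  for (gene in f$gene) {
    lay <- truth$trna[[gene]]
    s <- extract_gene(genome, gene)
    b <- seq_chars(s)
    arms <- layout_arms(lay, nchar(s))
    for (an in names(arms)) {
      a <- arms[[an]]
      for (r in seq_len(nrow(a))) {
        b3 <- b[a$pos3[r]]
        b5 <- b[a$pos5[r]]
        want <- if (b3 == "T") "G" else if (b3 == "G") "T" else NA
        if (!is.na(want) && b5 != want &&
            pair_class(b5, b3) == "WC")
          cands[[length(cands) + 1L]] <-
            list(gene = gene, pos = a$pos5[r], new = want)
      }
    }
  }
  if (length(cands) < k) stop("not enough perturbable WC pairs")
  genes <- vapply(cands, `[[`, "", "gene")
  # spread across tRNAs: take one per gene first, then wrap around
  sel <- order(ave(seq_along(genes), genes, FUN = seq_along),
               match(genes, unique(genes)))[seq_len(k)]
  for (ci in sel) {
    cd <- cands[[ci]]
    genome <- set_gene_base(genome, cd$gene, cd$pos, cd$new)
  }
  attr(genome, "truth") <- truth
  attr(genome, "segments") <- NULL  # sequence edited outside segments
  attr(genome, "n_injected") <- as.integer(k)
  genome
}

# overwrite one base of a gene, given coding-sense position (1-based)
set_gene_base <- function(genome, gene, pos, base) {
  f <- genome$features[genome$features$gene == gene, ]
  if (f$strand[1] == "J") {
    gpos <- f$start[1] + pos
    nb <- base
  } else {
    gpos <- f$end[1] - pos + 1L
    nb <- revcomp(base)
  }
  substr(genome$sequence, gpos, gpos) <- nb
  genome
}

#' Write a packaged fixture suite of simulated mitogenomes
#'
#' Simulates an 8-leaf clade (mirroring a small comparative study), injects
#' per-species tRNA stem wobbles, and writes one GenBank and one FASTA file
#' per leaf plus a `manifest.json` of generator ground truth (tree, true
#' pairwise path lengths, per-gene omega, injected perturbation counts).
#' Regeneration with the same seed is byte-identical. The tRNA substitution
#' rate is zero in this suite so the injected counts are exactly the
#' genomes' non-WC stem pair counts.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with `params`, `genomes`, `manifest`.
#' @export
fixture_suite <- function(dir, seed = 1L) {
  tree <- paste0("(((S1:0.015,S2:0.02):0.03,(S3:0.03,S4:0.025):0.025):0.04,",
                 "((S5:0.04,S6:0.03):0.03,(S7:0.05,S8:0.04):0.02):0.035);")
  trna_rate <- stats::setNames(rep(0, length(TRNA_SYMBOLS)), TRNA_SYMBOLS)
  perturb <- stats::setNames(c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 8L),
                             paste0("S", 1:8))
  params <- sim_params(tree = tree, kappa = 2,
                       per_gene_rate = as.list(trna_rate),
                       trna_perturbations = perturb, seed = seed)
  root <- simulate_root_genome(params)
  leaves <- evolve_on_tree(root, params)
  set.seed(params$seed + 2L)
  leaves <- lapply(names(leaves), function(lab)
    inject_trna_wobbles(leaves[[lab]], perturb[[lab]]))
  names(leaves) <- names(perturb)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(leaves)) {
    write_genbank(leaves[[lab]], file.path(dir, paste0(lab, ".gb")))
    write_fasta(stats::setNames(leaves[[lab]]$sequence, lab),
                file.path(dir, paste0(lab, ".fasta")))
  }
  phy <- ape::read.tree(text = tree)
  true_d <- ape::cophenetic.phylo(phy)
  true_d <- true_d[names(leaves), names(leaves)]
  manifest <- list(
    seed = seed, tree = tree, species = names(leaves),
    genome_length = stats::setNames(
      vapply(leaves, function(g) nchar(g$sequence), integer(1)),
      names(leaves)),
    n_cds = 13L, n_trna = 22L, n_rrna = 2L,
    gene_order = gene_order(root),
    kappa = params$kappa,
    base_frequencies = as.list(params$base_frequencies),
    per_gene_omega = as.list(params$per_gene_omega),
    trna_perturbations = as.list(perturb),
    true_distances = as.data.frame(true_d))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(params = params, genomes = leaves, manifest = manifest))
}
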