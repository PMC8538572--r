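#' Classify an RNA stem base pair
#'
#' Watson-Crick pairs are A:T, T:A, G:C, C:G; G:T and T:G are G-U wobble
#' pairs; everything else is a mismatch. (Sequences are handled in the DNA
#' alphabet; T stands for U.)
#'
#' @param b5,b3 Single bases on the 5' and 3' side of the pair.
#' @return `"WC"`, `"GU"` or `"mismatch"` (vectorised).
#' @export
pair_class <- function(b5, b3) {
  p <- paste0(toupper(b5), toupper(b3))
  ifelse(p %in% c("AT", "TA", "GC", "CG"), "WC",
         ifelse(p %in% c("GT", "TG"), "GU", "mismatch"))
}

PAIR_SCORE <- c(WC = 2, GU = 1, mismatch = -1)

## Canonical cloverleaf geometry: acceptor stem 7 pairs anchored at the
## termini with one unpaired discriminator base at the 3' end; anticodon
## stem 5 pairs around a 7-nt loop with the anticodon at its centre; DHU and
## TPsiC stems 2-4 pairs. The remaining segment lengths are enumerated.
CLOVERLEAF_BOUNDS <- list(
  s1 = 1:3,      # spacer between acceptor stem and DHU arm
  d = 2:4,       # DHU stem pairs (0 = arm absent)
  ld = 3:10,     # DHU loop
  s2 = 0:2,      # spacer between DHU arm and anticodon arm
  lv = 3:9,      # variable loop
  t = 2:4,       # TPsiC stem pairs
  lt = 3:9)      # TPsiC loop

#' Fold a tRNA sequence onto the cloverleaf template
#'
#' Deterministic template-constrained folding: the acceptor stem (7 pairs)
#' is anchored at the 5' and 3' termini (one unpaired discriminator base at
#' the 3' end), the anticodon stem is fixed at 5 pairs around a 7-nt loop,
#' and all combinations of DHU stem (2-4 pairs, or absent), TPsiC stem
#' (2-4 pairs), loop and spacer lengths consistent with the sequence length
#' are enumerated. Each candidate is scored
#' `2 x #WC + 1 x #GU - 1 x #mismatch` over its stem pairs; ties are broken
#' by more acceptor-stem WC pairs, then smaller variable loop, then the
#' 5'-most DHU stem, then the remaining layout parameters in order. The
#' search is exhaustive, so identical input always yields the identical
#' structure.
#'
#' @param seq tRNA sequence (55-80 nt; DNA alphabet).
#' @param anticodon Optional anticodon triplet; when given, only layouts
#'   placing it at the centre of the anticodon loop are considered.
#' @param allow_dhu_absent Consider DHU-less layouts (the mitochondrial
#'   tRNA-Ser(AGN) lacks the DHU arm; all other tRNAs should keep the
#'   default `FALSE` here via [mismatch_profile()]).
#' @return Object of class `cloverleaf`: list with `length`, `layout`
#'   (named integer vector of segment lengths), `arms` (named list of
#'   data.frames `pos5`, `pos3`, `base5`, `base3`, `class`; positions
#'   1-based), `anticodon`, `dhu_absent`, `score` and `candidates` (all
#'   scored layouts).
#' @export
fold_cloverleaf <- function(seq, anticodon = NULL, allow_dhu_absent = FALSE) {
  s <- chartr("uU", "tT", toupper(seq))
  n <- nchar(s)
  if (n < 55 || n > 80)
    stop("tRNA length ", n, " outside supported range 55-80")
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  dvals <- if (allow_dhu_absent) c(0L, CLOVERLEAF_BOUNDS$d)
           else CLOVERLEAF_BOUNDS$d
  grid <- expand.grid(s1 = CLOVERLEAF_BOUNDS$s1, d = dvals,
                      ld = CLOVERLEAF_BOUNDS$ld, s2 = CLOVERLEAF_BOUNDS$s2,
                      lv = CLOVERLEAF_BOUNDS$lv, t = CLOVERLEAF_BOUNDS$t,
                      lt = CLOVERLEAF_BOUNDS$lt)
  grid <- grid[32L + grid$s1 + 2L * grid$d + grid$ld + grid$s2 + grid$lv +
                 2L * grid$t + grid$lt == n, , drop = FALSE]
  if (!nrow(grid)) stop("no cloverleaf layout fits sequence of length ", n)
  if (!is.null(anticodon)) {
    ac <- toupper(chartr("uU", "tT", anticodon))
    ac_start <- 7L + grid$s1 + 2L * grid$d + grid$ld + grid$s2 + 5L + 3L
    keep <- substring(s, ac_start, ac_start + 2L) == ac
    grid <- grid[keep, , drop = FALSE]
    if (!nrow(grid))
      stop("no cloverleaf layout places anticodon ", ac,
           " at the loop centre")
  }
  codes <- match(b, c("A", "C", "G", "T"), nomatch = 0L)
  sc <- score_layouts_cpp(codes, as.matrix(grid))
  colnames(sc) <- c("score", "acc_wc")
  ord <- order(-sc[, "score"], -sc[, "acc_wc"], grid$lv, grid$s1,
               grid$d, grid$ld, grid$s2, grid$t, grid$lt)
  best <- grid[ord[1], ]
  arms <- layout_arms(best, n)
  arms <- lapply(arms, function(a) {
    if (!nrow(a)) return(a)
    a$base5 <- b[a$pos5]; a$base3 <- b[a$pos3]
    a$class <- pair_class(a$base5, a$base3)
    a
  })
  ac_start <- 7L + best[["s1"]] + 2L * best[["d"]] + best[["ld"]] + best[["s2"]] + 5L + 3L
  structure(list(
    length = n,
    layout = stats::setNames(as.integer(unlist(best)), names(best)),
    arms = arms,
    anticodon = substr(s, ac_start, ac_start + 2L),
    variable_loop = as.integer(best[["lv"]]),
    dhu_absent = best[["d"]] == 0L,
    score = unname(sc[ord[1], "score"]),
    candidates = {
      # pairing signature: layouts sharing it realize identical stem pairs
      # (e.g. the ld/s2 split is degenerate when d = 0)
      P <- 7L + grid$s1 + 2L * grid$d + grid$ld + grid$s2
      dstart <- ifelse(grid$d > 0, 7L + grid$s1, 0L)
      cbind(grid, sc,
            sig = paste(grid$d, dstart, P, P + 17L + grid$lv, grid$t,
                        sep = "/"))[ord, , drop = FALSE]
    },
    sequence = s), class = "cloverleaf")
}

# pair tables (pos5 < pos3, 1-based) for a layout over a length-n sequence
layout_arms <- function(g, n) {
  pairs_df <- function(p5, p3) data.frame(pos5 = as.integer(p5),
                                          pos3 = as.integer(p3))
  acc <- pairs_df(1:7, n - (1:7))
  pos <- 7L + g[["s1"]]
  dhu <- if (g[["d"]] > 0) {
    d5 <- pos + seq_len(g[["d"]])
    d3 <- pos + g[["d"]] + g[["ld"]] + g[["d"]] + 1L - seq_len(g[["d"]])
    pairs_df(d5, d3)
  } else pairs_df(integer(0), integer(0))
  pos <- pos + 2L * g[["d"]] + g[["ld"]] + g[["s2"]]
  ac5 <- pos + 1:5
  ac3 <- pos + 5L + 7L + 5L + 1L - (1:5)
  antic <- pairs_df(ac5, ac3)
  pos <- pos + 17L + g[["lv"]]
  t5 <- pos + seq_len(g[["t"]])
  t3 <- pos + g[["t"]] + g[["lt"]] + g[["t"]] + 1L - seq_len(g[["t"]])
  tps <- pairs_df(t5, t3)
  list(acceptor = acc, dhu = dhu, anticodon = antic, tpsic = tps)
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat(sprintf("<cloverleaf> %d nt, anticodon %s, score %g%s\n", x$length,
              x$anticodon, x$score,
              if (x$dhu_absent) ", DHU arm absent" else ""))
  for (a in names(x$arms)) {
    d <- x$arms[[a]]
    if (!nrow(d)) { cat(sprintf("  %-9s absent\n", a)); next }
    cat(sprintf("  %-9s %d pairs (%d WC, %d GU, %d mismatch)\n", a,
                nrow(d), sum(d$class == "WC"), sum(d$class == "GU"),
                sum(d$class == "mismatch")))
  }
  invisible(x)
}

#' Dot-bracket string of a cloverleaf structure
#'
#' @param x A `cloverleaf` from [fold_cloverleaf()] or
#'   [parse_structure_string()].
#' @return Dot-bracket string of the same length as the sequence.
#' @export
structure_string <- function(x) {
  db <- rep(".", x$length)
  for (a in x$arms) {
    if (!nrow(a)) next
    db[a$pos5] <- "("
    db[a$pos3] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse a dot-bracket secondary structure into a cloverleaf
#'
#' Accepts externally predicted structures (e.g. from tRNAscan-SE or MITOS)
#' for cross-checking the built-in folder. The four (or, without a DHU arm,
#' three) helices are identified from the nesting structure: the enclosing
#' helix is the acceptor stem and the inner hairpins, in 5' order, are the
#' DHU, anticodon and TPsiC arms.
#'
#' @param seq Sequence (same length as `structure`).
#' @param structure Dot-bracket string using `(`, `)` and `.`.
#' @return A `cloverleaf` object (without score/candidates).
#' @export
parse_structure_string <- function(seq, structure) {
  s <- chartr("uU", "tT", toupper(seq))
  if (nchar(s) != nchar(structure))
    stop("sequence and structure lengths differ")
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("structure contains symbols other than '(', ')', '.'")
  stack <- integer(0)
  mate <- rep(NA_integer_, length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      mate[i] <- j; mate[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure string")
  opens <- which(ch == "(")
  helix_id <- integer(length(opens))
  hid <- 0L
  for (k in seq_along(opens)) {
    i <- opens[k]
    if (k > 1 && opens[k - 1] == i - 1L && mate[i] == mate[i - 1L] - 1L)
      helix_id[k] <- hid
    else { hid <- hid + 1L; helix_id[k] <- hid }
  }
  helices <- lapply(split(opens, helix_id), function(p5)
    data.frame(pos5 = as.integer(p5), pos3 = as.integer(mate[p5])))
  if (length(helices) < 3 || length(helices) > 4)
    stop("expected 3-4 stems in a cloverleaf, found ", length(helices))
  span_min <- vapply(helices, function(h) min(h$pos5), integer(1))
  outer <- which.min(span_min)
  inner <- helices[setdiff(seq_along(helices), outer)]
  inner <- inner[order(vapply(inner, function(h) min(h$pos5), integer(1)))]
  dhu_absent <- length(inner) == 2L
  arms <- list(acceptor = helices[[outer]],
               dhu = if (dhu_absent)
                 data.frame(pos5 = integer(0), pos3 = integer(0))
               else inner[[1]],
               anticodon = if (dhu_absent) inner[[1]] else inner[[2]],
               tpsic = if (dhu_absent) inner[[2]] else inner[[3]])
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  arms <- lapply(arms, function(a) {
    if (!nrow(a)) return(a)
    a$base5 <- b[a$pos5]; a$base3 <- b[a$pos3]
    a$class <- pair_class(a$base5, a$base3)
    a
  })
  ac <- arms$anticodon
  loop_start <- max(ac$pos5) + 1L
  loop_len <- min(ac$pos3) - loop_start
  ac_center <- loop_start + (loop_len - 3L) %/% 2L
  structure(list(length = nchar(s), layout = NULL, arms = arms,
                 anticodon = substr(s, ac_center, ac_center + 2L),
                 variable_loop = NA_integer_,
                 dhu_absent = dhu_absent, score = NA_real_,
                 candidates = NULL, sequence = s),
            class = "cloverleaf")
}

#' Per-arm tRNA mismatch profile across genomes
#'
#' Folds the 22 tRNAs of each genome with [fold_cloverleaf()] (DHU-less
#' layouts are allowed only for tRNA-Ser(AGN)) and tallies the non-WC stem
#' pairs per arm. Because published tables of this kind conflate G-U wobble
#' pairs with true mismatches, both readings are reported: `nonwc` counts
#' all non-Watson-Crick pairs (G-U included) and `strict` counts only
#' non-WC, non-GU pairs. The grand total of G-U pairs over all species is
#' returned alongside.
#'
#' @param genomes List of [mitogenome()] objects.
#' @return List with `nonwc` and `strict` (`data.frame`s: species, acceptor,
#'   DHU, TPsiC, anticodon, sum), `gu_total`, and `failures` (per-species
#'   character vectors of tRNAs that could not be folded; a species with
#'   failures is marked in `partial`).
#' @export
mismatch_profile <- function(genomes) {
  arms_order <- c("acceptor", "dhu", "tpsic", "anticodon")
  rows_nonwc <- list(); rows_strict <- list()
  gu_total <- 0L
  failures <- list()
  for (gn in genomes) {
    f <- gn$features[gn$features$class == "tRNA" & !gn$features$warn, ]
    cnt_nonwc <- stats::setNames(integer(4), arms_order)
    cnt_strict <- stats::setNames(integer(4), arms_order)
    fails <- character(0)
    for (i in seq_len(nrow(f))) {
      seqt <- extract_gene(gn, f$gene[i])
      ac <- if (!is.na(f$anticodon[i])) f$anticodon[i] else NULL
      cl <- tryCatch(
        fold_cloverleaf(seqt, anticodon = ac,
                        allow_dhu_absent = f$gene[i] == "trnS1"),
        error = function(e) NULL)
      if (is.null(cl)) { fails <- c(fails, f$gene[i]); next }
      for (a in arms_order) {
        d <- cl$arms[[a]]
        if (!nrow(d)) next
        cnt_nonwc[a] <- cnt_nonwc[a] + sum(d$class != "WC")
        cnt_strict[a] <- cnt_strict[a] + sum(d$class == "mismatch")
        gu_total <- gu_total + sum(d$class == "GU")
      }
    }
    mk <- function(cnt) data.frame(
      species = gn$id, acceptor = cnt[["acceptor"]], DHU = cnt[["dhu"]],
      TPsiC = cnt[["tpsic"]], anticodon = cnt[["anticodon"]],
      sum = sum(cnt), partial = length(fails) > 0,
      stringsAsFactors = FALSE)
    rows_nonwc[[gn$id]] <- mk(cnt_nonwc)
    rows_strict[[gn$id]] <- mk(cnt_strict)
    if (length(fails)) failures[[gn$id]] <- fails
  }
  nonwc <- do.call(rbind, rows_nonwc); rownames(nonwc) <- NULL
  strict <- do.call(rbind, rows_strict); rownames(strict) <- NULL
  list(nonwc = nonwc, strict = strict, gu_total = gu_total,
       failures = failures)
}
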