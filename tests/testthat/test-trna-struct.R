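test_that("pair classification partitions all 16 base pairs", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b5 = bases, b3 = bases, stringsAsFactors = FALSE)
  cls <- pair_class(grid$b5, grid$b3)
  expect_identical(sum(cls == "WC"), 4L)
  expect_identical(sum(cls == "GU"), 2L)
  expect_identical(sum(cls == "mismatch"), 10L)
})

test_that("fold recovers generator-built cloverleafs exactly", {
  fx <- get_fixture()
  g <- fx$genomes[[1]]  # zero injected perturbations
  truth <- attr(fx$fs$genomes$S1, "truth")$trna
  for (gene in c("trnI", "trnM", "trnS1", "trnS2", "trnL1")) {
    s <- extract_gene(g, gene)
    cl <- fold_cloverleaf(s, anticodon = mitocomp:::TRNA_ANTICODON[[gene]],
                          allow_dhu_absent = gene == "trnS1")
    arms_true <- mitocomp:::layout_arms(truth[[gene]], nchar(s))
    expect_identical(lapply(cl$arms, function(a) a[, c("pos5", "pos3")]),
                     lapply(arms_true, function(a) a[, c("pos5", "pos3")]))
    expect_true(all(unlist(lapply(cl$arms, function(a)
      if (nrow(a)) a$class else character(0))) == "WC"))
    expect_identical(cl$dhu_absent, gene == "trnS1")
  }
})

test_that("a single acceptor perturbation yields exactly one non-WC pair", {
  fx <- get_fixture()
  g <- fx$fs$genomes$S1
  truth <- attr(g, "truth")$trna
  s <- extract_gene(g, "trnD")
  arms <- mitocomp:::layout_arms(truth$trnD, nchar(s))
  b <- strsplit(s, "")[[1]]
  k <- 4L
  p5 <- arms$acceptor$pos5[k]; p3 <- arms$acceptor$pos3[k]
  # substitute the 5' base so the pair becomes a mismatch (not G:U)
  b[p5] <- setdiff(c("A", "C", "G", "T"),
                   c(b[p5], revcomp(b[p3]),
                     if (b[p3] %in% c("T", "G")) chartr("TG", "GT", b[p3])))[1]
  cl <- fold_cloverleaf(paste(b, collapse = ""),
                        anticodon = mitocomp:::TRNA_ANTICODON[["trnD"]])
  per_arm <- vapply(cl$arms, function(a) sum(a$class != "WC"), integer(1))
  expect_identical(unname(per_arm),
                   c(1L, 0L, 0L, 0L))  # acceptor, dhu, anticodon, tpsic
  expect_identical(cl$arms$acceptor$class[k], "mismatch")
})

test_that("folding is deterministic and score-monotone", {
  fx <- get_fixture()
  s <- extract_gene(fx$genomes[[3]], "trnW")
  c1 <- fold_cloverleaf(s)
  c2 <- fold_cloverleaf(s)
  expect_identical(c1[c("layout", "arms", "score")],
                   c2[c("layout", "arms", "score")])
  # converting a mismatch (injected) back to WC never lowers the score
  g <- fx$fs$genomes$S5
  truth <- attr(g, "truth")$trna
  s <- extract_gene(g, "trnI")
  arms <- mitocomp:::layout_arms(truth$trnI, nchar(s))
  b <- strsplit(s, "")[[1]]
  p5 <- arms$tpsic$pos5[1]; p3 <- arms$tpsic$pos3[1]
  b2 <- b
  b2[p5] <- setdiff(c("A", "C"), c(b[p5], revcomp(b[p3])))[1]  # break pair
  worse <- fold_cloverleaf(paste(b2, collapse = ""))
  better <- fold_cloverleaf(paste(b, collapse = ""))
  expect_gte(better$score, worse$score)
})

test_that("length bounds and impossible layouts raise fold errors", {
  expect_error(fold_cloverleaf(strrep("A", 40)), "outside supported range")
  expect_error(fold_cloverleaf(strrep("A", 99)), "outside supported range")
  fx <- get_fixture()
  s <- extract_gene(fx$genomes[[1]], "trnM")
  expect_error(fold_cloverleaf(s, anticodon = "GGG"), "anticodon")
})

test_that("dot-bracket structures round-trip and classify arms", {
  fx <- get_fixture()
  s <- extract_gene(fx$genomes[[1]], "trnK")
  cl <- fold_cloverleaf(s)
  db <- structure_string(cl)
  expect_identical(nchar(db), nchar(s))
  cl2 <- parse_structure_string(s, db)
  expect_identical(lapply(cl2$arms, function(a) a[, c("pos5", "pos3")]),
                   lapply(cl$arms, function(a) a[, c("pos5", "pos3")]))
  expect_false(cl2$dhu_absent)
  expect_identical(cl2$anticodon, cl$anticodon)
  # three-stem structure -> DHU arm absent
  s1 <- extract_gene(fx$genomes[[1]], "trnS1")
  cl3 <- fold_cloverleaf(s1, allow_dhu_absent = TRUE)
  expect_true(cl3$dhu_absent)
  cl4 <- parse_structure_string(s1, structure_string(cl3))
  expect_true(cl4$dhu_absent)
  # malformed strings
  expect_error(parse_structure_string("ACGU", "(().."), "lengths differ")
  expect_error(parse_structure_string("ACGUA", "(().."), "unbalanced")
  expect_error(parse_structure_string("ACGUA", "((a))"), "symbols")
})

test_that("mismatch profiles recover injected wobble counts exactly", {
  fx <- get_fixture()
  prof <- mismatch_profile(fx$genomes)
  expected <- unlist(fx$fs$manifest$trna_perturbations)
  expect_identical(stats::setNames(prof$nonwc$sum, prof$nonwc$species),
                   stats::setNames(as.integer(expected), names(expected)))
  # arm tallies sum to the row total
  expect_equal(prof$nonwc$acceptor + prof$nonwc$DHU + prof$nonwc$TPsiC +
                 prof$nonwc$anticodon, prof$nonwc$sum)
  # injected pairs are wobbles: strict mismatch count is zero,
  # and the G-U grand total equals the injected total
  expect_true(all(prof$strict$sum == 0))
  expect_identical(prof$gu_total, sum(as.integer(expected)))
  expect_false(any(prof$nonwc$partial))
})
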