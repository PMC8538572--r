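#' Pipeline configuration
#'
#' All stage parameters in one serializable object. Unknown keys are
#' rejected so a stale config file cannot silently change behaviour.
#'
#' @param input Character vector of GenBank file paths, or a list of
#'   [mitogenome()] objects.
#' @param out_dir Output directory for the stage TSVs, JSON summary and
#'   log.
#' @param stages Stage toggles; subset of the default vector.
#' @param skew_strand `"J"` (whole-genome skew on the majority strand) or
#'   `"coding"` (per-region coding-sense concatenations only).
#' @param include Region classes for the supermatrix/distance stages.
#' @param bootstrap_n Bootstrap replicates for the tree stage.
#' @param match,mismatch,gap_open,gap_extend Aligner scores.
#' @param reference_order Reference gene order for the gene-order stage
#'   (default: ancestral arrangement).
#' @param seed Integer seed (bootstrap resampling).
#' @param verbose Print per-stage progress.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir = "mitocomp_out",
                            stages = c("composition", "codon", "trna",
                                       "distance", "kaks", "geneorder",
                                       "tree"),
                            skew_strand = c("J", "coding"),
                            include = c("PCG", "rRNA", "tRNA"),
                            bootstrap_n = 200L,
                            match = 1, mismatch = -1, gap_open = -5,
                            gap_extend = -1,
                            reference_order = ANCESTRAL_ORDER,
                            seed = 1L, verbose = TRUE) {
  stages <- match.arg(stages, c("composition", "codon", "trna", "distance",
                                "kaks", "geneorder", "tree"),
                      several.ok = TRUE)
  structure(list(input = input, out_dir = out_dir, stages = stages,
                 skew_strand = match.arg(skew_strand),
                 include = include, bootstrap_n = as.integer(bootstrap_n),
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 reference_order = reference_order,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Executes composition -> codon usage -> tRNA structure -> K2P distances
#' -> per-gene Ka/Ks -> gene order -> NJ tree with bootstrap, writing one
#' TSV per stage plus a JSON summary and a log with per-stage timings.
#' Stage failures are isolated: a failing stage is recorded and the run
#' continues. Stages requiring >= 2 genomes (distance, kaks, tree) are
#' skipped with a notice on single-genome input.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results, the `summary`
#'   list (also written as JSON), and `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  genomes <- if (is.character(config$input))
    lapply(config$input, parse_genbank) else config$input
  if (!length(genomes)) stop("empty input set")
  ids <- vapply(genomes, `[[`, "", "id")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mitocomp %s pipeline",
                         as.character(utils::packageVersion("mitocomp"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("genomes: %s", paste(ids, collapse = ", ")),
                 sprintf("stages: %s", paste(config$stages, collapse = ", ")),
                 sprintf("skew_strand: %s", config$skew_strand))
  results <- list()
  errors <- list()
  summary <- list(genomes = as.list(stats::setNames(
    vapply(genomes, function(g) nchar(g$sequence), integer(1)), ids)))
  tsv <- function(d, name) {
    utils::write.table(d, file.path(config$out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible())
    tic <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    secs <- round(as.numeric(difftime(Sys.time(), tic, units = "secs")), 2)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      log_lines <<- c(log_lines,
                      sprintf("stage %-12s FAILED after %ss: %s", name,
                              secs, conditionMessage(res)))
    } else {
      results[[name]] <<- res
      log_lines <<- c(log_lines,
                      sprintf("stage %-12s ok (%ss)", name, secs))
    }
    if (config$verbose)
      message(utils::tail(log_lines, 1))
  }
  multi <- length(genomes) >= 2L

  run_stage("composition", function() {
    d <- do.call(rbind, lapply(genomes, function(g) {
      r <- region_composition(g)
      cbind(genome = g$id, r)
    }))
    tsv(d, "composition")
    whole <- d[d$region == "whole", ]
    summary$composition <<- list(
      AT_content = as.list(stats::setNames(whole$AT_content, whole$genome)),
      AT_skew = as.list(stats::setNames(whole$AT_skew, whole$genome)),
      GC_skew = as.list(stats::setNames(whole$GC_skew, whole$genome)))
    d
  })

  run_stage("codon", function() {
    us <- usage_summary(genomes)
    tsv(us$codons, "rscu")
    tsv(us$families, "aa_usage")
    ss <- start_stop_table(genomes)
    tsv(ss, "start_stop")
    summary$codon <<- list(
      top_rscu = us$codons$codon[order(-us$codons$mean_rscu)][1:3],
      start_classes = as.list(table(ss$start_class)),
      stop_classes = as.list(table(ss$stop_class)))
    list(usage = us, start_stop = ss)
  })

  run_stage("trna", function() {
    prof <- mismatch_profile(genomes)
    tsv(prof$nonwc, "trna_mismatch")
    tsv(prof$strict, "trna_mismatch_strict")
    summary$trna <<- list(
      row_sums = as.list(stats::setNames(prof$nonwc$sum,
                                         prof$nonwc$species)),
      gu_total = prof$gu_total)
    prof
  })

  supermatrix <- NULL
  get_supermatrix <- function() {
    if (is.null(supermatrix))
      supermatrix <<- build_supermatrix(genomes, include = config$include)
    supermatrix
  }

  run_stage("distance", function() {
    if (!multi) { log_lines <<- c(log_lines,
      "stage distance     skipped: single genome"); return(NULL) }
    sm <- get_supermatrix()
    D_all <- distance_matrix(sm)
    # PCG-only view: subset the supermatrix columns by partition
    pp <- sm$partitions[sm$partitions$gene %in% PCG_SYMBOLS, ]
    pcg_rows <- vapply(sm$seqs, function(s)
      paste(substring(s, pp$start + 1L, pp$end), collapse = ""),
      character(1))
    D_pcg <- if (nrow(pp)) distance_matrix(pcg_rows) else D_all * NA
    long <- data.frame(
      a = rep(rownames(D_all), times = ncol(D_all)),
      b = rep(colnames(D_all), each = nrow(D_all)),
      k2p_allgene = round(as.vector(D_all), 4),
      k2p_pcg = round(as.vector(D_pcg), 4))
    long <- long[long$a < long$b, ]
    tsv(long, "distances")
    off <- D_all[upper.tri(D_all)]
    pair_names <- outer(rownames(D_all), colnames(D_all), paste, sep = "-")
    summary$distance <<- list(
      min = min(off, na.rm = TRUE), max = max(off, na.rm = TRUE),
      min_pair = pair_names[upper.tri(D_all)][which.min(off)])
    list(all = D_all, pcg = D_pcg)
  })

  run_stage("kaks", function() {
    if (!multi) { log_lines <<- c(log_lines,
      "stage kaks         skipped: single genome"); return(NULL) }
    rows <- lapply(PCG_SYMBOLS, function(g)
      tryCatch(as.data.frame(per_gene_kaks(genomes, g)),
               error = function(e) NULL))
    d <- do.call(rbind, rows)
    d$mean_ka <- round(d$mean_ka, 4)
    d$mean_ks <- round(d$mean_ks, 4)
    d$mean_ratio <- round(d$mean_ratio, 4)
    tsv(d, "kaks")
    summary$kaks <<- as.list(stats::setNames(d$mean_ratio, d$gene))
    d
  })

  run_stage("geneorder", function() {
    d <- do.call(rbind, lapply(genomes, function(g) {
      cmp <- gene_order_compare(gene_order(g), config$reference_order)
      data.frame(genome = g$id, matches_reference = cmp$identical,
                 breakpoints = cmp$breakpoint_count,
                 stringsAsFactors = FALSE)
    }))
    tsv(d, "gene_order")
    summary$gene_order <<- list(
      all_match_reference = all(d$matches_reference))
    d
  })

  run_stage("tree", function() {
    if (length(genomes) < 4L) { log_lines <<- c(log_lines,
      "stage tree         skipped: needs >= 4 genomes"); return(NULL) }
    sm <- get_supermatrix()
    tr <- bootstrap_support(sm, n_replicates = config$bootstrap_n,
                            seed = config$seed)
    write_newick(tr, file.path(config$out_dir, "nj_tree.nwk"))
    write_phylip(sm$seqs, file.path(config$out_dir, "supermatrix.phy"))
    write_nexus(sm$seqs, file.path(config$out_dir, "supermatrix.nex"),
                partitions = sm$partitions)
    summary$tree <<- list(
      newick = ape::write.tree(tr),
      mean_support = if (!is.null(tr$node.label))
        mean(as.numeric(tr$node.label), na.rm = TRUE) else NA)
    tr
  })

  summary$errors <- errors
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("total: %ss", round(as.numeric(
                   difftime(Sys.time(), t0, units = "secs")), 2)))
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  invisible(list(results = results, summary = summary, errors = errors,
                 exit_status = if (length(errors)) 1L else 0L))
}
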