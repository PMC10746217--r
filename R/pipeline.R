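# Pipeline wiring: run every stage in dependency order over a cohort and
# summarize at cohort level.

#' Pipeline configuration with study defaults
#'
#' Collects every stage parameter with its default: E-value threshold 1e-5
#' (strict), core pseudogene allowance 2, MAG minimum core genes 10
#' (representative MAGs 20), GC-anomaly threshold 5 points (strict),
#' rod/hook adjacency gap 3 intervening genes, chemosensory operon gap 5
#' intervening genes, cluster merge gap 10 kb, QC thresholds 80% / 5% with
#' an optional whitelist, and the FlgF/FlgG core exemption (see
#' [callFlagellated()]).
#'
#' @param evalue_max,pseudogene_allowance,mag_min_core,representative_min_core
#'   See [assignLabels()] and [callFlagellated()].
#' @param core_exempt See [callFlagellated()].
#' @param gc_threshold See [hgtScreen()].
#' @param rodhook_gap See [disambiguateRodHook()].
#' @param operon_gap_genes See [detectChemoSystems()].
#' @param cluster_gap_bp See [detectMajorCluster()].
#' @param qc_min_completeness,qc_max_contamination,qc_whitelist
#'   See [qcFilter()].
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(evalue_max = 1e-5, pseudogene_allowance = 2L,
                      mag_min_core = 10L, representative_min_core = 20L,
                      core_exempt = c("FlgF", "FlgG"),
                      gc_threshold = 5, rodhook_gap = 3L,
                      operon_gap_genes = 5L, cluster_gap_bp = 10000L,
                      qc_min_completeness = 80, qc_max_contamination = 5,
                      qc_whitelist = character()) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full analysis over a cohort
#'
#' Stages, in dependency order: metadata QC filter; label assignment from
#' homology hits; rod/hook disambiguation; presence-matrix construction;
#' per-genome flagellated calls and flagellar gene counts; chemosensory
#' system detection, F-class and receptor classification, core-four check
#' and cognate report; GC screen of the major flagellar cluster; GGDEF
#' census with the flagellated-versus-not comparison; optional tree
#' concordance. A stage failure aborts the run naming the stage, and any
#' partially written outputs are removed. Re-running on identical inputs
#' and config yields identical outputs.
#'
#' @param cohort In-memory cohort bundle (see [generateCohort()] /
#'   [readCohortDir()]), or `NULL` if `input_dir` is given.
#' @param input_dir Directory laid out as by [writeCohort()].
#' @param config A [runConfig()].
#' @param trees Optional list with `species_tree` and `gene_tree` (`phylo`
#'   or Newick paths) for the concordance stage; leaf classes are taken
#'   from metadata `tax_class` unless `tree_classes` is given.
#' @param tree_classes Optional named vector leaf -> class.
#' @param out_dir Optional output directory for the report TSVs
#'   (presence_matrix.tsv, flagellar_calls.tsv, chemo_systems.tsv,
#'   receptors.tsv, cognate_report.tsv, gc_screen.tsv, ggdef_census.tsv,
#'   transfers.tsv, summary.yaml).
#' @param registry A [FlagellarRegistry-class].
#' @return list of stage outputs plus `summary` (see [cohortSummary()]).
#' @export
runAll <- function(cohort = NULL, input_dir = NULL, config = runConfig(),
                   trees = NULL, tree_classes = NULL, out_dir = NULL,
                   registry = loadRegistry()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) unlink(.outFiles(out_dir))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(cohort)) {
    if (is.null(input_dir)) stop("supply a cohort or an input_dir")
    cohort <- stage("ingest", {
      if (length(list.files(input_dir)) == 0L)
        stop("input directory is empty: ", input_dir)
      readCohortDir(input_dir)
    })
  }
  meta <- stage("qc_filter", {
    .validateMeta(cohort$meta)
    qcFilter(cohort$meta, whitelist = config$qc_whitelist,
             min_completeness = config$qc_min_completeness,
             max_contamination = config$qc_max_contamination)$retained
  })
  ids <- meta$genome_id
  calls <- cohort$calls[mcols(cohort$calls)$genome_id %in% ids]
  hits <- cohort$hits[cohort$hits$genome_id %in% ids, , drop = FALSE]
  domains <- cohort$domains[cohort$domains$genome_id %in% ids, , drop = FALSE]

  calls <- stage("assign_labels",
    assignLabels(hits, calls, evalue_max = config$evalue_max,
                 registry = registry))
  calls <- stage("disambiguate_rod_hook",
    disambiguateRodHook(calls, max_gap = config$rodhook_gap))
  pm <- stage("presence_matrix",
    buildPresenceMatrix(calls, registry = registry, genomes = ids))

  fcalls <- stage("call_flagellated", {
    m <- presenceCells(pm)
    do.call(rbind, lapply(seq_along(ids), function(i) {
      out <- callFlagellated(m[ids[i], ], meta$assembly_level[i],
                             pseudogene_allowance = config$pseudogene_allowance,
                             mag_min_core = config$mag_min_core,
                             representative_min_core = config$representative_min_core,
                             core_exempt = config$core_exempt,
                             registry = registry)
      cbind(data.frame(genome_id = ids[i], stringsAsFactors = FALSE), out,
            n_flagellar_genes = countFlagellarGenes(m[ids[i], ]))
    }))
  })

  chemo <- stage("chemosensory", {
    det <- detectChemoSystems(calls, domains,
                              max_gap_genes = config$operon_gap_genes,
                              registry = registry)
    systems <- classifySystems(det$systems, registry = registry)
    chemoset <- hasChemotaxisSet(calls)
    list(systems = systems, receptors = det$receptors,
         chemotaxis_set = data.frame(
           genome_id = ids,
           has_chemotaxis_set = unname(chemoset[ids]) %in% TRUE,
           stringsAsFactors = FALSE),
         cognate = cognateReport(systems, det$receptors, registry = registry))
  })

  gc_screen <- stage("hgt_screen", {
    do.call(rbind, lapply(which(fcalls$flagellated), function(i) {
      gid <- ids[i]
      gcalls <- calls[mcols(calls)$genome_id == gid]
      mj <- detectMajorCluster(gcalls, max_gap_bp = config$cluster_gap_bp,
                               registry = registry)
      sq <- NULL
      if (!is.null(mj$major) && !is.null(cohort$seqs[[gid]])) {
        ctg <- cohort$seqs[[gid]][[mj$major$contig]]
        sq <- subseq(ctg, mj$major$start, min(mj$major$end, length(ctg)))
      }
      hgtScreen(sq, meta$genome_gc[i], threshold = config$gc_threshold,
                genome_id = gid)
    }))
  })

  census <- stage("ggdef_census", {
    flag <- setNames(fcalls$flagellated, fcalls$genome_id)
    ggdefCensus(domains, meta, flagellated = flag)
  })
  ggdef_test <- stage("ggdef_compare", {
    if (nrow(census) > 0L && length(unique(census$flagellated)) == 2L)
      groupCompare(census, "flagellated") else NULL
  })

  concordance <- NULL
  if (!is.null(trees)) {
    concordance <- stage("tree_concordance", {
      st <- if (is.character(trees$species_tree))
        readNewickTree(trees$species_tree) else trees$species_tree
      gt <- if (is.character(trees$gene_tree))
        readNewickTree(trees$gene_tree) else trees$gene_tree
      cls <- if (!is.null(tree_classes)) tree_classes else
        setNames(meta$tax_class, meta$genome_id)
      c(robinsonFoulds(st, gt),
        detectInterclassTransfers(gt, st, cls))
    })
  }

  res <- list(meta = meta, calls = calls, presence = pm,
              flagellar_calls = fcalls, chemo = chemo,
              gc_screen = gc_screen, ggdef_census = census,
              ggdef_test = ggdef_test, concordance = concordance)
  res$summary <- cohortSummary(res)
  if (!is.null(out_dir)) stage("write_outputs", .writeOutputs(res, out_dir))
  res
}

#' Cohort-level summary report
#'
#' Recomputed entirely from the per-genome tables (so the summary always
#' equals what the emitted tables imply): total genomes, flagellated count
#' and percentage (nearest integer), per-class flagellated ratios, the
#' number of flagellated genomes lacking a chemotaxis core set, the
#' flagellar-gene-count range among flagellated complete genomes, and the
#' GGDEF count range.
#'
#' @param results The list produced by [runAll()].
#' @return list of summary fields.
#' @export
cohortSummary <- function(results) {
  fc <- results$flagellar_calls
  meta <- results$meta
  nflag <- sum(fc$flagellated)
  per_class <- do.call(rbind, lapply(split(seq_len(nrow(meta)),
                                           meta$tax_class), function(i)
    data.frame(tax_class = meta$tax_class[i[1L]], n = length(i),
               n_flagellated = sum(fc$flagellated[i]),
               pct_flagellated = .pct(sum(fc$flagellated[i]), length(i)),
               stringsAsFactors = FALSE)))
  rownames(per_class) <- NULL
  no_chemo <- merge(fc[fc$flagellated, c("genome_id", "flagellated")],
                    results$chemo$chemotaxis_set, by = "genome_id")
  complete_flag <- fc$flagellated & meta$assembly_level == "complete"
  rng <- if (any(complete_flag))
    range(fc$n_flagellar_genes[complete_flag]) else c(NA_integer_,
                                                      NA_integer_)
  grng <- if (nrow(results$ggdef_census) > 0L)
    range(results$ggdef_census$n_ggdef) else c(NA_integer_, NA_integer_)
  list(total_genomes = nrow(meta),
       n_flagellated = nflag,
       pct_flagellated = .pct(nflag, nrow(meta)),
       per_class = per_class,
       n_flagellated_without_chemotaxis = sum(!no_chemo$has_chemotaxis_set),
       flagellar_gene_range_complete = rng,
       ggdef_range = grng)
}

#' @noRd
.outFiles <- function(dir) {
  file.path(dir, c("presence_matrix.tsv", "flagellar_calls.tsv",
                   "chemo_systems.tsv", "receptors.tsv",
                   "cognate_report.tsv", "gc_screen.tsv",
                   "ggdef_census.tsv", "transfers.tsv", "summary.yaml"))
}

#' @noRd
.writeOutputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePresenceMatrix(res$presence, file.path(dir, "presence_matrix.tsv"))
  fwrite(res$flagellar_calls, file.path(dir, "flagellar_calls.tsv"),
         sep = "\t")
  fwrite(res$chemo$systems, file.path(dir, "chemo_systems.tsv"), sep = "\t")
  fwrite(res$chemo$receptors, file.path(dir, "receptors.tsv"), sep = "\t")
  fwrite(res$chemo$cognate, file.path(dir, "cognate_report.tsv"), sep = "\t")
  if (!is.null(res$gc_screen) && nrow(res$gc_screen) > 0L)
    fwrite(res$gc_screen, file.path(dir, "gc_screen.tsv"), sep = "\t")
  fwrite(res$ggdef_census, file.path(dir, "ggdef_census.tsv"), sep = "\t")
  if (!is.null(res$concordance))
    fwrite(res$concordance$transfers, file.path(dir, "transfers.tsv"),
           sep = "\t")
  s <- res$summary
  s$flagellar_gene_range_complete <- as.list(s$flagellar_gene_range_complete)
  s$ggdef_range <- as.list(s$ggdef_range)
  s$per_class <- lapply(seq_len(nrow(res$summary$per_class)), function(i)
    as.list(res$summary$per_class[i, ]))
  yaml::write_yaml(s, file.path(dir, "summary.yaml"))
  invisible(dir)
}

#' Compare pipeline results with a cohort's planted ground truth
#'
#' Measures, on a cohort generated with planted truth, the recovery of each
#' estimated quantity: the flagellated call (all retained genomes), the
#' FlgE/FlgF/FlgG identities (over genomes whose planted cluster retains
#' the flgD anchor or the FlgF–FlgG adjacency), the chemosensory F class
#' (genomes with a planted class), the GGDEF census (non-MAG genomes), and
#' the GC-anomaly flag (screened genomes). Each element is the percentage
#' of exact matches.
#'
#' @param cohort A cohort with `truth` (see [generateCohort()]).
#' @param results The [runAll()] output for that cohort.
#' @return Named list of recovery percentages (and the counts they are
#'   based on, as attributes `n`).
#' @export
recoveryReport <- function(cohort, results) {
  tr <- cohort$truth$per_genome
  fc <- results$flagellar_calls
  m <- merge(tr, fc, by = "genome_id")
  out <- list()
  pctOf <- function(ok) {
    v <- if (length(ok) == 0L) NA_real_ else 100 * mean(ok)
    attr(v, "n") <- length(ok)
    v
  }
  out$flagellated <- pctOf(m$flagellated.x == m$flagellated.y)
  efg <- cohort$truth$efg
  if (!is.null(efg) && nrow(efg) > 0L) {
    # a locus is resolvable only while its gene-order cue survives:
    # FlgE needs the flgD anchor, FlgF/FlgG need the intact pair
    cue <- ifelse(efg$label == "FlgE",
                  tr$flgD_retained[match(efg$genome_id, tr$genome_id)],
                  tr$flgFG_adjacent[match(efg$genome_id, tr$genome_id)])
    efg <- efg[cue, , drop = FALSE]
    mc <- mcols(results$calls)
    got <- mc$label[match(efg$locus_tag, mc$locus_tag)]
    out$efg_labels <- pctOf(got == efg$label)
  }
  planted <- tr[tr$f_class != "none", , drop = FALSE]
  if (nrow(planted) > 0L) {
    sys <- results$chemo$systems
    ok <- vapply(seq_len(nrow(planted)), function(i)
      planted$f_class[i] %in%
        sys$f_class[sys$genome_id == planted$genome_id[i]], logical(1))
    out$f_class <- pctOf(ok)
  }
  cen <- merge(results$ggdef_census, tr[, c("genome_id", "n_ggdef")],
               by = "genome_id")
  if (nrow(cen) > 0L)
    out$ggdef <- pctOf(cen$n_ggdef.x == cen$n_ggdef.y)
  if (!is.null(results$gc_screen) && nrow(results$gc_screen) > 0L) {
    g <- merge(results$gc_screen, tr[, c("genome_id", "hgt_flag")],
               by = "genome_id")
    out$hgt_flag <- pctOf(g$flagged == g$hgt_flag)
  }
  out
}
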