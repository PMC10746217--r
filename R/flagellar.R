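# Flagellar gene labeling, rod/hook paralog disambiguation by gene order,
# the four-state presence/absence matrix, and the flagellated call.

.EFG <- c("FlgE", "FlgF", "FlgG")
.EFG_AMBIGUOUS <- "FlgEFG_ambiguous"

#' PresenceMatrix: genomes x flagellar genes with four-state cells
#'
#' Rows are genomes, columns are the registry's 50 flagellar genes in
#' registry order; each cell is one of `present`, `absent`, `pseudogene`,
#' `partial` (the four states drawn as solid, hollow, shaded and half
#' squares in presence/absence figures; `partial` marks a coding sequence
#' truncated by a contig edge, most likely intact in the underlying genome).
#'
#' @slot cells Character matrix with genome_ids as rownames and gene symbols
#'   as colnames.
#' @seealso [buildPresenceMatrix()], [callFlagellated()],
#'   [writePresenceMatrix()]
#' @export
setClass("PresenceMatrix", representation(cells = "matrix"))

setValidity("PresenceMatrix", function(object) {
  m <- object@cells
  if (!is.character(m)) return("cells must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("cells must carry genome_ids as rownames and genes as colnames")
  ok <- m %in% c("present", "absent", "pseudogene", "partial")
  if (!all(ok)) return("every cell must be present/absent/pseudogene/partial")
  TRUE
})

#' Construct a PresenceMatrix from a coded character matrix
#' @param cells Character matrix of the four states with dimnames set.
#' @return A [PresenceMatrix-class].
#' @export
PresenceMatrix <- function(cells) new("PresenceMatrix", cells = cells)

#' Accessors for PresenceMatrix
#' @param x A [PresenceMatrix-class].
#' @return `presenceCells()`: the character matrix; `genomeIds()`,
#'   `geneSymbols()`: row/column names.
#' @rdname presence-accessors
#' @export
presenceCells <- function(x) x@cells

#' @rdname presence-accessors
#' @export
genomeIds <- function(x) rownames(x@cells)

#' @rdname presence-accessors
#' @export
geneSymbols <- function(x) colnames(x@cells)

setMethod("show", "PresenceMatrix", function(object) {
  m <- object@cells
  cat(sprintf("PresenceMatrix: %d genome(s) x %d gene(s)\n", nrow(m), ncol(m)))
  tab <- table(factor(m, levels = c("present", "absent", "pseudogene",
                                    "partial")))
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})

#' Assign gene labels to loci from homology hits
#'
#' Each locus receives at most one label: among its hits with
#' `evalue < evalue_max` the best one wins (lowest E-value, ties broken by
#' highest bitscore, then lexicographically smallest query symbol — a
#' deterministic rule). Hits at or above the threshold are ignored. Query
#' symbols that are registry aliases are canonicalized (e.g. FlaG to YvyC,
#' FlhO/FlhP to FlgF/FlgG). Labels among FlgE/FlgF/FlgG are provisional:
#' these rod/hook paralogs share highly similar D0/Dc domains and must be
#' finalized by [disambiguateRodHook()] using gene order.
#'
#' @param hits Homology-hit data.frame (see [readTabularHits()]); extra
#'   columns such as `genome_id` are carried along but matching is by
#'   `subject_locus`, which must be unique across the supplied calls.
#' @param calls [GRanges] of gene calls with a `locus_tag` metadata column.
#' @param evalue_max Strict E-value threshold; default `1e-5`.
#' @param registry A [FlagellarRegistry-class] used to canonicalize aliases.
#' @return `calls` with the `label` column filled (`"unassigned"` where no
#'   hit passes).
#' @export
assignLabels <- function(hits, calls, evalue_max = 1e-5,
                         registry = loadRegistry()) {
  tags <- mcols(calls)$locus_tag
  orphans <- setdiff(unique(hits$subject_locus), tags)
  if (length(orphans) > 0L)
    stop("hits reference unknown locus tag(s): ",
         paste(head(orphans, 10L), collapse = ", "),
         if (length(orphans) > 10L) sprintf(" (and %d more)",
                                            length(orphans) - 10L) else "")
  pass <- hits[hits$evalue < evalue_max, , drop = FALSE]
  mcols(calls)$label <- "unassigned"
  if (nrow(pass) == 0L) return(calls)
  # canonicalize alias query symbols
  g <- geneCatalog(registry)
  amap <- list()
  for (i in which(nzchar(g$aliases)))
    for (a in .splitSet(g$aliases[i])) amap[[a]] <- g$name[i]
  qs <- pass$query_symbol
  hasAlias <- qs %in% names(amap)
  qs[hasAlias] <- unlist(amap[qs[hasAlias]], use.names = FALSE)
  pass$query_symbol <- qs
  ord <- order(pass$subject_locus, pass$evalue, -pass$bitscore,
               pass$query_symbol)
  pass <- pass[ord, , drop = FALSE]
  best <- pass[!duplicated(pass$subject_locus), , drop = FALSE]
  idx <- match(best$subject_locus, tags)
  mcols(calls)$label[idx] <- best$query_symbol
  calls
}

#' Disambiguate FlgE / FlgF / FlgG by conserved gene order
#'
#' FlgE (hook), FlgF and FlgG (distal rod) are close paralogs whose homology
#' hits cross-react; the conserved gene orders *flgD–flgE* and *flgF–flgG*
#' are used as cues. Per contig (gene positions in coordinate order): the
#' candidate nearest a FlgD call, within `max_gap` intervening genes, is
#' labeled FlgE (each FlgD anchors at most one FlgE; downstream candidates
#' win distance ties, matching the *flgD–flgE* orientation). Remaining
#' candidates that form an adjacent pair (within `max_gap` intervening
#' genes, no FlgD cue) are labeled FlgF (upstream in transcriptional order)
#' and FlgG (downstream). Candidates resolvable by neither cue — isolated
#' ones, or runs of three or more — are labeled `"FlgEFG_ambiguous"`.
#' The multiset of loci is unchanged; only labels change, and FlgF/FlgG are
#' never both assigned to one locus.
#'
#' @param calls Labeled [GRanges] from [assignLabels()].
#' @param max_gap Maximum intervening genes for adjacency; default 3.
#' @return `calls` with final FlgE/FlgF/FlgG labels.
#' @export
disambiguateRodHook <- function(calls, max_gap = 3L) {
  if (length(calls) == 0L) return(calls)
  mc <- mcols(calls)
  gid <- if (!is.null(mc$genome_id)) as.character(mc$genome_id) else ""
  key <- paste(gid, as.character(seqnames(calls)), sep = "\r")
  labels <- mc$label
  for (k in unique(key)) {
    sel <- which(key == k)
    sel <- sel[order(start(calls)[sel])]
    lab <- labels[sel]
    cand <- which(lab %in% .EFG)
    if (length(cand) == 0L) next
    newlab <- lab
    newlab[cand] <- .EFG_AMBIGUOUS
    unres <- cand
    # cue 1: flgD-flgE adjacency; nearest candidate per FlgD, downstream wins ties
    for (dpos in which(lab == "FlgD")) {
      if (length(unres) == 0L) break
      gaps <- abs(unres - dpos) - 1L
      ok <- which(gaps <= max_gap)
      if (length(ok) == 0L) next
      # prefer smallest gap, then downstream (larger position)
      pick <- ok[order(gaps[ok], -unres[ok])][1L]
      newlab[unres[pick]] <- "FlgE"
      unres <- unres[-pick]
    }
    # cue 2: adjacent candidate pairs -> FlgF (upstream), FlgG (downstream)
    if (length(unres) > 0L) {
      runs <- split(unres, cumsum(c(1L, diff(unres) - 1L > max_gap)))
      for (r in runs) {
        if (length(r) == 2L) {
          # transcriptional order: reverse coordinate order on minus strand
          strands <- as.character(strand(calls)[sel[r]])
          if (all(strands == "-")) r <- rev(r)
          newlab[r[1L]] <- "FlgF"
          newlab[r[2L]] <- "FlgG"
        }  # singletons and runs >= 3: no cue, stay ambiguous
      }
    }
    labels[sel] <- newlab
  }
  mcols(calls)$label <- labels
  calls
}

#' Build the genomes x genes presence/absence matrix
#'
#' Aggregates final labeled gene calls into a [PresenceMatrix-class]. A cell
#' is `present` if the genome has at least one call with that label and
#' status present; otherwise `pseudogene` if any pseudogene-status call;
#' otherwise `partial` if any partial-status call; otherwise `absent`
#' (precedence present > pseudogene > partial).
#'
#' @param calls Labeled [GRanges]; a `genome_id` metadata column groups
#'   calls by genome (a single unnamed genome is assumed otherwise).
#' @param registry A [FlagellarRegistry-class]; columns follow its gene
#'   order.
#' @param genomes Optional character vector fixing row set and order
#'   (genomes without calls get all-absent rows).
#' @return A [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(calls, registry = loadRegistry(),
                                genomes = NULL) {
  genes <- geneCatalog(registry)$name
  mc <- mcols(calls)
  gid <- if (!is.null(mc$genome_id)) as.character(mc$genome_id)
         else rep("genome", length(calls))
  if (is.null(genomes)) genomes <- unique(gid)
  m <- matrix("absent", nrow = length(genomes), ncol = length(genes),
              dimnames = list(genomes, genes))
  keep <- mc$label %in% genes & gid %in% genomes
  if (any(keep)) {
    df <- data.frame(g = gid[keep], gene = mc$label[keep],
                     status = mc$status[keep], stringsAsFactors = FALSE)
    rank <- c(present = 3L, pseudogene = 2L, partial = 1L)
    df$r <- rank[df$status]
    agg <- stats::aggregate(df$r, by = list(g = df$g, gene = df$gene), FUN = max)
    agg$r <- agg$x
    inv <- setNames(names(rank), rank)
    m[cbind(agg$g, agg$gene)] <- inv[as.character(agg$r)]
  }
  PresenceMatrix(m)
}

#' Call a genome flagellated or not from its presence-matrix row
#'
#' Implements the assembly-level-specific core-gene rules over the 24-gene
#' ancient core set:
#' \itemize{
#'   \item complete/draft genomes (`complete_rule`): flagellated iff every
#'     required core gene is non-absent and at most `pseudogene_allowance`
#'     of them are pseudogenes ("allowing for one or two pseudogene cases");
#'     partial (contig-edge) calls count as present.
#'   \item MAGs (`mag_rule`): flagellated iff at least `mag_min_core` of the
#'     24 core genes are present or partial. The stricter
#'     representative-MAG predicate (at least `representative_min_core`,
#'     default 20) is reported separately as `representative_ok` and does
#'     not affect the call.
#' }
#' By default FlgF and FlgG are exempt from the complete-rule presence
#' requirement (`core_exempt`): both distal-rod genes were lost wholesale in
#' the later actinobacterial classes, whose species are nonetheless
#' flagellated, so requiring them would misclassify every later-class
#' genome. The exemption is unconditional (rather than "only when both are
#' missing") so that the call is monotone: switching any core cell to
#' present can never revoke a flagellated call. Pass
#' `core_exempt = character()` for the strict all-24 reading.
#'
#' @param row Named character vector: one presence-matrix row (states for
#'   all registry genes), or a [PresenceMatrix-class] plus `genome_id`.
#' @param assembly_level `"complete"`, `"draft"` or `"MAG"`.
#' @param pseudogene_allowance Core pseudogenes tolerated under the
#'   complete rule; default 2.
#' @param mag_min_core MAG-tier minimum core genes; default 10.
#' @param representative_min_core Representative-MAG minimum; default 20.
#' @param core_exempt Core genes exempt from the complete-rule presence
#'   requirement; default `c("FlgF", "FlgG")`.
#' @param registry A [FlagellarRegistry-class].
#' @return One-row data.frame: `flagellated`, `tier`, `core_present`,
#'   `core_pseudogenes`, `core_absent`, `representative_ok`, `rationale`.
#' @export
callFlagellated <- function(row, assembly_level,
                            pseudogene_allowance = 2L,
                            mag_min_core = 10L,
                            representative_min_core = 20L,
                            core_exempt = c("FlgF", "FlgG"),
                            registry = loadRegistry()) {
  core <- coreGeneSet(registry)
  miss <- setdiff(core, names(row))
  if (length(miss) > 0L)
    stop("presence row lacks core gene(s): ", paste(miss, collapse = ", "))
  cr <- row[core]
  n_present <- sum(cr %in% c("present", "partial"))
  n_pseudo <- sum(cr == "pseudogene")
  n_absent <- sum(cr == "absent")
  if (assembly_level %in% c("complete", "draft")) {
    req <- setdiff(core, core_exempt)
    rr <- row[req]
    flag <- all(rr != "absent") && sum(rr == "pseudogene") <= pseudogene_allowance
    tier <- "complete_rule"
    rep_ok <- NA
    why <- sprintf("%d/%d required core genes non-absent, %d pseudogene(s) (allowance %d)",
                   sum(rr != "absent"), length(req), sum(rr == "pseudogene"),
                   pseudogene_allowance)
  } else if (assembly_level == "MAG") {
    flag <- n_present >= mag_min_core
    tier <- "mag_rule"
    rep_ok <- n_present >= representative_min_core
    why <- sprintf("%d/24 core genes present-or-partial (MAG threshold %d)",
                   n_present, mag_min_core)
  } else {
    stop("unknown assembly_level: ", assembly_level)
  }
  data.frame(flagellated = flag, tier = tier, core_present = n_present,
             core_pseudogenes = n_pseudo, core_absent = n_absent,
             representative_ok = rep_ok, rationale = why,
             stringsAsFactors = FALSE)
}

#' Count flagellar genes in a presence-matrix row
#'
#' Number of non-absent cells across all 50 registry genes (present,
#' pseudogene and partial all count). In complete actinobacterial genomes
#' with a flagellar gene set this count falls in a narrow band (reported
#' range 32–41).
#'
#' @param row Named character vector of states.
#' @return Integer count.
#' @export
countFlagellarGenes <- function(row) sum(row != "absent")

#' Detect the major flagellar gene cluster
#'
#' Flagellar-labeled calls on one contig separated by at most `max_gap_bp`
#' are merged into clusters; the cluster containing the most flagellar genes
#' is the major cluster (almost all flagellar genes sit in one big cluster
#' in actinobacterial genomes, with very few 1–2 gene outliers). Ties on
#' gene count are broken by larger genomic span and reported via the `tie`
#' flag.
#'
#' @param calls Labeled [GRanges] for a single genome.
#' @param max_gap_bp Maximum gap between consecutive cluster members;
#'   default 10000.
#' @param registry A [FlagellarRegistry-class] defining flagellar labels
#'   (provisional `FlgEFG_ambiguous` counts as flagellar).
#' @return list with `clusters` (data.frame: contig, start, end, n_genes,
#'   span), `major` (one-row data.frame or NULL), `outliers` (data.frame of
#'   flagellar calls outside the major cluster), `tie` (logical).
#' @export
detectMajorCluster <- function(calls, max_gap_bp = 10000L,
                               registry = loadRegistry()) {
  flag_labels <- c(geneCatalog(registry)$name, .EFG_AMBIGUOUS)
  sel <- which(mcols(calls)$label %in% flag_labels)
  empty <- list(clusters = data.frame(), major = NULL,
                outliers = data.frame(), tie = FALSE)
  if (length(sel) == 0L) return(empty)
  fc <- calls[sel]
  ord <- order(as.character(seqnames(fc)), start(fc))
  fc <- fc[ord]
  ctg <- as.character(seqnames(fc))
  newc <- c(TRUE, ctg[-1L] != ctg[-length(ctg)] |
                  start(fc)[-1L] - end(fc)[-length(fc)] - 1L > max_gap_bp)
  cid <- cumsum(newc)
  clusters <- do.call(rbind, lapply(split(seq_along(cid), cid), function(i) {
    data.frame(contig = ctg[i[1L]], start = min(start(fc)[i]),
               end = max(end(fc)[i]), n_genes = length(i),
               stringsAsFactors = FALSE)
  }))
  clusters$span <- clusters$end - clusters$start + 1L
  best_n <- max(clusters$n_genes)
  cand <- which(clusters$n_genes == best_n)
  tie <- length(cand) > 1L          # reported even when span breaks it
  if (tie) cand <- cand[order(-clusters$span[cand])]
  major_id <- cand[1L]
  out_idx <- which(cid != major_id)
  outliers <- data.frame(contig = ctg[out_idx], start = start(fc)[out_idx],
                         end = end(fc)[out_idx],
                         locus_tag = mcols(fc)$locus_tag[out_idx],
                         label = mcols(fc)$label[out_idx],
                         stringsAsFactors = FALSE)
  list(clusters = clusters, major = clusters[major_id, , drop = FALSE],
       outliers = outliers, tie = tie)
}
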