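# Chemosensory system detection, F-class assignment, chemoreceptor heptad
# typing, and cognate matching between arrays and receptors.

.CHEMO_COMPONENTS <- c("CheA", "CheW", "CheB", "CheR", "CheC", "CheD",
                       "CheX", "CheY", "MCP")
.CHEMO_ABBREV <- c(CheA = "A", "CheA:W" = "A:W", CheW = "W", CheB = "B",
                   CheR = "R", CheC = "C", CheD = "D", CheX = "X",
                   CheY = "Y", MCP = "M")

#' Detect chemosensory systems (gene neighborhoods) in labeled calls
#'
#' Chemosensory-labeled genes (CheA/W/B/R/C/D/X/Y and MCP chemoreceptors) on
#' one contig with at most `max_gap_genes` intervening non-chemosensory
#' genes between consecutive members are grouped into one system. A CheA
#' locus that additionally carries a CheW domain hit becomes the `CheA:W`
#' kinase variant. Groups of at least two genes are systems; isolated
#' chemoreceptors are recorded as receptor records but not as systems. The
#' order string lists component abbreviations (A, A:W, W, M, B, R, C, D, Y,
#' X) in transcriptional order (reversed for systems entirely on the minus
#' strand).
#'
#' @param calls Labeled [GRanges] (optionally with a `genome_id` column).
#' @param domain_hits Domain-hit data.frame (see [readDomainHits()]),
#'   used for the CheA:W variant and for receptor signaling-domain lengths
#'   (domain `MCP-signal`).
#' @param max_gap_genes Maximum intervening non-chemosensory genes within a
#'   system; default 5.
#' @param registry A [FlagellarRegistry-class] (heptad classes for receptor
#'   typing).
#' @return list with `systems` (data.frame: genome_id, contig, system_id,
#'   member_loci, components, order_string, f_class = NA) and `receptors`
#'   (data.frame: genome_id, protein_locus, signaling_domain_length,
#'   h_class, in_system).
#' @export
detectChemoSystems <- function(calls, domain_hits, max_gap_genes = 5L,
                               registry = loadRegistry()) {
  mc <- mcols(calls)
  gid <- if (!is.null(mc$genome_id)) as.character(mc$genome_id)
         else rep("genome", length(calls))
  chew_loci <- unique(domain_hits$protein_locus[
    domain_hits$domain_name == "CheW"])
  systems <- list()
  receptors <- list()
  sys_n <- 0L
  for (g in unique(gid)) {
    gsel <- which(gid == g)
    in_system <- character()
    for (ctg in unique(as.character(seqnames(calls)[gsel]))) {
      sel <- gsel[as.character(seqnames(calls)[gsel]) == ctg]
      sel <- sel[order(start(calls)[sel])]
      lab <- mc$label[sel]
      chemo <- which(lab %in% .CHEMO_COMPONENTS)
      if (length(chemo) == 0L) next
      grp <- cumsum(c(1L, diff(chemo) - 1L > max_gap_genes))
      for (members in split(chemo, grp)) {
        if (length(members) < 2L) next     # isolated gene: not a system
        idx <- sel[members]
        comp <- mc$label[idx]
        tags <- mc$locus_tag[idx]
        comp[comp == "CheA" & tags %in% chew_loci] <- "CheA:W"
        strands <- as.character(strand(calls)[idx])
        ordv <- seq_along(idx)
        if (all(strands == "-")) ordv <- rev(ordv)
        sys_n <- sys_n + 1L
        systems[[sys_n]] <- data.frame(
          genome_id = g, contig = ctg,
          system_id = sprintf("%s_sys%02d", g, sys_n),
          member_loci = paste(tags[ordv], collapse = ","),
          components = paste(sort(comp), collapse = ","),
          order_string = paste(.CHEMO_ABBREV[comp[ordv]], collapse = " "),
          f_class = NA_character_, stringsAsFactors = FALSE)
        in_system <- c(in_system, tags)
      }
    }
    mcp_idx <- gsel[mc$label[gsel] == "MCP"]
    if (length(mcp_idx) > 0L) {
      tags <- mc$locus_tag[mcp_idx]
      len <- .signalDomainLength(tags, domain_hits)
      receptors[[g]] <- data.frame(
        genome_id = g, protein_locus = tags,
        signaling_domain_length = len,
        h_class = vapply(len, function(L)
          if (is.na(L)) "unassigned" else classifyReceptorH(L, registry),
          character(1)),
        in_system = tags %in% in_system, stringsAsFactors = FALSE)
    }
  }
  emptySys <- data.frame(genome_id = character(), contig = character(),
                         system_id = character(), member_loci = character(),
                         components = character(), order_string = character(),
                         f_class = character(), stringsAsFactors = FALSE)
  emptyRec <- data.frame(genome_id = character(), protein_locus = character(),
                         signaling_domain_length = numeric(),
                         h_class = character(), in_system = logical(),
                         stringsAsFactors = FALSE)
  list(systems = if (length(systems)) do.call(rbind, systems) else emptySys,
       receptors = if (length(receptors)) do.call(rbind, c(receptors,
                     make.row.names = FALSE)) else emptyRec)
}

#' @noRd
.signalDomainLength <- function(tags, domain_hits) {
  dh <- domain_hits[domain_hits$domain_name == "MCP-signal", , drop = FALSE]
  vapply(tags, function(t) {
    rows <- dh[dh$protein_locus == t, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    max(rows$env_end - rows$env_start + 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Does a genome encode the chemotaxis core four?
#'
#' The core of a chemosensory system comprises four components:
#' a chemoreceptor (MCP), CheA, CheW and CheY. Returns TRUE for a genome iff
#' at least one of each is encoded anywhere in it, regardless of whether
#' they cluster into a detected system.
#'
#' @param calls Labeled [GRanges] (optionally with `genome_id`).
#' @return Named logical vector, one element per genome.
#' @export
hasChemotaxisSet <- function(calls) {
  mc <- mcols(calls)
  gid <- if (!is.null(mc$genome_id)) as.character(mc$genome_id)
         else rep("genome", length(calls))
  core4 <- c("MCP", "CheA", "CheW", "CheY")
  vapply(split(mc$label, gid), function(lab) all(core4 %in% lab),
         logical(1))
}

#' Assign a chemosensory F class to a detected system
#'
#' Rule precedence (conflicts are reported in the evidence trail, never
#' silently dropped):
#' \enumerate{
#'   \item F1 — both auxiliary components CheC and CheD present (F1 has no
#'     conserved gene order, so components alone decide);
#'   \item F5 — the CheA:W kinase variant present AND the gene order matches
#'     the conserved `A:W W ... B R` motif (interleaved chemoreceptor M and
#'     CheY genes are ignored when matching);
#'   \item F7 / F9 / ACF — required-component signatures from the registry
#'     (shipped as editable placeholders).
#' }
#' Systems matching no rule are `"unclassified"`.
#'
#' @param system One row of the `systems` data.frame from
#'   [detectChemoSystems()] (needs `components` and `order_string`).
#' @param registry A [FlagellarRegistry-class].
#' @return One-row data.frame: `f_class`, `evidence`.
#' @export
classifyFClass <- function(system, registry = loadRegistry()) {
  comp <- .splitSet(system$components)
  toks <- strsplit(system$order_string, " ", fixed = TRUE)[[1L]]
  ftab <- fClassTable(registry)
  matches <- character()
  evid <- character()
  # F1: components only
  if (all(c("CheC", "CheD") %in% comp)) {
    matches <- c(matches, "F1")
    evid <- c(evid, "F1: diagnostic CheC and CheD present")
  }
  # F5: kinase variant + AW...BR order (M and Y ignored)
  core_toks <- toks[!toks %in% c("M", "Y")]
  f5_order <- length(core_toks) >= 4L &&
    identical(core_toks[1:2], c("A:W", "W")) &&
    identical(tail(core_toks, 2L), c("B", "R"))
  if ("CheA:W" %in% comp && f5_order) {
    matches <- c(matches, "F5")
    evid <- c(evid, "F5: CheA:W kinase variant with conserved A:W W ... B R order")
  }
  for (fc in c("F7", "F9", "ACF")) {
    req <- .splitSet(ftab$required_components[ftab$name == fc])
    if (all(req %in% comp)) {
      matches <- c(matches, fc)
      evid <- c(evid, sprintf("%s: required components {%s} present (placeholder signature)",
                              fc, paste(req, collapse = ", ")))
    }
  }
  if (length(matches) == 0L)
    return(data.frame(f_class = "unclassified",
                      evidence = "no signature matched",
                      stringsAsFactors = FALSE))
  assigned <- matches[1L]
  trail <- evid[1L]
  if (length(matches) > 1L)
    trail <- paste0(trail, "; also matched (lower precedence): ",
                    paste(matches[-1L], collapse = ", "))
  data.frame(f_class = assigned, evidence = trail, stringsAsFactors = FALSE)
}

#' Classify all detected systems
#'
#' Applies [classifyFClass()] to each row of a systems table.
#'
#' @param systems The `systems` data.frame from [detectChemoSystems()].
#' @param registry A [FlagellarRegistry-class].
#' @return `systems` with `f_class` and `evidence` columns filled.
#' @export
classifySystems <- function(systems, registry = loadRegistry()) {
  if (nrow(systems) == 0L) {
    systems$evidence <- character(0)
    return(systems)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(systems)), function(i)
    classifyFClass(systems[i, ], registry)))
  systems$f_class <- res$f_class
  systems$evidence <- res$evidence
  systems
}

#' Assign a chemoreceptor heptad (H) class from signaling-domain length
#'
#' The cytoplasmic signaling domain of MCP chemoreceptors comes in discrete
#' length classes counted in 7-residue heptads (e.g. 44H, 38H). The class
#' whose heptad count is nearest to `length/7` wins, provided the distance
#' is within that class's tolerance (default 2 heptads); otherwise
#' `"unassigned"`. A deterministic step function of length: perturbations
#' below tolerance x 7 / 2 residues never change the class.
#'
#' @param signaling_domain_length Domain length in residues (> 0).
#' @param registry A [FlagellarRegistry-class].
#' @return Heptad-class label or `"unassigned"`.
#' @export
classifyReceptorH <- function(signaling_domain_length,
                              registry = loadRegistry()) {
  if (length(signaling_domain_length) != 1L ||
      is.na(signaling_domain_length) || signaling_domain_length <= 0)
    stop("signaling_domain_length must be a single positive number")
  h <- hClassTable(registry)
  d <- abs(signaling_domain_length / 7 - h$heptad_count)
  i <- which.min(d)
  if (d[i] <= h$tolerance[i]) h$label[i] else "unassigned"
}

#' Per-genome cognate report: F classes versus receptor H-class counts
#'
#' For each genome: counts of chemoreceptors per heptad class, the modal
#' H class, the detected F classes, and whether the modal H class equals
#' the cognate heptad class of each detected F class (chemoreceptors of an
#' H category feed the array formed by their cognate F class: 44H for F1,
#' 38H for F5, 36H for F7, 44H for F9, 40H for ACF). Genomes with receptors
#' but no systems yield a row with counts only.
#'
#' @param systems Classified systems (see [classifySystems()]).
#' @param receptors Receptor records from [detectChemoSystems()].
#' @param registry A [FlagellarRegistry-class].
#' @return data.frame: `genome_id`, one `n_<label>` count column per heptad
#'   class (plus `n_unassigned`), `n_receptors`, `modal_h`, `f_classes`
#'   (comma-separated), `cognate_match` (comma-separated `class=TRUE/FALSE`).
#' @export
cognateReport <- function(systems, receptors, registry = loadRegistry()) {
  hlabs <- c(hClassTable(registry)$label, "unassigned")
  cog <- cognateHMap(registry)
  genomes <- union(unique(systems$genome_id), unique(receptors$genome_id))
  rows <- lapply(genomes, function(g) {
    rec <- receptors[receptors$genome_id == g, , drop = FALSE]
    counts <- table(factor(rec$h_class, levels = hlabs))
    assigned <- counts[setdiff(hlabs, "unassigned")]
    modal <- if (sum(assigned) == 0L) NA_character_ else {
      top <- names(assigned)[assigned == max(assigned)]
      if (length(top) > 1L) "ambiguous" else top
    }
    fcl <- unique(systems$f_class[systems$genome_id == g &
                                  !is.na(systems$f_class) &
                                  systems$f_class != "unclassified"])
    match_str <- if (length(fcl) == 0L) "" else
      paste(sprintf("%s=%s", fcl,
                    !is.na(modal) & modal == cog[fcl]), collapse = ",")
    out <- data.frame(genome_id = g, t(as.matrix(counts)),
                      n_receptors = nrow(rec),
                      modal_h = modal,
                      f_classes = paste(fcl, collapse = ","),
                      cognate_match = match_str,
                      stringsAsFactors = FALSE, check.names = FALSE)
    colnames(out)[2:(1 + length(hlabs))] <- paste0("n_", hlabs)
    out
  })
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
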