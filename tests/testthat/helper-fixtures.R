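# Shared fixture builders. Everything is constructed in code; no files are
# shipped.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Build a GRanges of gene calls from parallel vectors; genes are laid out
# 1 kb apart on one contig unless starts are given.
makeCalls <- function(labels, status = "present", contig = "ctg1",
                      strand = "+", genome_id = "G1", starts = NULL,
                      width = 900L) {
  n <- length(labels)
  if (is.null(starts)) starts <- seq(1L, by = 1000L, length.out = n)
  gr <- GRanges(contig, IRanges(starts, starts + width - 1L),
                strand = rep(strand, length.out = n))
  mcols(gr) <- DataFrame(genome_id = rep(genome_id, length.out = n),
                         locus_tag = sprintf("%s_%03d", genome_id, seq_len(n)),
                         status = rep(status, length.out = n),
                         label = labels)
  gr
}

# One homology-hit row in the reader's schema.
makeHit <- function(query, locus, evalue = 1e-30, bitscore = 200,
                    genome_id = "G1") {
  data.frame(genome_id = genome_id, query_symbol = query,
             subject_locus = locus, percent_identity = 50,
             alignment_length = 300, mismatches = 90, gap_opens = 2,
             q_start = 1, q_end = 300, s_start = 1, s_end = 300,
             evalue = evalue, bitscore = bitscore, query_coverage = 0.9,
             stringsAsFactors = FALSE)
}

makeDomain <- function(locus, domain = "GGDEF", s = 10L, e = 170L,
                       score = 60, genome_id = "G1") {
  data.frame(genome_id = genome_id, protein_locus = locus,
             domain_name = domain, env_start = s, env_end = e,
             score = score, stringsAsFactors = FALSE)
}

# A presence-matrix row: all registry genes set to `fill`, then overridden.
makeRow <- function(fill = "present", ..., registry = loadRegistry()) {
  genes <- geneCatalog(registry)$name
  row <- setNames(rep(fill, length(genes)), genes)
  override <- list(...)
  for (g in names(override)) row[g] <- override[[g]]
  row
}

# Independent brute-force bipartition oracle for Robinson-Foulds tests:
# walks the edge matrix directly, canonicalizes each split by the side not
# containing the first leaf (alphabetically), and drops trivial splits.
oracleBipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  ref <- sort(tree$tip.label)[1L]
  tipsUnder <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tipsUnder))
  }
  internal <- tree$edge[tree$edge[, 2L] > n, 2L]
  splits <- vapply(internal, function(node) {
    side <- tipsUnder(node)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  sizes <- lengths(strsplit(splits, "|", fixed = TRUE))
  unique(splits[sizes >= 2L & sizes <= n - 2L])
}

oracleRF <- function(t1, t2) {
  b1 <- oracleBipartitions(t1)
  b2 <- oracleBipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Direct translation of the stated calling rules, used as the truth-table
# oracle for callFlagellated.
oracleFlagellated <- function(states, allowance = 2L, exempt = character(),
                              registry = loadRegistry()) {
  core <- coreGeneSet(registry)
  req <- setdiff(core, exempt)
  s <- states[req]
  all(s != "absent") && sum(s == "pseudogene") <= allowance
}
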