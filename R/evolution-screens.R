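# GC-content HGT screen on the major flagellar cluster and the GGDEF-domain
# census with ecological group comparisons.

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous `N` bases are excluded from
#' both numerator and denominator. Letters outside A/C/G/T/N, or a sequence
#' with no countable bases, raise an error.
#'
#' @param sequence A character string, [Biostrings::DNAString] or length-1
#'   [Biostrings::DNAStringSet].
#' @return GC percentage (numeric scalar).
#' @examples
#' gcContent("GCGC")   # 100
#' gcContent("ATGCN")  # 50
#' @export
gcContent <- function(sequence) {
  if (is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- sequence[[1L]]
  }
  if (is.character(sequence)) {
    stopifnot(length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence))
      stop("sequence contains letters outside {A,C,G,T,N}")
    sequence <- Biostrings::DNAString(sequence)
  }
  counts <- letterFrequency(sequence, c("A", "C", "G", "T", "N"))
  if (sum(counts) != length(sequence))
    stop("sequence contains letters outside {A,C,G,T,N}")
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L)
    stop("empty or all-N sequence: GC content undefined")
  unname(100 * sum(counts[c("G", "C")]) / denom)
}

#' GC-content screen of a flagellar gene cluster for horizontal transfer
#'
#' Compares the GC content of the major flagellar gene cluster with the
#' whole-genome GC content. A cluster whose absolute difference strictly
#' exceeds `threshold` percentage points is flagged as a horizontal-transfer
#' candidate (in the genome-scale survey this screen motivated, only one
#' genome exceeded 5%, and even that one's flagellar proteins grouped
#' robustly with the other actinobacterial homologs). The screen is
#' symmetric in the sign of the difference. A genome without a detected
#' cluster yields an unflagged row with a `"no-cluster"` note.
#'
#' @param cluster_sequence Nucleotide sequence of the major cluster span
#'   (character / DNAString / DNAStringSet of length 1), or `NULL` when no
#'   cluster was detected.
#' @param genome_gc Whole-genome GC percent (from metadata, or computed).
#' @param threshold Flagging threshold in percentage points; default 5
#'   (strict inequality).
#' @param genome_id Optional identifier carried into the result.
#' @return One-row data.frame: `genome_id`, `cluster_gc`, `genome_gc`,
#'   `abs_difference`, `flagged`, `note`.
#' @export
hgtScreen <- function(cluster_sequence, genome_gc, threshold = 5,
                      genome_id = NA_character_) {
  if (is.null(cluster_sequence) || (is(cluster_sequence, "DNAStringSet") &&
                                    length(cluster_sequence) == 0L)) {
    return(data.frame(genome_id = genome_id, cluster_gc = NA_real_,
                      genome_gc = genome_gc, abs_difference = NA_real_,
                      flagged = FALSE, note = "no-cluster",
                      stringsAsFactors = FALSE))
  }
  cgc <- gcContent(cluster_sequence)
  d <- abs(cgc - genome_gc)
  data.frame(genome_id = genome_id, cluster_gc = cgc, genome_gc = genome_gc,
             abs_difference = d, flagged = d > threshold, note = "",
             stringsAsFactors = FALSE)
}

#' Census of GGDEF-domain-containing proteins per genome
#'
#' Counts, per genome, the distinct protein loci carrying at least one
#' GGDEF domain hit (the diguanylate-cyclase signature domain, a proxy for
#' the size of the c-di-GMP signaling network). A protein with multiple
#' GGDEF hits counts once. MAG genomes are excluded by default (domain
#' counts from incomplete assemblies undercount).
#'
#' @param domain_hits Domain-hit data.frame with a `genome_id` column.
#' @param meta Genome-metadata data.frame.
#' @param flagellated Optional named logical (by genome_id).
#' @param zoospore Optional named logical (by genome_id).
#' @param domain Domain name to census; default `"GGDEF"`.
#' @param include_mags Include MAG genomes; default FALSE.
#' @return data.frame: `genome_id`, `n_ggdef`, `ecology`, `flagellated`,
#'   `zoospore_former`.
#' @export
ggdefCensus <- function(domain_hits, meta, flagellated = NULL,
                        zoospore = NULL, domain = "GGDEF",
                        include_mags = FALSE) {
  .assertCols(meta, c("genome_id", "ecology", "assembly_level"),
              "genome metadata")
  .assertCols(domain_hits, c("genome_id", "protein_locus", "domain_name"),
              "domain hits")
  keep <- if (include_mags) meta else
    meta[meta$assembly_level != "MAG", , drop = FALSE]
  dh <- domain_hits[domain_hits$domain_name == domain, , drop = FALSE]
  counts <- vapply(keep$genome_id, function(g)
    length(unique(dh$protein_locus[dh$genome_id == g])), integer(1))
  lk <- function(v, ids) if (is.null(v)) rep(NA, length(ids)) else
    unname(v[ids])
  data.frame(genome_id = keep$genome_id, n_ggdef = unname(counts),
             ecology = keep$ecology,
             flagellated = lk(flagellated, keep$genome_id),
             zoospore_former = lk(zoospore, keep$genome_id),
             stringsAsFactors = FALSE)
}

#' Compare GGDEF counts between groups
#'
#' Summarizes a census by a grouping (n, mean, median per group) and, when
#' exactly two groups are compared, adds a rank-based two-sample test
#' (Wilcoxon rank-sum). A rank test is used because per-genome GGDEF counts
#' are heavily right-tailed (observed range 0–80); it is invariant under any
#' strictly increasing transform of the counts.
#'
#' @param census Census data.frame from [ggdefCensus()].
#' @param grouping Name of a census column (`"ecology"`, `"flagellated"`,
#'   `"zoospore_former"`) or a vector of group labels aligned with rows.
#' @return list with `summary` (data.frame: group, n, mean, median) and
#'   `test` (an `htest` for two groups, else `NULL`).
#' @export
groupCompare <- function(census, grouping) {
  g <- if (length(grouping) == 1L && is.character(grouping) &&
           grouping %in% colnames(census)) census[[grouping]] else grouping
  if (length(g) != nrow(census))
    stop("grouping must name a census column or match its row count")
  if (anyNA(g))
    stop("grouping contains missing values; annotate every genome")
  g <- if (is.factor(g)) g else factor(g)
  sizes <- table(g)
  if (any(sizes == 0L))
    stop("empty group(s): ", paste(names(sizes)[sizes == 0L], collapse = ", "))
  x <- census$n_ggdef
  summ <- data.frame(group = names(sizes), n = as.integer(sizes),
                     mean = as.numeric(tapply(x, g, mean)),
                     median = as.numeric(tapply(x, g, median)),
                     stringsAsFactors = FALSE)
  test <- NULL
  if (nlevels(g) == 2L) {
    lv <- levels(g)
    test <- suppressWarnings(
      wilcox.test(x[g == lv[1L]], x[g == lv[2L]], exact = FALSE))
  }
  list(summary = summ, test = test)
}
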