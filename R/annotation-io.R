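# Readers/writers for external formats and the genome-metadata QC filter.
# Coordinates are 1-based inclusive (GFF3 convention) throughout.

.ASSEMBLY_LEVELS <- c("complete", "draft", "MAG")
.ECOLOGIES <- c("sea", "terrestrial_water", "soil", "host_associated", "other")
.STATUS_LEVELS <- c("present", "pseudogene", "partial")

#' Read a GFF3 annotation into gene-call skeletons
#'
#' Parses CDS and pseudogene features of a GFF3 file into a [GRanges] of
#' unlabeled gene calls (label `"unassigned"`): coordinates and strand are
#' preserved exactly, the `ID` (or `locus_tag`) attribute becomes the locus
#' tag, features typed `pseudogene` or carrying `pseudo=true` get status
#' `pseudogene`, and features carrying `partial=true` get status `partial`
#' provided the call lies within `edge_margin` bp of a contig edge (contig
#' lengths from `##sequence-region` pragmas when present). Other feature
#' types are skipped with a message. Malformed lines (not 9 tab-separated
#' fields) raise an error naming the line number.
#'
#' @param path GFF3 file path.
#' @param edge_margin Maximum distance (bp) from a contig edge for a
#'   partial-flagged call to keep status `partial`; default 20.
#' @return [GRanges] with metadata columns `locus_tag`, `status`, `label`.
#' @export
readGff <- function(path, edge_margin = 20L) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                 bad, path, nfield[which(nfield != 9L)[1L]]))
  }
  seqlens <- .gffSeqlens(lines)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "pseudogene")
  nskip <- sum(!keep)
  if (nskip > 0L)
    message(sprintf("readGff: skipped %d feature(s) of other types in %s",
                    nskip, basename(path)))
  gr <- gr[keep]
  if (length(gr) == 0L) {
    out <- GRanges()
    mcols(out)$locus_tag <- character()
    mcols(out)$status <- character()
    mcols(out)$label <- character()
    return(out)
  }
  tag <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    tag <- ifelse(is.na(tag) | !nzchar(tag), lt, tag)
  }
  if (anyNA(tag)) stop("GFF3 feature without ID/locus_tag attribute in ", path)
  status <- rep("present", length(gr))
  pseudo <- as.character(gr$type) == "pseudogene"
  if (!is.null(gr$pseudo))
    pseudo <- pseudo | tolower(as.character(gr$pseudo)) %in% "true"
  status[pseudo] <- "pseudogene"
  if (!is.null(gr$partial)) {
    part <- tolower(as.character(gr$partial)) %in% "true"
    at_edge <- .atContigEdge(gr, seqlens, edge_margin)
    status[part & at_edge & !pseudo] <- "partial"
  }
  out <- granges(gr)
  mcols(out) <- DataFrame(locus_tag = tag, status = status,
                          label = "unassigned")
  out
}

#' @noRd
.gffSeqlens <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr) == 0L) return(integer())
  parts <- strsplit(trimws(sr), "\\s+")
  setNames(vapply(parts, function(p) as.integer(p[4L]), integer(1)),
           vapply(parts, function(p) p[2L], character(1)))
}

#' @noRd
.atContigEdge <- function(gr, seqlens, margin) {
  near_start <- start(gr) <= margin + 1L
  ctg <- as.character(seqnames(gr))
  near_end <- rep(TRUE, length(gr))          # unknown length: trust the flag
  known <- ctg %in% names(seqlens)
  near_end[known] <- end(gr)[known] >= seqlens[ctg[known]] - margin
  near_start | near_end
}

#' Read 12-column tabular homology hits (BLAST outfmt-6 dialect)
#'
#' Loads all rows or rejects the file: a row with a column count other than
#' 12, a negative E-value or bitscore, or an unparseable number raises an
#' error naming the row. Scientific-notation E-values parse. The returned
#' table carries `query_coverage = NA` (a 12-column file does not carry
#' query lengths; generators may fill it).
#'
#' @param path Tab-separated hits file; may be empty (returns a 0-row table).
#' @return data.frame with columns `query_symbol`, `subject_locus`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`,
#'   `query_coverage`.
#' @export
readTabularHits <- function(path) {
  cols <- c("query_symbol", "subject_locus", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "q_start",
            "q_end", "s_start", "s_end", "evalue", "bitscore")
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12L), cols))
    out$query_coverage <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L)
    stop(sprintf("parse error in %s: row %d has %d columns, expected 12",
                 path, bad[1L], lengths(fields)[bad[1L]]))
  m <- do.call(rbind, fields)
  out <- data.frame(query_symbol = m[, 1L], subject_locus = m[, 2L],
                    stringsAsFactors = FALSE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(apply(num, 1L, anyNA))[1L]
    stop(sprintf("parse error in %s: row %d has a non-numeric field", path, bad))
  }
  out[cols[3:12]] <- as.data.frame(num)
  if (any(out$evalue < 0))
    stop("parse error in ", path, ": negative E-value at row ",
         which(out$evalue < 0)[1L])
  if (any(out$bitscore < 0))
    stop("parse error in ", path, ": negative bitscore at row ",
         which(out$bitscore < 0)[1L])
  out$query_coverage <- NA_real_
  out
}

#' Read tabular protein-domain hits
#'
#' A domtblout-like tab-separated table with columns `protein_locus`,
#' `domain_name`, `env_start`, `env_end`, `score` (1-based inclusive residue
#' coordinates). Rows with `env_start > env_end` are rejected.
#'
#' @param path Domain-hit table path.
#' @return data.frame with the five columns above.
#' @export
readDomainHits <- function(path) {
  if (!file.exists(path)) stop("domain-hit file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  .assertCols(dt, c("protein_locus", "domain_name", "env_start", "env_end",
                    "score"), "domain-hit table")
  if (any(dt$env_start > dt$env_end))
    stop("domain-hit table ", path, ": env_start > env_end at row ",
         which(dt$env_start > dt$env_end)[1L])
  dt
}

#' Read the genome-metadata table
#'
#' Tab-separated with columns `genome_id`, `species`, `tax_class`, `ecology`,
#' `assembly_level` (complete/draft/MAG), `completeness`, `contamination`,
#' `genome_gc` (all percent), `genome_size` (bp). Percent fields outside
#' \[0, 100\] or non-positive sizes are rejected rather than coerced.
#'
#' @param path Metadata TSV path.
#' @return data.frame, one row per genome.
#' @export
readGenomeMeta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  .assertCols(dt, c("genome_id", "species", "tax_class", "ecology",
                    "assembly_level", "completeness", "contamination",
                    "genome_gc", "genome_size"), "genome metadata")
  .validateMeta(dt)
  dt
}

#' @noRd
.validateMeta <- function(meta) {
  for (col in c("completeness", "contamination", "genome_gc")) {
    bad <- which(is.na(meta[[col]]) | meta[[col]] < 0 | meta[[col]] > 100)
    if (length(bad) > 0L)
      stop(sprintf("metadata %s out of [0,100] for genome(s): %s", col,
                   paste(meta$genome_id[bad], collapse = ", ")))
  }
  if (any(meta$genome_size <= 0))
    stop("metadata genome_size must be > 0 for genome(s): ",
         paste(meta$genome_id[meta$genome_size <= 0], collapse = ", "))
  if (!all(meta$assembly_level %in% .ASSEMBLY_LEVELS))
    stop("unknown assembly_level for genome(s): ",
         paste(meta$genome_id[!meta$assembly_level %in% .ASSEMBLY_LEVELS],
               collapse = ", "))
  invisible(meta)
}

#' Quality-control filter on genome metadata
#'
#' Removes a genome iff `completeness < 80` OR `contamination > 5`, unless
#' its `genome_id` is whitelisted. OR-semantics is used for the removal
#' clause: the documented exceptions this filter exists for are two
#' flagellated deep-sea isolates whose only defect is contamination slightly
#' above 5% (7.12% and 6.03%), which only need exempting if either defect
#' alone removes a genome. The partition is exhaustive and disjoint, and the
#' filter is idempotent.
#'
#' @param meta Genome-metadata data.frame (see [readGenomeMeta()]).
#' @param whitelist Character vector of genome_ids exempt from removal.
#' @param min_completeness,max_contamination Thresholds (percent); defaults
#'   80 and 5.
#' @return list with data.frames `retained` and `removed`.
#' @export
qcFilter <- function(meta, whitelist = character(),
                     min_completeness = 80, max_contamination = 5) {
  .assertCols(meta, c("genome_id", "completeness", "contamination"),
              "genome metadata")
  bad <- which(is.na(meta$completeness) | is.na(meta$contamination))
  if (length(bad) > 0L)
    stop("missing completeness/contamination for genome(s): ",
         paste(meta$genome_id[bad], collapse = ", "))
  fails <- (meta$completeness < min_completeness |
            meta$contamination > max_contamination) &
           !(meta$genome_id %in% whitelist)
  list(retained = meta[!fails, , drop = FALSE],
       removed = meta[fails, , drop = FALSE])
}

#' Write / read a presence matrix as TSV
#'
#' One row per genome, one column per registry gene in registry order; cells
#' are `1` (present), `0` (absent), `P` (pseudogene), `H` (half/partial,
#' i.e. a coding sequence truncated by a contig edge). The pair of functions
#' round-trips losslessly.
#'
#' @param matrix A [PresenceMatrix-class].
#' @param path Output (or input) TSV path.
#' @return `writePresenceMatrix`: `path` invisibly; `readPresenceMatrix`:
#'   a [PresenceMatrix-class].
#' @rdname presence-io
#' @export
writePresenceMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "PresenceMatrix"))
  code <- c(present = "1", absent = "0", pseudogene = "P", partial = "H")
  m <- matrix@cells
  coded <- structure(code[m], dim = dim(m), dimnames = dimnames(m))
  df <- data.frame(genome_id = rownames(coded), coded, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- try(fwrite(df, path, sep = "\t"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write presence matrix to ", path, ": ",
         attr(ok, "condition")$message)
  invisible(path)
}

#' @rdname presence-io
#' @export
readPresenceMatrix <- function(path) {
  if (!file.exists(path)) stop("presence-matrix file not found: ", path)
  df <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
              colClasses = "character")
  if (colnames(df)[1L] != "genome_id")
    stop("presence-matrix TSV must start with a genome_id column: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$genome_id
  decode <- c(`1` = "present", `0` = "absent", P = "pseudogene", H = "partial")
  if (!all(m %in% names(decode)))
    stop("presence-matrix cells must be one of 1/0/P/H: ", path)
  cells <- structure(unname(decode[m]), dim = dim(m),
                     dimnames = dimnames(m))
  PresenceMatrix(cells)
}
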