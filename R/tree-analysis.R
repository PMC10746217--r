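# Species-tree / flagellar-tree concordance and inter-class transfer
# detection.

#' Read / write Newick trees
#'
#' Thin, validating wrappers around [ape::read.tree()] /
#' [ape::write.tree()]: unbalanced parentheses are reported with their
#' character position, and duplicate leaf labels are an error (leaf labels
#' are genome identifiers and must be unique). Branch lengths and support
#' values are preserved to printed precision.
#'
#' @param path Newick file path.
#' @param tree A `phylo` object (for `writeNewickTree`).
#' @return `readNewickTree`: a `phylo`; `writeNewickTree`: `path` invisibly.
#' @rdname newick-io
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  txt <- paste(readLines(path), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1L]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1L]] == ")", -1L, 0L)))
  if (any(depth < 0L))
    stop(sprintf("Newick parse error in %s: unbalanced ')' at position %d",
                 path, which(depth < 0L)[1L]))
  if (tail(depth, 1L) != 0L)
    stop(sprintf("Newick parse error in %s: %d unclosed '(' at end of input",
                 path, tail(depth, 1L)))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate leaf label(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  tree
}

#' @rdname newick-io
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Robinson–Foulds distance between two leaf-labeled trees
#'
#' The size of the symmetric difference of the non-trivial bipartition sets
#' of the two trees, compared unrooted (rooted inputs are unrooted first).
#' Zero iff the topologies are identical; symmetric in its arguments; a
#' metric on leaf-labeled topologies over a fixed leaf set. Operationalizes
#' "very similar topology" claims about species-tree/gene-tree pairs as a
#' number.
#'
#' @param t1,t2 `phylo` objects over identical leaf sets (error listing the
#'   difference otherwise).
#' @return list: `rf_distance`, `shared_bipartitions`, `max_possible`
#'   (= total non-trivial bipartitions across both trees, the distance
#'   attained by two completely conflicting trees).
#' @export
robinsonFoulds <- function(t1, t2) {
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) > 0L || length(only2) > 0L)
    stop("leaf sets differ; only in tree 1: {",
         paste(only1, collapse = ", "), "}; only in tree 2: {",
         paste(only2, collapse = ", "), "}")
  u1 <- if (is.rooted(t1)) unroot(t1) else t1
  u2 <- if (is.rooted(t2)) unroot(t2) else t2
  rf <- as.numeric(phangorn::RF.dist(u1, u2, check.labels = TRUE))
  b <- function(t) t$Nnode - 1L   # internal edges of an unrooted tree
  total <- b(u1) + b(u2)
  list(rf_distance = rf, shared_bipartitions = (total - rf) / 2,
       max_possible = total)
}

#' @noRd
.sisterMajority <- function(tree, tip_index, classes) {
  parent <- tree$edge[tree$edge[, 2L] == tip_index, 1L]
  kids <- tree$edge[tree$edge[, 1L] == parent, 2L]
  kids <- kids[kids != tip_index]
  tips <- unlist(phangorn::Descendants(tree, kids, type = "tips"))
  cls <- classes[tree$tip.label[tips]]
  tab <- sort(table(cls), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L])
    return(NA_character_)               # tie: ambiguous
  names(tab)[1L]
}

#' Detect inter-class transfers from gene-tree / species-tree discordance
#'
#' A leaf is reported as an inter-class transfer iff the majority taxonomic
#' class among its sister clade in the gene tree differs from its own class,
#' while in the species tree its sister-clade majority matches its own class
#' (i.e. the species tree places it with its kin, the gene tree does not).
#' Majority ties are reported separately as ambiguous rather than silently
#' resolved. When the gene tree equals the species tree the report is empty
#' for any class annotation. This is the package's operationalization of
#' clade-level exchange claims (e.g. a single flagellar exchange between
#' two classes across an otherwise concordant tree pair).
#'
#' @param gene_tree,species_tree `phylo` objects over the same leaves.
#' @param classes Named character vector mapping every leaf to its
#'   taxonomic class (error if any leaf is unannotated).
#' @return list with `transfers` (data.frame: leaf, expected_class,
#'   observed_sister_class) and `ambiguous` (data.frame: leaf, tree, note).
#' @export
detectInterclassTransfers <- function(gene_tree, species_tree, classes) {
  leaves <- gene_tree$tip.label
  if (!setequal(leaves, species_tree$tip.label))
    stop("gene tree and species tree must share the same leaf set")
  missing <- setdiff(leaves, names(classes))
  if (length(missing) > 0L)
    stop("unannotated leaf/leaves: ", paste(missing, collapse = ", "))
  transfers <- list()
  ambig <- list()
  for (leaf in leaves) {
    gi <- which(gene_tree$tip.label == leaf)
    si <- which(species_tree$tip.label == leaf)
    gmaj <- .sisterMajority(gene_tree, gi, classes)
    smaj <- .sisterMajority(species_tree, si, classes)
    own <- classes[[leaf]]
    if (is.na(gmaj)) {
      ambig[[length(ambig) + 1L]] <- data.frame(
        leaf = leaf, tree = "gene",
        note = "sister-clade class majority tied", stringsAsFactors = FALSE)
      next
    }
    if (gmaj != own && !is.na(smaj) && smaj == own) {
      transfers[[length(transfers) + 1L]] <- data.frame(
        leaf = leaf, expected_class = own, observed_sister_class = gmaj,
        stringsAsFactors = FALSE)
    }
  }
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  list(transfers = if (length(transfers)) do.call(rbind, transfers) else
         empty(leaf = character(), expected_class = character(),
               observed_sister_class = character()),
       ambiguous = if (length(ambig)) do.call(rbind, ambig) else
         empty(leaf = character(), tree = character(), note = character()))
}
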