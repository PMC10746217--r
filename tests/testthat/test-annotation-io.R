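writeGffLines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("readGff maps CDS, pseudogene and contig-edge partial features", {
  path <- writeGffLines(c(
    "##sequence-region ctg1 1 5000",
    "ctg1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=loc1",
    "ctg1\tsrc\tCDS\t600\t900\t.\t-\t0\tID=loc2;pseudo=true",
    "ctg1\tsrc\tCDS\t4700\t4995\t.\t+\t0\tID=loc3;partial=true",
    "ctg1\tsrc\tCDS\t2000\t2500\t.\t+\t0\tID=loc4;partial=true",
    "ctg1\tsrc\tregion\t1\t5000\t.\t+\t.\tID=reg1"))
  gr <- suppressMessages(readGff(path))
  expect_length(gr, 4L)          # region feature skipped
  expect_equal(start(gr)[1], 100L)
  expect_equal(end(gr)[1], 400L)
  expect_equal(as.character(strand(gr))[1], "+")
  st <- setNames(mcols(gr)$status, mcols(gr)$locus_tag)
  expect_equal(st[["loc1"]], "present")
  expect_equal(st[["loc2"]], "pseudogene")
  expect_equal(st[["loc3"]], "partial")     # within 20 bp of the contig end
  expect_equal(st[["loc4"]], "present")     # partial flag mid-contig ignored
  expect_true(all(mcols(gr)$label == "unassigned"))
})

test_that("readGff rejects malformed lines with the line number", {
  path <- writeGffLines(c(
    "ctg1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=loc1",
    "ctg1\tsrc\tCDS\t100\t400"))
  expect_error(readGff(path), "line 3")
})

test_that("readTabularHits parses 12-column hit tables strictly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FliF\tloc1\t45.2\t300\t120\t3\t1\t300\t1\t300\t1e-30\t250",
               "FliM\tloc2\t38.0\t250\t130\t4\t1\t250\t5\t254\t2.5e-08\t90"),
             path)
  h <- readTabularHits(path)
  expect_equal(nrow(h), 2L)
  expect_equal(h$evalue, c(1e-30, 2.5e-8))
  expect_equal(h$query_symbol, c("FliF", "FliM"))
  expect_true(all(is.na(h$query_coverage)))

  writeLines(character(), path)
  expect_equal(nrow(readTabularHits(path)), 0L)

  writeLines("FliF\tloc1\t45.2\t300\t120\t3\t1\t300\t1\t300\t1e-30", path)
  expect_error(readTabularHits(path), "11 columns")

  writeLines("FliF\tloc1\t45.2\t300\t120\t3\t1\t300\t1\t300\t1e-30\t-5",
             path)
  expect_error(readTabularHits(path), "negative bitscore")
})

test_that("domain-hit reader enforces coordinate sanity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_locus\tdomain_name\tenv_start\tenv_end\tscore",
               "p1\tGGDEF\t10\t170\t60",
               "p2\tCheW\t200\t100\t30"), path)
  expect_error(readDomainHits(path), "env_start > env_end")
})

test_that("qcFilter removes on completeness OR contamination, honors the whitelist, and is idempotent", {
  meta <- data.frame(
    genome_id = c("ok", "lowc", "highcont", "exempt1", "exempt2"),
    completeness = c(90, 75, 90, 92, 88),
    contamination = c(1, 0, 6, 7.12, 6.03),
    stringsAsFactors = FALSE)
  res <- qcFilter(meta, whitelist = c("exempt1", "exempt2"))
  expect_setequal(res$retained$genome_id, c("ok", "exempt1", "exempt2"))
  expect_setequal(res$removed$genome_id, c("lowc", "highcont"))
  # exhaustive and disjoint partition
  expect_equal(sort(c(res$retained$genome_id, res$removed$genome_id)),
               sort(meta$genome_id))
  # idempotent
  again <- qcFilter(res$retained, whitelist = c("exempt1", "exempt2"))
  expect_equal(nrow(again$removed), 0L)
  # missing metadata is an error naming the genome
  meta$contamination[2] <- NA
  expect_error(qcFilter(meta), "lowc")
})

test_that("presence matrix TSV round-trips all four states", {
  genes <- geneCatalog(loadRegistry())$name
  m <- matrix("present", nrow = 2, ncol = length(genes),
              dimnames = list(c("GA", "GB"), genes))
  m["GA", "FliC"] <- "pseudogene"
  m["GA", "MotA"] <- "absent"
  m["GB", "FlgE"] <- "partial"
  pm <- PresenceMatrix(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePresenceMatrix(pm, path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  expect_equal(raw[raw$genome_id == "GA", "FliC"], "P")
  expect_equal(raw[raw$genome_id == "GA", "MotA"], "0")
  expect_equal(raw[raw$genome_id == "GB", "FlgE"], "H")
  back <- readPresenceMatrix(path)
  expect_equal(presenceCells(back), presenceCells(pm))
})

test_that("metadata reader rejects out-of-range percents", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(genome_id = "g", species = "s", tax_class = "Actinomycetia",
                   ecology = "soil", assembly_level = "complete",
                   completeness = 101, contamination = 0, genome_gc = 65,
                   genome_size = 1e6)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readGenomeMeta(path), "completeness")
})
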