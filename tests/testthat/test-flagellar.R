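test_that("assignLabels picks the best passing hit deterministically", {
  calls <- makeCalls(rep("unassigned", 4))
  tags <- mcols(calls)$locus_tag
  hits <- rbind(
    makeHit("FliF", tags[1], evalue = 1e-40),
    makeHit("FliM", tags[2], evalue = 1e-8),
    makeHit("FliN", tags[2], evalue = 1e-12),      # better E-value wins
    makeHit("MotA", tags[3], evalue = 1e-4),       # at/above threshold: ignored
    makeHit("FlgK", tags[4], evalue = 1e-20, bitscore = 100),
    makeHit("FlgL", tags[4], evalue = 1e-20, bitscore = 300)) # bitscore tie-break
  out <- assignLabels(hits, calls)
  lab <- setNames(mcols(out)$label, tags)
  expect_equal(unname(lab), c("FliF", "FliN", "unassigned", "FlgL"))
})

test_that("assignLabels canonicalizes organism aliases and flags orphans", {
  calls <- makeCalls(rep("unassigned", 2))
  tags <- mcols(calls)$locus_tag
  out <- assignLabels(rbind(makeHit("FlaG", tags[1]),
                            makeHit("CwlQ", tags[2])), calls)
  expect_equal(unname(mcols(out)$label), c("YvyC", "FlgJ"))
  expect_error(assignLabels(makeHit("FliF", "nope"), calls), "nope")
})

test_that("rod/hook disambiguation follows the flgD-flgE and flgF-flgG cues", {
  # candidate directly downstream of FlgD -> FlgE; distant pair -> FlgF/FlgG
  calls <- makeCalls(c("FlgD", "FlgE", "FliK", "FliM", "FliN", "FliP",
                       "FlgG", "FlgF"))
  out <- disambiguateRodHook(calls)
  expect_equal(mcols(out)$label[2], "FlgE")
  expect_equal(mcols(out)$label[7:8], c("FlgF", "FlgG"))  # upstream first
  # conservation: only labels change
  expect_equal(mcols(out)$locus_tag, mcols(calls)$locus_tag)
  expect_equal(granges(out), granges(calls))
})

test_that("disambiguation resolves the contiguous flgDEFG arrangement", {
  calls <- makeCalls(c("FlgB", "FlgC", "FlgD", "FlgE", "FlgF", "FlgG"))
  out <- disambiguateRodHook(calls)
  expect_equal(mcols(out)$label[3:6], c("FlgD", "FlgE", "FlgF", "FlgG"))
})

test_that("minus-strand pairs are ordered transcriptionally", {
  calls <- makeCalls(c("FlgE", "FlgF"), strand = "-")
  out <- disambiguateRodHook(calls)
  # transcription runs right to left: the downstream-coordinate gene is FlgF
  expect_equal(mcols(out)$label, c("FlgG", "FlgF"))
})

test_that("candidates without a cue stay ambiguous, never doubly assigned", {
  lone <- makeCalls("FlgF")
  expect_equal(mcols(disambiguateRodHook(lone))$label, "FlgEFG_ambiguous")
  trio <- makeCalls(c("FlgE", "FlgF", "FlgG"))
  out <- disambiguateRodHook(trio)
  expect_true(all(mcols(out)$label == "FlgEFG_ambiguous"))
  pair_near_d <- makeCalls(c("FlgD", "FlgE", "FlgF", "FlgG"))
  lab <- mcols(disambiguateRodHook(pair_near_d))$label
  expect_equal(sum(lab == "FlgF"), 1L)
  expect_equal(sum(lab == "FlgG"), 1L)
})

test_that("presence matrix applies the present > pseudogene > partial precedence", {
  calls <- c(makeCalls(c("FliC", "FliC"), status = c("pseudogene", "present")),
             makeCalls("FlgK", status = "pseudogene",
                       starts = 50000L),
             makeCalls("FlgL", status = "partial", starts = 60000L))
  pm <- buildPresenceMatrix(calls)
  row <- presenceCells(pm)["G1", ]
  expect_equal(unname(row["FliC"]), "present")
  expect_equal(unname(row["FlgK"]), "pseudogene")
  expect_equal(unname(row["FlgL"]), "partial")
  expect_equal(unname(row["MotA"]), "absent")
  expect_equal(geneSymbols(pm), geneCatalog(loadRegistry())$name)
})

test_that("flagellated call enforces the complete-genome core rule", {
  # all 24 core present
  expect_true(callFlagellated(makeRow(), "complete")$flagellated)
  # 22 present + 2 core pseudogenes: allowed; 3 pseudogenes: not
  two <- makeRow(FliC = "pseudogene", FlgK = "pseudogene")
  expect_true(callFlagellated(two, "complete")$flagellated)
  three <- makeRow(FliC = "pseudogene", FlgK = "pseudogene",
                   FliM = "pseudogene")
  expect_false(callFlagellated(three, "complete")$flagellated)
  # an absent core gene (other than the exempt rod pair) is disqualifying
  expect_false(callFlagellated(makeRow(FliM = "absent"),
                               "complete")$flagellated)
  # partial counts as present
  expect_true(callFlagellated(makeRow(FliM = "partial"),
                              "complete")$flagellated)
  expect_error(callFlagellated(makeRow(), "plasmid"), "assembly_level")
})

test_that("the FlgF/FlgG exemption reflects later-class rod composition", {
  later <- makeRow(FlgF = "absent", FlgG = "absent")
  expect_true(callFlagellated(later, "complete")$flagellated)
  # strict reading available
  expect_false(callFlagellated(later, "complete",
                               core_exempt = character())$flagellated)
})

test_that("MAG tier uses the 10-core threshold and reports the 20-core representative flag", {
  mkMag <- function(n_present) {
    core <- coreGeneSet(loadRegistry())
    row <- makeRow(fill = "absent")
    row[core[seq_len(n_present)]] <- "present"
    row
  }
  expect_true(callFlagellated(mkMag(10), "MAG")$flagellated)
  expect_false(callFlagellated(mkMag(9), "MAG")$flagellated)
  r <- callFlagellated(mkMag(20), "MAG")
  expect_true(r$representative_ok)
  expect_false(callFlagellated(mkMag(19), "MAG")$representative_ok)
  expect_equal(r$tier, "mag_rule")
})

test_that("flagellated call is monotone in cell upgrades", {
  reg <- loadRegistry()
  core <- coreGeneSet(reg)
  set.seed(42)
  for (i in 1:60) {
    row <- makeRow()
    bad <- sample(core, sample(0:4, 1))
    row[bad] <- sample(c("absent", "pseudogene"), length(bad),
                       replace = TRUE)
    for (level in c("complete", "MAG")) {
      before <- callFlagellated(row, level)$flagellated
      up <- row
      target <- sample(names(row), 1)
      up[target] <- "present"
      after <- callFlagellated(up, level)$flagellated
      expect_true(after >= before)
    }
  }
})

test_that("countFlagellarGenes counts non-absent cells", {
  expect_equal(countFlagellarGenes(makeRow(fill = "absent")), 0L)
  expect_equal(countFlagellarGenes(makeRow()), 50L)
  row <- makeRow(fill = "absent")
  row[1:30] <- "present"
  row[31:32] <- "pseudogene"
  expect_equal(countFlagellarGenes(row), 32L)
})

test_that("major cluster detection merges by gap and reports outliers and ties", {
  labs30 <- geneCatalog(loadRegistry())$name[1:30]
  one <- makeCalls(labs30)
  res <- detectMajorCluster(one)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$major$n_genes, 30L)
  expect_equal(nrow(res$outliers), 0L)

  # 28 contiguous + 2 genes 500 kb away
  split2 <- makeCalls(labs30, starts = c(seq(1, by = 1000, length.out = 28),
                                         500000, 501000))
  res2 <- detectMajorCluster(split2)
  expect_equal(res2$major$n_genes, 28L)
  expect_equal(nrow(res2$outliers), 2L)

  # two equal clusters of 15: tie reported, broken by larger span
  wide <- makeCalls(labs30,
                    starts = c(seq(1, by = 2000, length.out = 15),
                               seq(900000, by = 1000, length.out = 15)))
  res3 <- detectMajorCluster(wide)
  expect_true(res3$tie)
  expect_equal(res3$major$start, 1L)     # the wider cluster wins
  expect_equal(res3$major$n_genes, 15L)

  expect_equal(nrow(detectMajorCluster(makeCalls("unassigned"))$clusters),
               0L)
})
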