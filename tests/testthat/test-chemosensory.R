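f5Calls <- function(genome_id = "G1") {
  makeCalls(c("CheA", "CheW", "MCP", "CheB", "CheR"),
            genome_id = genome_id)
}

f5Domains <- function(calls) {
  tags <- mcols(calls)$locus_tag
  rbind(makeDomain(tags[1], "CheW", 620, 760),
        makeDomain(tags[3], "MCP-signal", 200, 200 + 266 - 1))
}

test_that("a contiguous operon becomes one system with the right order string", {
  calls <- f5Calls()
  det <- detectChemoSystems(calls, f5Domains(calls))
  expect_equal(nrow(det$systems), 1L)
  expect_equal(det$systems$order_string, "A:W W M B R")
  expect_true(grepl("CheA:W", det$systems$components))
  expect_equal(nrow(det$receptors), 1L)
  expect_true(det$receptors$in_system)
})

test_that("scattered chemoreceptors are records, not systems", {
  calls <- makeCalls(c("MCP", rep("unassigned", 6), "MCP",
                       rep("unassigned", 6), "MCP"))
  tags <- mcols(calls)$locus_tag[c(1, 8, 15)]
  dh <- do.call(rbind, lapply(tags, makeDomain, domain = "MCP-signal",
                              s = 200, e = 200 + 308 - 1))
  det <- detectChemoSystems(calls, dh)
  expect_equal(nrow(det$systems), 0L)
  expect_equal(nrow(det$receptors), 3L)
  expect_true(all(det$receptors$h_class == "44H"))
  expect_false(any(det$receptors$in_system))
})

test_that("runs separated by many unrelated genes form separate systems", {
  calls <- makeCalls(c("CheA", "CheW", rep("unassigned", 50),
                       "CheB", "CheR"))
  det <- detectChemoSystems(calls, makeDomain("none", "CheW")[0, ])
  expect_equal(nrow(det$systems), 2L)
})

test_that("the chemotaxis core four is a genome-wide presence check", {
  yes <- makeCalls(c("MCP", "CheA", "CheW", "CheY"))
  expect_true(hasChemotaxisSet(yes)[["G1"]])
  no_mcp <- makeCalls(c("CheA", "CheW", "CheY"))
  expect_false(hasChemotaxisSet(no_mcp)[["G1"]])
  none <- makeCalls(c("FliC", "FlgE", "MotA"))
  expect_false(hasChemotaxisSet(none)[["G1"]])
})

test_that("F-class assignment follows the diagnostic rules with precedence", {
  reg <- loadRegistry()
  sys <- function(components, order_string)
    data.frame(components = components, order_string = order_string,
               stringsAsFactors = FALSE)
  # F1: CheC + CheD, no order requirement
  expect_equal(classifyFClass(
    sys("CheA,CheB,CheC,CheD,CheR,CheW", "C A W D B R"), reg)$f_class, "F1")
  # F5: kinase variant plus AW...BR, M and Y interleaved are ignored
  expect_equal(classifyFClass(
    sys("CheA:W,CheB,CheR,CheW,MCP,CheY", "A:W W M B R Y"), reg)$f_class,
    "F5")
  # plain backbone in the wrong order matches nothing
  expect_equal(classifyFClass(
    sys("CheA,CheB,CheR,CheW", "R A W B"), reg)$f_class, "unclassified")
  # placeholder signatures for the remaining classes
  expect_equal(classifyFClass(
    sys("CheA,CheB,CheR,CheW,CheX", "A W X B R"), reg)$f_class, "F7")
  expect_equal(classifyFClass(
    sys("CheA,CheB,CheC,CheR,CheW", "A W C B R"), reg)$f_class, "F9")
  expect_equal(classifyFClass(
    sys("CheA,CheB,CheD,CheR,CheW", "A W D B R"), reg)$f_class, "ACF")
  # conflicts surface in the evidence trail, and F1 outranks F5
  both <- classifyFClass(
    sys("CheA:W,CheB,CheC,CheD,CheR,CheW", "A:W W C D B R"), reg)
  expect_equal(both$f_class, "F1")
  expect_match(both$evidence, "also matched")
})

test_that("a missing kinase variant or broken order rules out F5", {
  reg <- loadRegistry()
  sys <- function(components, order_string)
    data.frame(components = components, order_string = order_string,
               stringsAsFactors = FALSE)
  expect_equal(classifyFClass(
    sys("CheA,CheB,CheR,CheW", "A W B R"), reg)$f_class, "unclassified")
  expect_equal(classifyFClass(
    sys("CheA:W,CheB,CheR,CheW", "W A:W B R"), reg)$f_class, "unclassified")
})

test_that("heptad classification is nearest-class within tolerance", {
  reg <- loadRegistry()
  expect_equal(classifyReceptorH(308, reg), "44H")   # 44 x 7
  expect_equal(classifyReceptorH(266, reg), "38H")   # 38 x 7
  expect_equal(classifyReceptorH(150, reg), "unassigned")
  expect_error(classifyReceptorH(0, reg), "positive")
  # step function: perturbations below tolerance*7/2 never change the class
  for (L in c(266, 308)) {
    base <- classifyReceptorH(L, reg)
    for (d in c(-6, -3, 3, 6))
      expect_equal(classifyReceptorH(L + d, reg), base)
  }
})

test_that("cognate report pairs modal receptor type with each F class", {
  reg <- loadRegistry()
  systems <- data.frame(genome_id = c("GA", "GB"),
                        f_class = c("F1", "F5"),
                        stringsAsFactors = FALSE)
  receptors <- data.frame(
    genome_id = c(rep("GA", 11), rep("GB", 5), rep("GC", 2)),
    protein_locus = sprintf("p%02d", 1:18),
    signaling_domain_length = 1,
    h_class = c(rep("44H", 10), "38H", rep("38H", 5), rep("40H", 2)),
    stringsAsFactors = FALSE)
  rep <- cognateReport(systems, receptors, reg)
  ga <- rep[rep$genome_id == "GA", ]
  expect_equal(ga$modal_h, "44H")
  expect_equal(ga$n_44H, 10L)
  expect_equal(ga$cognate_match, "F1=TRUE")
  gb <- rep[rep$genome_id == "GB", ]
  expect_equal(gb$modal_h, "38H")
  expect_equal(gb$cognate_match, "F5=TRUE")
  # a genome with receptors but no system: counts only
  gc_row <- rep[rep$genome_id == "GC", ]
  expect_equal(gc_row$f_classes, "")
  expect_equal(gc_row$cognate_match, "")
  expect_equal(gc_row$n_40H, 2L)
})
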