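test_that("contradictory or out-of-range specs are rejected", {
  expect_error(genomeSpec("g", flagellated = FALSE, include_flgFG = TRUE),
               "contradictory")
  expect_error(genomeSpec("g", flagellated = TRUE, pseudogene_rate = 1.2),
               "0, 1")
  expect_error(genomeSpec("g", f_class = "F3"), "f_class")
})

test_that("generated bundles are deterministic under a fixed seed", {
  sp <- genomeSpec("g", f_class = "F5", receptors = c("38H" = 4),
                   include_flgFG = FALSE, seed = 17)
  a <- generateGenome(sp)
  b <- generateGenome(sp)
  expect_identical(a$hits, b$hits)
  expect_identical(a$domains, b$domains)
  expect_identical(as.character(a$seqs$g[[1]]), as.character(b$seqs$g[[1]]))
  expect_identical(a$truth, b$truth)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(a, d1)
  writeCohort(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("flagellated specs plant the conserved cluster with its adjacencies", {
  sp <- genomeSpec("g", flagellated = TRUE, include_flgFG = TRUE,
                   pseudogene_rate = 0, accessory_jitter = 0, seed = 1)
  b <- generateGenome(sp)
  labs <- b$hits$query_symbol
  # presence row recovered downstream has all 24 core genes present
  calls <- disambiguateRodHook(assignLabels(b$hits, b$calls))
  row <- presenceCells(buildPresenceMatrix(calls))["g", ]
  expect_true(all(row[coreGeneSet(loadRegistry())] == "present"))
  expect_equal(countFlagellarGenes(row), 41L)
  # rod/hook loci carry deliberately ambiguous hits
  efg_hits <- b$hits[b$hits$subject_locus %in% names(b$truth$efg), ]
  expect_true(all(table(efg_hits$subject_locus) == 3L))
  expect_true(all(efg_hits$evalue <= 1e-20))
})

test_that("later-class composition drops the FlgFG module", {
  sp <- genomeSpec("g", flagellated = TRUE, include_flgFG = FALSE,
                   pseudogene_rate = 0, accessory_jitter = 0, seed = 2)
  b <- generateGenome(sp)
  calls <- disambiguateRodHook(assignLabels(b$hits, b$calls))
  row <- presenceCells(buildPresenceMatrix(calls))["g", ]
  expect_true(all(row[c("FlgF", "FlgG", "FlgJ", "FlhX", "YvyC", "FlhF",
                        "FlgM")] == "absent"))
  expect_equal(b$truth$n_flagellar_genes, 34L)
  expect_equal(countFlagellarGenes(row), 34L)
  expect_true(callFlagellated(row, "complete")$flagellated)
})

test_that("chemosensory operons follow the class templates", {
  sp5 <- genomeSpec("g", f_class = "F5", receptors = c("38H" = 3), seed = 7)
  b5 <- generateGenome(sp5)
  det <- detectChemoSystems(assignLabels(b5$hits, b5$calls), b5$domains)
  expect_equal(det$systems$order_string, "A:W W M B R Y")
  expect_equal(classifySystems(det$systems)$f_class, "F5")
  sp1 <- genomeSpec("g", f_class = "F1", receptors = c("44H" = 3), seed = 8)
  b1 <- generateGenome(sp1)
  det1 <- detectChemoSystems(assignLabels(b1$hits, b1$calls), b1$domains)
  expect_equal(classifySystems(det1$systems)$f_class, "F1")
})

test_that("MAG truncation drops the stated fraction of annotations", {
  full <- generateGenome(genomeSpec("g", assembly_level = "MAG",
                                    mag_retention = 1, seed = 5))
  cut <- generateGenome(genomeSpec("g", assembly_level = "MAG",
                                   mag_retention = 0.6, seed = 5))
  expect_equal(length(cut$calls),
               length(full$calls) - round(0.4 * length(full$calls)))
  expect_setequal(c(mcols(cut$calls)$locus_tag, cut$truth$dropped_loci),
                  mcols(full$calls)$locus_tag)
})

test_that("planted GC offsets are realized in the cluster span", {
  hot <- generateGenome(genomeSpec("g", cluster_gc_offset = 8,
                                   genome_gc = 64, seed = 9))
  sq <- Biostrings::subseq(hot$seqs$g[[1]], hot$truth$cluster_start,
                           hot$truth$cluster_end)
  expect_gt(gcContent(sq), 70)
  expect_true(hot$truth$hgt_flag)
  cold <- generateGenome(genomeSpec("g", cluster_gc_offset = 0,
                                    genome_gc = 64, seed = 9))
  expect_false(cold$truth$hgt_flag)
})

test_that("generated files parse under the package's own readers", {
  prof <- defaultCohortProfiles()[c(1, 7), ]
  prof$n <- c(3, 2); prof$n_flagellated <- c(1, 2)
  co <- generateCohort(prof, seed = 4, draw = "exact")
  d <- withr::local_tempdir()
  writeCohort(co, d)
  back <- suppressMessages(readCohortDir(d))
  expect_equal(back$meta, co$meta)
  expect_equal(length(back$calls), length(co$calls))
  expect_setequal(mcols(back$calls)$locus_tag, mcols(co$calls)$locus_tag)
  expect_equal(nrow(back$hits), nrow(co$hits))
  expect_equal(back$domains[order(back$domains$protein_locus,
                                  back$domains$env_start), ]$env_end,
               co$domains[order(co$domains$protein_locus,
                                co$domains$env_start), ]$env_end)
})

test_that("cohort draws respect planted per-class fractions", {
  prof <- defaultCohortProfiles()
  prof$n <- rep(10L, nrow(prof))
  prof$n_flagellated <- c(1L, 0L, 0L, 6L, 5L, 4L, 9L, 8L, 5L)
  ex <- generateCohort(prof, seed = 3, draw = "exact",
                       pseudogene_rate = 0, mag_retention = 1)
  re <- ex$truth$realized
  expect_equal(setNames(re$n_flagellated, re$tax_class)[prof$tax_class],
               setNames(prof$n_flagellated, prof$tax_class))
  # binomial draw: realized fraction recorded, basal classes richer than
  # Actinomycetia under the default profiles
  prof2 <- defaultCohortProfiles()
  prof2$n <- c(100L, 5L, 5L, 20L, 20L, 20L, 20L, 20L, 20L)
  bi <- generateCohort(prof2, seed = 6, draw = "binomial",
                       pseudogene_rate = 0, mag_retention = 1)
  rb <- bi$truth$realized
  basal <- rb$flag_frac[rb$tax_class %in% c("Aquicultoria",
                                            "Geothermincolia")]
  expect_gt(mean(basal), rb$flag_frac[rb$tax_class == "Actinomycetia"])
  expect_error(generateCohort(within(prof, n[1] <- 0L)), ">= 1")
})

test_that("planted GGDEF means are ordered by ecology", {
  pars <- defaultGgdefParams()$per_ecology
  expect_lt(pars$mu[pars$ecology == "host_associated"],
            min(pars$mu[pars$ecology %in% c("sea", "terrestrial_water",
                                            "soil")]))
})

test_that("tree pairs honor k and determinism", {
  cs <- c(A = 5, B = 5, C = 5, D = 5)
  zero <- generateTreePair(cs, 0L, seed = 2)
  expect_equal(robinsonFoulds(zero$species_tree, zero$gene_tree)$rf_distance,
               0)
  one <- generateTreePair(cs, 1L, seed = 2)
  expect_equal(nrow(one$moved), 1L)
  two_a <- generateTreePair(cs, 2L, seed = 2)
  two_b <- generateTreePair(cs, 2L, seed = 2)
  expect_identical(ape::write.tree(two_a$gene_tree),
                   ape::write.tree(two_b$gene_tree))
  expect_identical(two_a$moved, two_b$moved)
  expect_error(generateTreePair(cs, 6L, seed = 1), "quarter")
  expect_error(generateTreePair(c(A = 8, B = 8), 2L, seed = 1),
               "infeasible")
})
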