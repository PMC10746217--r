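# Seeded synthetic genome annotation bundles with planted ground truth:
# flagellar clusters in conserved order, chemosensory operons per F class,
# chemoreceptor domain tables, GGDEF censuses, metadata and tree pairs.

# Conserved order of the 41 flagellar genes carried by basal-class genomes;
# flgD-flgE and flgF-flgG adjacencies are built in. Later (non-FlgFG)
# classes lack the 7 genes in .NONFLGFG_LOST.
.CLUSTER_ORDER <- c(
  "FliA", "FlhF", "FlhG", "FlgM", "FliW", "YvyC",
  "FliC", "FliD", "FliS", "FliT", "FlgN",
  "FlgK", "FlgL",
  "FlgD", "FlgE",
  "FliK",
  "FlgB", "FlgC", "FliE", "FliF", "FliG", "FliH", "FliI", "FliJ",
  "FliL", "FliM", "FliN", "FliY",
  "FliO", "FliP", "FliQ", "FliR",
  "FlhB", "FlhA", "FlhX", "FlhE",
  "FlgF", "FlgG",
  "FlgJ",
  "MotA", "MotB")

.NONFLGFG_LOST <- c("FlgF", "FlgG", "FlgJ", "FlhX", "YvyC", "FlhF", "FlgM")

# accessory (non-core) genes that may be absent in individual genomes
.ACCESSORY_DROPPABLE <- c("FliT", "FliS", "FlgN", "FliY", "FliL")

# chemosensory operon templates in genomic order; "CheA:W" marks the kinase
# variant carrying an extra CheW domain
.OPERON_TEMPLATES <- list(
  F1  = c("CheA", "CheW", "MCP", "CheC", "CheD", "CheB", "CheR", "CheY"),
  F5  = c("CheA:W", "CheW", "MCP", "CheB", "CheR", "CheY"),
  F7  = c("CheA", "CheW", "CheX", "MCP", "CheB", "CheR", "CheY"),
  F9  = c("CheA", "CheW", "CheC", "MCP", "CheB", "CheR", "CheY"),
  ACF = c("CheA", "CheW", "CheD", "CheB", "CheR", "MCP"))

#' Specification of one synthetic genome
#'
#' Validates and fills a genome spec for [generateGenome()]. All randomness
#' downstream flows from `seed`.
#'
#' @param genome_id Identifier (used as locus-tag prefix).
#' @param tax_class,ecology,species Metadata fields.
#' @param assembly_level `"complete"`, `"draft"` or `"MAG"`.
#' @param flagellated Plant a flagellar gene cluster?
#' @param include_flgFG Basal-class gene composition (41 genes, with the
#'   distal-rod pair FlgF/FlgG) versus later-class composition (34 genes)?
#'   Contradictory with `flagellated = FALSE`.
#' @param f_class `"F1"`, `"F5"`, `"F7"`, `"F9"`, `"ACF"` or `"none"`.
#' @param receptors Named integer vector of chemoreceptor counts per heptad
#'   class, e.g. `c("44H" = 6, "38H" = 1)`.
#' @param n_ggdef Number of distinct GGDEF-domain proteins to plant.
#' @param pseudogene_rate Fraction of non-core flagellar genes planted as
#'   pseudogenes (core genes are never disrupted, so the planted
#'   flagellated status is unaffected).
#' @param mag_retention Fraction of genes retained under MAG truncation
#'   (applies only when `assembly_level = "MAG"`).
#' @param cluster_gc_offset GC percentage points added to the flagellar
#'   cluster span relative to `genome_gc`.
#' @param genome_gc,genome_size,completeness,contamination Metadata values.
#' @param accessory_jitter Maximum number of droppable accessory genes
#'   removed at random (default 2; gives the observed spread of per-genome
#'   flagellar gene counts).
#' @param seed Integer seed.
#' @return A validated list of class `"GenomeSpec"`.
#' @export
genomeSpec <- function(genome_id, tax_class = "Actinomycetia",
                       ecology = "soil", species = genome_id,
                       assembly_level = "complete",
                       flagellated = TRUE, include_flgFG = TRUE,
                       f_class = "none",
                       receptors = integer(),
                       n_ggdef = 5L, pseudogene_rate = 0,
                       mag_retention = 1, cluster_gc_offset = 0,
                       genome_gc = 65, genome_size = 4e6,
                       completeness = 100, contamination = 0,
                       accessory_jitter = 2L, seed = 1L) {
  if (!flagellated && include_flgFG)
    stop("contradictory spec: flagellated = FALSE with include_flgFG = TRUE")
  if (pseudogene_rate < 0 || pseudogene_rate > 1 ||
      mag_retention < 0 || mag_retention > 1)
    stop("pseudogene_rate and mag_retention must lie in [0, 1]")
  if (!f_class %in% c(names(.OPERON_TEMPLATES), "none"))
    stop("unknown f_class: ", f_class)
  if (!assembly_level %in% .ASSEMBLY_LEVELS)
    stop("unknown assembly_level: ", assembly_level)
  spec <- list(genome_id = genome_id, tax_class = tax_class,
               ecology = ecology, species = species,
               assembly_level = assembly_level, flagellated = flagellated,
               include_flgFG = include_flgFG, f_class = f_class,
               receptors = receptors, n_ggdef = as.integer(n_ggdef),
               pseudogene_rate = pseudogene_rate,
               mag_retention = mag_retention,
               cluster_gc_offset = cluster_gc_offset,
               genome_gc = genome_gc, genome_size = genome_size,
               completeness = completeness, contamination = contamination,
               accessory_jitter = as.integer(accessory_jitter),
               seed = as.integer(seed))
  class(spec) <- "GenomeSpec"
  spec
}

#' Generate one annotated synthetic genome with planted truth
#'
#' Emits an annotation bundle in the same shape the ingest readers produce:
#' gene calls ([GRanges]), 12-column homology hits, domain hits, a contig
#' sequence, a metadata row — plus a ground-truth record of every planted
#' quantity. Flagellated specs carry a single flagellar cluster in the
#' conserved gene order (with the *flgD–flgE* and, when `include_flgFG`,
#' *flgF–flgG* adjacencies) and matching best-hit rows at E-values below
#' 1e-20; FlgE/FlgF/FlgG loci deliberately receive equally good hits to all
#' three paralogs, so only the gene-order cue can recover their identity.
#' Pseudogenes are planted among non-core genes at `pseudogene_rate`; MAG
#' specs drop a uniform fraction `1 - mag_retention` of genes; the cluster
#' span's base composition is offset by `cluster_gc_offset`. Identical
#' seeds give identical bundles.
#'
#' @param spec A [genomeSpec()].
#' @return list with `meta` (1-row data.frame), `calls` ([GRanges]),
#'   `hits`, `domains` (data.frames), `seqs` (named list of
#'   [Biostrings::DNAStringSet]), `truth` (list).
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  withr::with_seed(spec$seed, .generateGenomeImpl(spec))
}

#' @noRd
.generateGenomeImpl <- function(spec) {
  gid <- spec$genome_id
  roster <- list()
  add <- function(label, kind, len, h = NA_character_) {
    roster[[length(roster) + 1L]] <<- list(label = label, kind = kind,
                                           len = len, h = h)
  }
  filler <- function(n) for (i in seq_len(n))
    add(NA_character_, "filler", sample(seq(300L, 900L, 150L), 1L))

  filler(2L)
  cluster_genes <- character()
  if (spec$flagellated) {
    cluster_genes <- .CLUSTER_ORDER
    if (!spec$include_flgFG)
      cluster_genes <- setdiff(cluster_genes, .NONFLGFG_LOST)
    ndrop <- sample(0:spec$accessory_jitter, 1L)
    if (ndrop > 0L) {
      drop <- sample(intersect(.ACCESSORY_DROPPABLE, cluster_genes), ndrop)
      cluster_genes <- setdiff(cluster_genes, drop)
    }
    for (g in cluster_genes)
      add(g, "flagellar", sample(seq(450L, 1500L, 150L), 1L))
  }
  filler(2L)
  cognate <- cognateHMap(loadRegistry())
  rec_left <- spec$receptors[spec$receptors > 0]
  if (spec$f_class != "none") {
    for (comp in .OPERON_TEMPLATES[[spec$f_class]]) {
      if (comp == "MCP") {
        h <- if (cognate[[spec$f_class]] %in% names(rec_left))
          cognate[[spec$f_class]] else if (length(rec_left)) names(rec_left)[1L]
          else "44H"
        if (h %in% names(rec_left)) {
          rec_left[h] <- rec_left[h] - 1L
          rec_left <- rec_left[rec_left > 0]
        }
        add("MCP", "chemo", 1950L, h = h)
      } else {
        add(comp, "chemo", sample(seq(450L, 1800L, 150L), 1L))
      }
    }
  }
  ggdef_pool <- spec$n_ggdef
  iso <- function() {            # >= 6 non-chemosensory genes of isolation
    n_g <- min(ggdef_pool, 3L)
    ggdef_pool <<- ggdef_pool - n_g
    for (i in seq_len(n_g)) add(NA_character_, "ggdef",
                                sample(seq(600L, 1200L, 150L), 1L))
    filler(6L - n_g)
  }
  for (h in rep(names(rec_left), rec_left)) {
    iso()
    add("MCP", "chemo_scattered", 1950L, h = h)
  }
  iso()
  for (i in seq_len(ggdef_pool)) add(NA_character_, "ggdef",
                                     sample(seq(600L, 1200L, 150L), 1L))
  filler(1L)

  df <- data.frame(label = vapply(roster, `[[`, "", "label"),
                   kind = vapply(roster, `[[`, "", "kind"),
                   len = vapply(roster, function(r) r$len, integer(1)),
                   h = vapply(roster, `[[`, "", "h"),
                   stringsAsFactors = FALSE)
  spacer <- 100L
  df$end <- cumsum(df$len + spacer) - spacer
  df$start <- df$end - df$len + 1L
  df$locus_tag <- sprintf("%s_%04d", gid, seq_len(nrow(df)))
  df$status <- "present"
  noncore <- df$kind == "flagellar" &
    !df$label %in% coreGeneSet(loadRegistry())
  if (spec$pseudogene_rate > 0 && any(noncore))
    df$status[noncore][runif(sum(noncore)) < spec$pseudogene_rate] <-
      "pseudogene"

  truth_pseudo <- df$locus_tag[df$status == "pseudogene"]
  cluster_span <- if (spec$flagellated)
    c(min(df$start[df$kind == "flagellar"]),
      max(df$end[df$kind == "flagellar"])) else c(NA_integer_, NA_integer_)

  # MAG truncation: a uniform fraction of gene calls is lost from the
  # assembly (sequence coordinates stay; the annotations disappear)
  dropped <- character()
  if (spec$assembly_level == "MAG" && spec$mag_retention < 1) {
    ndrop <- round((1 - spec$mag_retention) * nrow(df))
    drop_idx <- sample(nrow(df), ndrop)
    dropped <- df$locus_tag[drop_idx]
    df <- df[-drop_idx, , drop = FALSE]
  }

  contig <- "ctg1"
  contig_len <- max(df$end) + spacer
  calls <- GRanges(contig, IRanges(df$start, df$end), strand = "+")
  mcols(calls) <- DataFrame(genome_id = gid, locus_tag = df$locus_tag,
                            status = df$status, label = "unassigned")

  hits <- .plantHits(df, gid)
  domains <- .plantDomains(df, gid)
  seq <- .plantSequence(contig_len, spec$genome_gc / 100,
                        spec$cluster_gc_offset / 100, cluster_span)
  seqs <- setNames(list(setNames(DNAStringSet(seq), contig)), gid)

  meta <- data.frame(genome_id = gid, species = spec$species,
                     tax_class = spec$tax_class, ecology = spec$ecology,
                     assembly_level = spec$assembly_level,
                     completeness = spec$completeness,
                     contamination = spec$contamination,
                     genome_gc = spec$genome_gc,
                     genome_size = spec$genome_size,
                     stringsAsFactors = FALSE)

  efg_rows <- df[df$label %in% .EFG & !is.na(df$label), , drop = FALSE]
  rec_rows <- df[df$kind %in% c("chemo", "chemo_scattered") &
                 df$label == "MCP", , drop = FALSE]
  truth <- list(
    genome_id = gid, flagellated = spec$flagellated,
    include_flgFG = spec$include_flgFG, f_class = spec$f_class,
    efg = setNames(efg_rows$label, efg_rows$locus_tag),
    receptor_h = setNames(rec_rows$h, rec_rows$locus_tag),
    n_ggdef = spec$n_ggdef,
    hgt_flag = abs(spec$cluster_gc_offset) > 5,
    cluster_contig = if (spec$flagellated) contig else NA_character_,
    cluster_start = cluster_span[1L], cluster_end = cluster_span[2L],
    n_flagellar_genes = sum(df$kind == "flagellar"),
    pseudogene_loci = truth_pseudo, dropped_loci = dropped,
    flgD_retained = "FlgD" %in% df$label,
    flgFG_adjacent = all(c("FlgF", "FlgG") %in% df$label))
  list(meta = meta, calls = calls, hits = hits, domains = domains,
       seqs = seqs, truth = truth)
}

#' @noRd
.plantHits <- function(df, gid) {
  rows <- list()
  hit <- function(q, locus, evalue, bits, alen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_id = gid, query_symbol = q, subject_locus = locus,
      percent_identity = round(runif(1, 30, 90), 1),
      alignment_length = alen, mismatches = round(alen * 0.3),
      gap_opens = sample(0:5, 1L), q_start = 1L, q_end = alen,
      s_start = 1L, s_end = alen, evalue = evalue,
      bitscore = bits, query_coverage = round(runif(1, 0.7, 1), 2),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    lab <- df$label[i]
    alen <- max(50L, round(df$len[i] / 3))
    if (is.na(lab)) next
    if (lab %in% .EFG) {
      # the three rod/hook paralogs cross-react: equally good hits to all
      # three, resolvable only by gene order
      for (q in .EFG) hit(q, df$locus_tag[i], 1e-25, 300, alen)
    } else if (df$kind[i] == "flagellar") {
      hit(lab, df$locus_tag[i], 10^-sample(25:60, 1L),
          sample(150:500, 1L), alen)
    } else {                     # chemosensory component or receptor
      q <- sub(":W$", "", lab)   # CheA:W is a CheA hit + CheW domain
      hit(q, df$locus_tag[i], 10^-sample(25:50, 1L),
          sample(150:400, 1L), alen)
    }
  }
  # sub-threshold decoys on two filler loci: must be ignored downstream
  fil <- which(df$kind == "filler")
  for (i in head(fil, 2L))
    hit(sample(c("FliM", "FlgE", "CheA"), 1L), df$locus_tag[i], 1e-4, 40, 80)
  if (length(rows) == 0L) return(.emptyHits())
  do.call(rbind, rows)
}

#' @noRd
.emptyHits <- function() {
  data.frame(genome_id = character(), query_symbol = character(),
             subject_locus = character(), percent_identity = numeric(),
             alignment_length = numeric(), mismatches = numeric(),
             gap_opens = numeric(), q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(), evalue = numeric(),
             bitscore = numeric(), query_coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' @noRd
.plantDomains <- function(df, gid) {
  rows <- list()
  dom <- function(locus, name, s, e, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_id = gid, protein_locus = locus, domain_name = name,
      env_start = s, env_end = e, score = score, stringsAsFactors = FALSE)
  }
  first_ggdef <- TRUE
  for (i in seq_len(nrow(df))) {
    lab <- df$label[i]
    if (!is.na(lab) && lab == "CheA:W")
      dom(df$locus_tag[i], "CheW", 620L, 760L, 85)
    if (!is.na(lab) && lab == "MCP") {
      L <- as.integer(substr(df$h[i], 1L, nchar(df$h[i]) - 1L)) * 7L
      dom(df$locus_tag[i], "MCP-signal", 200L, 200L + L - 1L, 120)
    }
    if (df$kind[i] == "ggdef") {
      dom(df$locus_tag[i], "GGDEF", 10L, 170L, 65)
      if (first_ggdef) {         # a second hit on one protein: counts once
        dom(df$locus_tag[i], "GGDEF", 220L, 380L, 40)
        first_ggdef <- FALSE
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(), protein_locus = character(),
                      domain_name = character(), env_start = integer(),
                      env_end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @noRd
.plantSequence <- function(len, gc, offset, cluster_span) {
  p <- rep(gc, len)
  if (!is.na(cluster_span[1L]))
    p[cluster_span[1L]:cluster_span[2L]] <- gc + offset
  u <- runif(len)
  base <- ifelse(u < p / 2, "G",
          ifelse(u < p, "C",
          ifelse(u < p + (1 - p) / 2, "A", "T")))
  paste(base, collapse = "")
}

# --- cohorts ---------------------------------------------------------------

#' Default cohort profiles emulating the published 538-genome survey
#'
#' One row per actinobacterial class: number of genomes, fraction with a
#' flagellar gene set, rod composition (FlgFG-containing basal classes vs
#' later classes), dominant chemosensory class (F1 in basal, F5 in later
#' classes), assembly level, and an ecology probability mix. The numbers
#' are chosen so a cohort drawn with `draw = "exact"` plants 69 flagellated
#' genomes out of 538 with per-class ratios inside the reported ranges
#' (6% in Actinomycetia, 41–91% across basal classes, none in
#' Coriobacteriia or Rubrobacteria).
#'
#' @return data.frame of per-class profiles.
#' @export
defaultCohortProfiles <- function() {
  p <- function(class, n, nflag, flgFG, f_class, level, sea, tw, soil, host,
                chemo_absent = 0) {
    data.frame(tax_class = class, n = n, n_flagellated = nflag,
               flgFG = flgFG, f_class = f_class, assembly_level = level,
               eco_sea = sea, eco_terrestrial_water = tw, eco_soil = soil,
               eco_host_associated = host,
               eco_other = 1 - sea - tw - soil - host,
               chemo_absent_frac = chemo_absent, stringsAsFactors = FALSE)
  }
  rbind(
    p("Actinomycetia",   433, 26, FALSE, "F5", "complete",
      0.05, 0.06, 0.46, 0.43, chemo_absent = 0.5),
    p("Coriobacteriia",   25,  0, FALSE, "none", "complete", 0, 0, 0, 1),
    p("Rubrobacteria",     6,  0, FALSE, "none", "draft", 0.5, 0.5, 0, 0),
    p("Thermoleophilia",  12,  7, TRUE,  "F1", "complete", 0.3, 0.5, 0.2, 0),
    p("Acidimicrobiia",   20, 10, FALSE, "F5", "draft", 0.6, 0.3, 0.1, 0),
    p("Nitriliruptoria",  17,  7, FALSE, "F5", "draft", 0.7, 0.2, 0.1, 0),
    p("Aquicultoria",     11, 10, TRUE,  "F1", "MAG", 0.2, 0.8, 0, 0),
    p("Geothermincolia",   8,  6, TRUE,  "F1", "MAG", 0.1, 0.9, 0, 0),
    p("Humimicrobiia",     6,  3, TRUE,  "F1", "MAG", 0.1, 0.9, 0, 0))
}

#' Default negative-binomial parameters for planted GGDEF counts
#'
#' Counts are negative-binomial per ecology (heavy right tail, matching the
#' observed 0–80 spread; a Poisson would be far too thin), host-associated
#' genomes lower than free-living ones, with multipliers for flagellated
#' genomes and zoospore formers.
#'
#' @return list with `per_ecology` (data.frame ecology/mu/size),
#'   `flagellated_multiplier`, `zoospore_multiplier`, `max_count`.
#' @export
defaultGgdefParams <- function() {
  list(per_ecology = data.frame(
         ecology = c("sea", "terrestrial_water", "soil", "host_associated",
                     "other"),
         mu = c(12, 12, 14, 4, 10), size = 1.5, stringsAsFactors = FALSE),
       flagellated_multiplier = 2.5, zoospore_multiplier = 5,
       max_count = 80L)
}

#' Generate a cohort of synthetic genomes with planted truth
#'
#' Draws genomes class by class from per-class profiles (see
#' [defaultCohortProfiles()]). `draw = "binomial"` samples each genome's
#' flagellated status independently at the class fraction;
#' `draw = "exact"` plants exactly `n_flagellated` per class (useful when
#' planted totals are the input to an arithmetic check). One flagellated
#' complete/draft genome (by default) is planted as a horizontal-transfer
#' candidate with a cluster GC offset of `hgt_offset` points; all others
#' have offset 0. Receptor counts are cognate-dominated (4–8 cognate
#' receptors, occasionally one of another class). All randomness flows from
#' `seed`; realized per-class fractions are recorded in the truth table.
#'
#' @param profiles Per-class profile data.frame; columns as in
#'   [defaultCohortProfiles()] (a `flag_frac` column may replace
#'   `n_flagellated`).
#' @param seed Integer seed.
#' @param draw `"binomial"` or `"exact"`.
#' @param pseudogene_rate,mag_retention Noise controls passed to every
#'   genome (defaults 0.08 and 0.85; set 0 and 1 for noise-free cohorts).
#' @param n_hgt_offenders Number of planted GC-anomalous clusters
#'   (default 1).
#' @param hgt_offset GC offset (points) for planted offenders; default 8.
#' @param ggdef_params See [defaultGgdefParams()].
#' @return list: `meta`, `calls`, `hits`, `domains`, `seqs` (cohort-wide,
#'   keyed by genome), and `truth` (list with `per_genome` data.frame,
#'   `efg`, `receptors` data.frames, `realized` per-class fractions).
#' @export
generateCohort <- function(profiles = defaultCohortProfiles(), seed = 1L,
                           draw = c("binomial", "exact"),
                           pseudogene_rate = 0.08, mag_retention = 0.85,
                           n_hgt_offenders = 1L, hgt_offset = 8,
                           ggdef_params = defaultGgdefParams()) {
  draw <- match.arg(draw)
  if (any(profiles$n < 1L)) stop("n_per_class must be >= 1")
  withr::with_seed(seed, .generateCohortImpl(
    profiles, draw, pseudogene_rate, mag_retention, n_hgt_offenders,
    hgt_offset, ggdef_params))
}

#' @noRd
.generateCohortImpl <- function(profiles, draw, pseudogene_rate,
                                mag_retention, n_hgt_offenders, hgt_offset,
                                ggdef_params) {
  ecos <- c("sea", "terrestrial_water", "soil", "host_associated", "other")
  specs <- list()
  gnum <- 0L
  for (ci in seq_len(nrow(profiles))) {
    pr <- profiles[ci, ]
    n <- pr$n
    nflag <- if ("n_flagellated" %in% colnames(pr) && !is.na(pr$n_flagellated))
      pr$n_flagellated else round(pr$flag_frac * n)
    frac <- nflag / n
    flag <- if (draw == "exact") {
      v <- rep(FALSE, n); v[sample(n, nflag)] <- TRUE; v
    } else as.logical(rbinom(n, 1L, frac))
    eco_p <- as.numeric(pr[paste0("eco_", c("sea", "terrestrial_water",
                                            "soil", "host_associated",
                                            "other"))])
    eco_p <- pmax(eco_p, 0)
    for (i in seq_len(n)) {
      gnum <- gnum + 1L
      gid <- sprintf("G%04d", gnum)
      eco <- sample(ecos, 1L, prob = eco_p)
      chemo_absent <- flag[i] && runif(1) < pr$chemo_absent_frac
      fcl <- if (flag[i] && !chemo_absent) pr$f_class else "none"
      zoosp <- FALSE
      receptors <- integer()
      if (fcl != "none") {
        cog <- cognateHMap(loadRegistry())[[fcl]]
        receptors <- setNames(sample(4:8, 1L), cog)
        if (runif(1) < 0.3) {
          other <- sample(setdiff(c("36H", "38H", "40H", "44H"), cog), 1L)
          receptors[other] <- 1L
        }
      }
      mu <- ggdef_params$per_ecology$mu[
        ggdef_params$per_ecology$ecology == eco]
      size <- ggdef_params$per_ecology$size[
        ggdef_params$per_ecology$ecology == eco]
      if (flag[i]) mu <- mu * ggdef_params$flagellated_multiplier
      if (zoosp) mu <- mu * ggdef_params$zoospore_multiplier
      ngg <- min(rnbinom(1L, mu = mu, size = size), ggdef_params$max_count)
      level <- pr$assembly_level
      specs[[gnum]] <- genomeSpec(
        genome_id = gid, tax_class = pr$tax_class, ecology = eco,
        assembly_level = level, flagellated = flag[i],
        include_flgFG = flag[i] && pr$flgFG, f_class = fcl,
        receptors = receptors, n_ggdef = ngg,
        pseudogene_rate = if (flag[i]) pseudogene_rate else 0,
        mag_retention = if (level == "MAG") mag_retention else 1,
        cluster_gc_offset = 0,
        genome_gc = round(runif(1, 58, 72), 1),
        genome_size = round(runif(1, 2e6, 9e6)),
        completeness = switch(level, complete = 100,
                              draft = round(runif(1, 90, 99), 1),
                              MAG = round(runif(1, 80, 95), 1)),
        contamination = round(runif(1, 0, 4), 2),
        seed = sample.int(.Machine$integer.max - 1L, 1L))
    }
  }
  # plant GC-anomalous clusters among flagellated complete/draft genomes
  flag_cd <- which(vapply(specs, function(s)
    s$flagellated && s$assembly_level != "MAG", logical(1)))
  offenders <- head(sample(flag_cd), n_hgt_offenders)
  for (i in offenders) specs[[i]]$cluster_gc_offset <- hgt_offset

  bundles <- lapply(specs, generateGenome)
  cohort <- .bindBundles(bundles)
  pg <- cohort$truth$per_genome
  realized <- do.call(rbind, lapply(split(pg, pg$tax_class), function(d)
    data.frame(tax_class = d$tax_class[1L], n = nrow(d),
               n_flagellated = sum(d$flagellated),
               flag_frac = mean(d$flagellated), stringsAsFactors = FALSE)))
  rownames(realized) <- NULL
  cohort$truth$realized <- realized
  cohort
}

#' @noRd
.bindBundles <- function(bundles) {
  meta <- do.call(rbind, lapply(bundles, `[[`, "meta"))
  calls <- suppressWarnings(do.call(c, lapply(bundles, `[[`, "calls")))
  hits <- do.call(rbind, lapply(bundles, `[[`, "hits"))
  domains <- do.call(rbind, lapply(bundles, `[[`, "domains"))
  seqs <- do.call(c, lapply(bundles, `[[`, "seqs"))
  truths <- lapply(bundles, `[[`, "truth")
  pg <- do.call(rbind, lapply(truths, function(t) data.frame(
    genome_id = t$genome_id, flagellated = t$flagellated,
    include_flgFG = t$include_flgFG, f_class = t$f_class,
    n_ggdef = t$n_ggdef, hgt_flag = t$hgt_flag,
    cluster_contig = t$cluster_contig, cluster_start = t$cluster_start,
    cluster_end = t$cluster_end,
    n_flagellar_genes = t$n_flagellar_genes,
    n_receptors = length(t$receptor_h),
    flgD_retained = t$flgD_retained,
    flgFG_adjacent = t$flgFG_adjacent, stringsAsFactors = FALSE)))
  pg$tax_class <- meta$tax_class[match(pg$genome_id, meta$genome_id)]
  efg <- do.call(rbind, lapply(truths, function(t)
    if (length(t$efg)) data.frame(genome_id = t$genome_id,
                                  locus_tag = names(t$efg),
                                  label = unname(t$efg),
                                  stringsAsFactors = FALSE)))
  rec <- do.call(rbind, lapply(truths, function(t)
    if (length(t$receptor_h)) data.frame(genome_id = t$genome_id,
                                         locus_tag = names(t$receptor_h),
                                         h_class = unname(t$receptor_h),
                                         stringsAsFactors = FALSE)))
  list(meta = meta, calls = calls, hits = hits, domains = domains,
       seqs = seqs,
       truth = list(per_genome = pg, efg = efg, receptors = rec))
}

# --- bundle serialization ---------------------------------------------------

#' Write / read a cohort bundle as plain files
#'
#' `writeCohort()` lays a cohort out as `metadata.tsv` plus, per genome,
#' `<id>.gff3`, `<id>.fna`, `<id>_hits.tsv` (12-column, headerless) and
#' `<id>_domains.tsv`; ground truth, when present, goes to
#' `truth_per_genome.tsv` (the pipeline never reads it).
#' `readCohortDir()` re-assembles the same in-memory structure using the
#' package's own format readers, so generated fixtures are guaranteed to
#' parse under the same code paths as real data.
#'
#' @param cohort A cohort bundle (see [generateCohort()]).
#' @param dir Directory (created if needed).
#' @return `writeCohort`: `dir` invisibly; `readCohortDir`: a cohort list
#'   (without `truth`).
#' @rdname cohort-io
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(cohort$meta, file.path(dir, "metadata.tsv"), sep = "\t")
  mc <- mcols(cohort$calls)
  for (gid in cohort$meta$genome_id) {
    sel <- mc$genome_id == gid
    calls <- cohort$calls[sel]
    .writeGff(calls, cohort$seqs[[gid]], file.path(dir, paste0(gid, ".gff3")))
    writeXStringSet(cohort$seqs[[gid]], file.path(dir, paste0(gid, ".fna")))
    h <- cohort$hits[cohort$hits$genome_id == gid,
                     c("query_symbol", "subject_locus", "percent_identity",
                       "alignment_length", "mismatches", "gap_opens",
                       "q_start", "q_end", "s_start", "s_end", "evalue",
                       "bitscore"), drop = FALSE]
    fwrite(h, file.path(dir, paste0(gid, "_hits.tsv")), sep = "\t",
           col.names = FALSE)
    d <- cohort$domains[cohort$domains$genome_id == gid,
                        c("protein_locus", "domain_name", "env_start",
                          "env_end", "score"), drop = FALSE]
    fwrite(d, file.path(dir, paste0(gid, "_domains.tsv")), sep = "\t")
  }
  if (is.data.frame(cohort$truth$per_genome))
    fwrite(cohort$truth$per_genome, file.path(dir, "truth_per_genome.tsv"),
           sep = "\t")
  invisible(dir)
}

#' @noRd
.writeGff <- function(calls, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ctg in names(seqs))
    writeLines(sprintf("##sequence-region %s 1 %d", ctg, width(seqs[ctg])),
               con)
  mc <- mcols(calls)
  type <- ifelse(mc$status == "pseudogene", "pseudogene", "CDS")
  attr9 <- sprintf("ID=%s", mc$locus_tag)
  attr9 <- ifelse(mc$status == "pseudogene", paste0(attr9, ";pseudo=true"),
                  attr9)
  attr9 <- ifelse(mc$status == "partial", paste0(attr9, ";partial=true"),
                  attr9)
  writeLines(sprintf("%s\tflagscan_sim\t%s\t%d\t%d\t.\t%s\t0\t%s",
                     as.character(seqnames(calls)), type, start(calls),
                     end(calls), as.character(strand(calls)), attr9), con)
}

#' @rdname cohort-io
#' @export
readCohortDir <- function(dir) {
  meta <- readGenomeMeta(file.path(dir, "metadata.tsv"))
  calls <- list()
  hits <- list()
  domains <- list()
  seqs <- list()
  for (gid in meta$genome_id) {
    g <- readGff(file.path(dir, paste0(gid, ".gff3")))
    mcols(g)$genome_id <- gid
    mcols(g) <- mcols(g)[, c("genome_id", "locus_tag", "status", "label")]
    calls[[gid]] <- g
    h <- readTabularHits(file.path(dir, paste0(gid, "_hits.tsv")))
    h$genome_id <- if (nrow(h)) gid else character(0)
    hits[[gid]] <- h
    d <- readDomainHits(file.path(dir, paste0(gid, "_domains.tsv")))
    d$genome_id <- if (nrow(d)) gid else character(0)
    domains[[gid]] <- d
    fna <- readDNAStringSet(file.path(dir, paste0(gid, ".fna")))
    names(fna) <- sub("\\s.*$", "", names(fna))
    seqs[[gid]] <- fna
  }
  list(meta = meta,
       calls = suppressWarnings(do.call(c, unname(calls))),
       hits = do.call(rbind, c(unname(hits), make.row.names = FALSE)),
       domains = do.call(rbind, c(unname(domains), make.row.names = FALSE)),
       seqs = seqs)
}

# --- tree pairs -------------------------------------------------------------

#' Generate a species-tree / gene-tree pair with planted transfers
#'
#' Builds a species tree in which each taxonomic class is monophyletic,
#' then produces a gene tree by regrafting `k_transfers` leaves into
#' foreign-class clades (each moved leaf is attached above the common
#' ancestor of two leaves of the target class, so only the moved leaf's
#' sister-clade majority changes). Source and target classes are all
#' distinct, so planted events never overlap.
#'
#' @param class_sizes Named integer vector: leaves per class (each >= 2;
#'   at least `2 * k_transfers` classes).
#' @param k_transfers Number of planted inter-class transfers
#'   (`<= n_leaves / 4`).
#' @param seed Integer seed.
#' @return list: `species_tree`, `gene_tree` (`phylo`), `classes` (named
#'   vector leaf -> class), `moved` (data.frame: leaf, from_class,
#'   to_class).
#' @export
generateTreePair <- function(class_sizes, k_transfers = 0L, seed = 1L) {
  stopifnot(all(class_sizes >= 2L))
  n_leaves <- sum(class_sizes)
  if (k_transfers > n_leaves / 4)
    stop("k_transfers must be at most a quarter of the leaf count")
  if (k_transfers > 0L && length(class_sizes) < 2L * k_transfers)
    stop("infeasible regraft: need at least 2 * k_transfers classes")
  withr::with_seed(seed, {
    classes <- character()
    backbone <- if (length(class_sizes) == 1L) NULL else
      ape::rtree(length(class_sizes), tip.label = names(class_sizes))
    sub <- lapply(names(class_sizes), function(cl) {
      labs <- sprintf("%s_%02d", cl, seq_len(class_sizes[[cl]]))
      classes[labs] <<- cl
      ape::rtree(class_sizes[[cl]], tip.label = labs)
    })
    names(sub) <- names(class_sizes)
    stree <- backbone
    for (cl in names(class_sizes)) {
      at <- which(stree$tip.label == cl)
      stree <- ape::bind.tree(stree, sub[[cl]], where = at)
    }
    gtree <- stree
    moved <- data.frame(leaf = character(), from_class = character(),
                        to_class = character(), stringsAsFactors = FALSE)
    if (k_transfers > 0L) {
      picked <- sample(names(class_sizes), 2L * k_transfers)
      for (j in seq_len(k_transfers)) {
        from <- picked[2L * j - 1L]
        to <- picked[2L * j]
        leaf <- sample(names(classes)[classes == from], 1L)
        targets <- sample(names(classes)[classes == to], 2L)
        gtree <- ape::drop.tip(gtree, leaf)
        node <- ape::getMRCA(gtree, targets)
        # an explicit tip edge length keeps bind.tip from discarding the
        # tree's branch lengths
        gtree <- phytools::bind.tip(gtree, leaf,
                                    edge.length = mean(gtree$edge.length),
                                    where = node,
                                    position = 0.5 * .parentEdgeLength(gtree,
                                                                       node))
        moved <- rbind(moved, data.frame(leaf = leaf, from_class = from,
                                         to_class = to,
                                         stringsAsFactors = FALSE))
      }
    }
    list(species_tree = stree, gene_tree = gtree, classes = classes,
         moved = moved)
  })
}

#' @noRd
.parentEdgeLength <- function(tree, node) {
  e <- which(tree$edge[, 2L] == node)
  if (length(e) == 0L || is.null(tree$edge.length)) return(0)
  tree$edge.length[e]
}
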