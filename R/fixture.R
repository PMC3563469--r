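# The worked-example family: a deterministic bundle encoding the published
# genotypes, prediction scores and trio read depths, padded with Mendelian
# filler and QC decoys so every pipeline stage has work to do at desk scale.

fixture_samples <- c("mother", "father", "child1", "child2", "child3",
                     "child4")

fixture_ad_for_gt <- function(gt) {
  switch(gt, "0/0" = c(150L, 0L), "0/1" = c(75L, 75L), "1/1" = c(2L, 148L),
         c(NA_integer_, NA_integer_))
}

fixture_gt <- function(...) {
  gts <- c(...)
  stats::setNames(gts, fixture_samples)
}

#' The worked-example nuclear-family fixture
#'
#' A deterministic `family_bundle` (no random draws) encoding the published
#' worked example end to end: the affected mother / two affected children
#' pedigree; the ten segregating novel nonsynonymous variants with their
#' printed chromosome, position and five prediction scores (heterozygous in
#' all affecteds, homozygous reference in all unaffecteds); four additional
#' segregating variants carrying a 1000 Genomes frequency, so the cascade
#' yields 14 segregating variants and 10 after the exclusion stage; the four
#' common asthma-associated SNPs with their published genotypes (none
#' segregates); the two de novo variants with the printed per-member allelic
#' depths (mean coverage 212x); candidate-gene variants realizing the
#' published per-child novel (8/8/3/5) and novel-nonsynonymous (6/6/1/4)
#' burden numerators; Mendelian filler variants; and one QC decoy per hard
#' filter. Values the publication does not print (reference/alternate bases
#' of some sites, filler positions) are arbitrary but fixed.
#'
#' Per-child totals at the scale of the full exome (tens of thousands of
#' QC-passed variants per child) are not emulated; the published 2x2 burden
#' tables are reproduced by supplying the printed per-child totals directly
#' to [build_table()].
#'
#' @return A `family_bundle` list: `pedigree`, `variants`, `annotation`,
#'   `genes`, `truth`.
#' @export
paper_family_fixture <- function() {
  ped <- new_pedigree(tibble::tibble(
    family_id = "FAM1",
    sample_id = fixture_samples,
    father_id = c(NA, NA, "father", "father", "father", "father"),
    mother_id = c(NA, NA, "mother", "mother", "mother", "mother"),
    sex = c("female", "male", "male", "female", "male", "female"),
    affection = c("affected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected")
  ))

  seg_gt <- fixture_gt("0/1", "0/0", "0/1", "0/1", "0/0", "0/0")
  rows <- list()
  ann <- list()
  truth <- list()
  add <- function(chrom, pos, ref, alt, gt, class, region = "exonic",
                  exonic_function = "nonsynonymous",
                  gene, aa_change = NA_character_, dbsnp = NA_character_,
                  kg_af = NA_real_, sift = NA_real_, polyphen2 = NA_real_,
                  phylop = NA_real_, mutation_taster = NA_real_,
                  lrt = NA_real_, ad = NULL, metrics = list(
                    qual = 900, dp = 300, qd = 3, fs = 1.2, mq0 = 0),
                  carrier = NA_character_) {
    if (is.null(ad)) ad <- lapply(gt, fixture_ad_for_gt)
    rows[[length(rows) + 1L]] <<- make_variant(
      chrom, pos, ref, alt, gt, ad = ad, qual = metrics$qual,
      dp = metrics$dp, qd = metrics$qd, fs = metrics$fs, mq0 = metrics$mq0)
    ann[[length(ann) + 1L]] <<- tibble::tibble(
      chrom = as.character(chrom), pos = as.integer(pos), ref = ref,
      alt = alt, region = region, exonic_function = exonic_function,
      gene = gene, aa_change = aa_change, dbsnp = dbsnp, kg_af = kg_af,
      sift = sift, polyphen2 = polyphen2, phylop = phylop,
      mutation_taster = mutation_taster, lrt = lrt)
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      variant_id = variant_key(chrom, pos, ref, alt), class = class,
      carrier = carrier)
    invisible(NULL)
  }

  # -- the ten segregating novel nonsynonymous variants with printed scores --
  ten <- tibble::tribble(
    ~gene,      ~aa,     ~chrom, ~pos,       ~ref, ~alt, ~sift, ~pp2, ~phy,    ~mt,   ~lrt,
    "PDE4DIP",  "I303L", "1",    144930802L, "A",  "C",  0.47,  0.45, 0.75,    1.00,  0.95,
    "FCRL6",    "R123Q", "1",    159778799L, "G",  "A",  0.14,  0.28, 0.02,    0.01,  0.00,
    "AIM2",     "N194D", "1",    159035936L, "A",  "G",  0.00,  0.99, 0.16,    0.08,  0.69,
    "ZBTB37",   "M396V", "1",    173854936L, "A",  "G",  0.00,  NA,   NA,      NA,    NA,
    "IER5",     "E103K", "1",    181058345L, "G",  "A",  0.07,  0.07, 0.94,    0.02,  0.91,
    "CBLB",     "D454A", "3",    105438937L, "T",  "G",  0.37,  0.78, 0.99,    0.99,  0.99,
    "CCDC80",   "S95L",  "3",    112358469L, "C",  "T",  0.13,  0.03, 6.2e-4,  0.04,  6.0e-6,
    "KALRN",    "L1644F","3",    124281690L, "C",  "T",  0.00,  0.83, 0.99,    0.72,  0.99,
    "GALNTL6",  "I160V", "4",    173269765L, "A",  "G",  1.00,  0.00, 0.99,    0.00,  0.84,
    "COMMD5",   "R38Q",  "8",    146076611L, "G",  "A",  0.47,  0.03, 0.10,    0.06,  0.94
  )
  for (i in seq_len(nrow(ten))) {
    r <- ten[i, ]
    add(r$chrom, r$pos, r$ref, r$alt, seg_gt, "segregating", gene = r$gene,
        aa_change = r$aa, sift = r$sift, polyphen2 = r$pp2, phylop = r$phy,
        mutation_taster = r$mt, lrt = r$lrt)
  }

  # -- four segregating variants removed at the 1000 Genomes stage -----------
  kg4 <- tibble::tribble(
    ~gene,      ~chrom, ~pos,       ~kg_af,
    "TTLL5",    "14",   76201433L,  0.002,
    "ZZEF1",    "17",   4004521L,   0.004,
    "PKHD1L1",  "8",    110374996L, 0.005,
    "ABCA7",    "19",   1042837L,   0.008
  )
  for (i in seq_len(nrow(kg4))) {
    r <- kg4[i, ]
    add(r$chrom, r$pos, "C", "T", seg_gt, "kg_flagged", gene = r$gene,
        aa_change = "A100T", kg_af = r$kg_af,
        sift = 0.10, polyphen2 = 0.20, phylop = 0.30, mutation_taster = 0.10,
        lrt = 0.20)
  }

  # -- the four common asthma-associated SNPs (published genotypes) ----------
  add("17", 38069949L, "C", "T",
      fixture_gt("1/1", "0/1", "0/1", "0/1", "0/1", "0/1"),
      "background", region = "intronic", exonic_function = NA_character_,
      gene = "ORMDL3", dbsnp = "rs7216389", kg_af = 0.45)
  add("5", 131892979L, "G", "T",
      fixture_gt("0/1", "0/1", "1/1", "1/1", "1/1", "0/0"),
      "background", region = "intronic", exonic_function = NA_character_,
      gene = "RAD50", dbsnp = "rs2706347", kg_af = 0.38)
  add("2", 178672016L, "A", "C",
      fixture_gt("0/0", "0/1", "0/1", "0/1", "0/1", "0/0"),
      "background", region = "intronic", exonic_function = NA_character_,
      gene = "PDE11A", dbsnp = "rs11684634", kg_af = 0.30)
  add("5", 58400047L, "C", "T",
      fixture_gt("0/0", "0/1", "0/1", "0/0", "0/1", "0/1"),
      "background", region = "intronic", exonic_function = NA_character_,
      gene = "PDE4D", dbsnp = "rs1544791", kg_af = 0.41)

  # -- the two de novo variants with printed per-member allelic depths -------
  add("15", 100252908L, "C", "T",
      fixture_gt("0/0", "0/0", "0/1", "0/0", "0/0", "0/0"),
      "denovo", gene = "MEF2A", aa_change = "P279L", carrier = "child1",
      sift = 0.20, polyphen2 = 0.30, phylop = 0.40, mutation_taster = 0.10,
      lrt = 0.10,
      ad = list(mother = c(155L, 0L), father = c(187L, 0L),
                child1 = c(73L, 65L), child2 = c(223L, 0L),
                child3 = c(76L, 0L), child4 = c(196L, 3L)))
  add("6", 56485113L, "G", "A",
      fixture_gt("0/0", "0/0", "0/0", "0/0", "0/0", "0/1"),
      "denovo", gene = "DST", aa_change = "T1458I", carrier = "child4",
      sift = 0.30, polyphen2 = 0.10, phylop = 0.20, mutation_taster = 0.20,
      lrt = 0.30,
      ad = list(mother = c(221L, 0L), father = c(333L, 1L),
                child1 = c(248L, 0L), child2 = c(326L, 0L),
                child3 = c(145L, 0L), child4 = c(168L, 122L)))

  # -- candidate-gene burden variants: per-child novel numerators ------------
  candidate_genes <- c(
    "ORMDL3", "PDE4D", "RAD50", "PDE11A", "IL13", "IL4", "IL4R", "ADAM33",
    "DPP10", "HLA-DRB1", "HLA-DQB1", "IL1RL1", "IL18R1", "IL33", "SMAD3",
    "TLE4", "DENND1B", "RORA", "SLC22A5", "TNF", "CHI3L1", "FLG", "MUC7",
    "NPSR1"
  )
  burden_plan <- data.frame(
    child = c(rep("child1", 6), rep("child2", 6), "child3",
              rep("child4", 4), rep("child1", 2), rep("child2", 2),
              rep("child3", 2), "child4"),
    fn = c(rep("nonsynonymous", 17), rep("synonymous", 7))
  )
  burden_genes <- rep(candidate_genes[5:16], length.out = nrow(burden_plan))
  for (i in seq_len(nrow(burden_plan))) {
    carrier <- burden_plan$child[i]
    gt <- fixture_gt("0/0", "0/1", "0/0", "0/0", "0/0", "0/0")
    gt[carrier] <- "0/1"
    add("2", 102650000L + 1000L * i, "G", "A", gt, "background",
        gene = burden_genes[i], exonic_function = burden_plan$fn[i],
        aa_change = if (burden_plan$fn[i] == "nonsynonymous") "K10R"
                    else NA_character_,
        sift = 0.05, polyphen2 = 0.05, phylop = 0.05, mutation_taster = 0.05,
        lrt = 0.05)
  }

  # -- Mendelian filler across region classes --------------------------------
  filler <- tibble::tribble(
    ~chrom, ~pos,       ~gene,    ~region,     ~fn,           ~dbsnp,
    "1",    10177210L,  "ACTB",   "exonic",    "synonymous",  "rs5000001",
    "2",    20017888L,  "GAPDH",  "UTR3",      NA,            "rs5000002",
    "7",    100450765L, "TP53",   "intronic",  NA,            "rs5000003",
    "9",    35056065L,  "EGFR",   "UTR5",      NA,            "rs5000004",
    "10",   89623860L,  "PTEN",   "exonic",    "nonsynonymous","rs5000005",
    "12",   25398284L,  "KRAS",   "ncRNA_exonic", NA,         "rs5000006",
    "16",   68857441L,  "CDH1",   "exonic",    "synonymous",  "rs5000007",
    "21",   36421924L,  "RUNX1",  "UTR3",      NA,            "rs5000008"
  )
  filler_gts <- list(
    fixture_gt("0/1", "0/1", "0/1", "0/0", "1/1", "0/1"),
    fixture_gt("0/1", "0/0", "0/1", "0/1", "0/0", "0/0"),
    fixture_gt("1/1", "0/1", "0/1", "1/1", "0/1", "1/1"),
    fixture_gt("0/0", "0/1", "0/1", "0/0", "0/1", "0/0"),
    fixture_gt("0/1", "0/1", "1/1", "0/1", "0/0", "0/1"),
    fixture_gt("0/1", "0/0", "0/0", "0/1", "0/1", "0/0"),
    fixture_gt("1/1", "1/1", "1/1", "1/1", "1/1", "1/1"),
    fixture_gt("0/0", "0/1", "0/1", "0/1", "0/0", "0/1")
  )
  for (i in seq_len(nrow(filler))) {
    r <- filler[i, ]
    add(r$chrom, r$pos, "A", "G", filler_gts[[i]], "background",
        region = r$region, exonic_function = r$fn, gene = r$gene,
        dbsnp = r$dbsnp, kg_af = 0.2,
        sift = 0.5, polyphen2 = 0.5, phylop = 0.5, mutation_taster = 0.5,
        lrt = 0.5)
  }

  # -- one QC decoy per hard filter ------------------------------------------
  decoy_gt <- fixture_gt("0/0", "0/1", "0/1", "0/0", "0/0", "0/0")
  qc_metric_sets <- list(
    map_ambiguity = list(qual = 500, dp = 100, qd = 5, fs = 5, mq0 = 6),
    min_depth = list(qual = 60, dp = 3, qd = 20, fs = 5, mq0 = 0),
    min_qual = list(qual = 40, dp = 20, qd = 2, fs = 5, mq0 = 0),
    min_qd = list(qual = 100, dp = 100, qd = 1.0, fs = 5, mq0 = 0),
    strand_bias = list(qual = 500, dp = 100, qd = 5, fs = 250, mq0 = 0)
  )
  decoy_pos <- 400000L
  for (f in names(qc_metric_sets)) {
    decoy_pos <- decoy_pos + 50000L
    add("20", decoy_pos, "C", "A", decoy_gt, paste0("qc_decoy:", f),
        gene = "DECOY1", aa_change = "D1E", metrics = qc_metric_sets[[f]],
        sift = 0.5, polyphen2 = 0.5, phylop = 0.5, mutation_taster = 0.5,
        lrt = 0.5)
  }
  for (off in c(0L, 4L, 8L)) {
    add("20", 900010L + off, "C", "A", decoy_gt, "qc_decoy:cluster3in10",
        gene = "DECOY2", aa_change = "D2E",
        sift = 0.5, polyphen2 = 0.5, phylop = 0.5, mutation_taster = 0.5,
        lrt = 0.5)
  }

  variants <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  annotation <- dplyr::bind_rows(ann)
  annotation$variant_id <- variant_key(annotation$chrom, annotation$pos,
                                       annotation$ref, annotation$alt)
  annotation <- dplyr::relocate(
    dplyr::arrange(annotation, .data$chrom, .data$pos), "variant_id")

  structure(
    list(pedigree = ped, variants = variants, annotation = annotation,
         genes = candidate_genes, truth = dplyr::bind_rows(truth),
         config = NULL),
    class = "family_bundle"
  )
}

#' Published per-child burden counts for the worked example
#'
#' The per-child candidate-gene allele counts (all / novel / novel and
#' nonsynonymous tiers) and per-child QC-passed variant totals as printed,
#' in the shape [build_table()] and [burden_test()] consume. These are the
#' inputs of the published 2x2 arithmetic: affected numerators 16 novel / 12
#' novel nonsynonymous against remainders 56,767, unaffected 8 / 5 against
#' 55,742.
#'
#' @return A `burden_counts` tibble with one row per child.
#' @export
published_burden_counts <- function() {
  out <- tibble::tibble(
    sample_id = c("child1", "child2", "child3", "child4"),
    n_all = c(415L, 427L, 396L, 422L),
    n_novel = c(8L, 8L, 3L, 5L),
    n_novel_nonsyn = c(6L, 6L, 1L, 4L),
    n_total_qc = c(28370L, 28413L, 27376L, 28374L)
  )
  class(out) <- c("burden_counts", class(tibble::tibble()))
  out
}
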