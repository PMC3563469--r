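trio_variant <- function(child_gt, mother_gt = "0/0", father_gt = "0/0",
                         ad = NULL, pos = 1000) {
  site("1", pos, gt6(mother_gt, father_gt, child_gt, "0/0", "0/0", "0/0"),
       ad = ad)
}

test_that("a child allele absent from both called parents is a candidate", {
  ped <- family_ped()
  cand <- denovo_candidates(trio_variant("0/1"), ped, quiet = TRUE)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$child_id, "child1")
  expect_equal(cand$child_gt, "het")

  # allele present in a parent: no candidate
  expect_equal(nrow(denovo_candidates(trio_variant("0/1",
                                                   mother_gt = "0/1"),
                                      ped, quiet = TRUE)), 0L)
  # all hom-ref: no candidate
  expect_equal(nrow(denovo_candidates(trio_variant("0/0"), ped,
                                      quiet = TRUE)), 0L)
  # founders never appear as carriers
  v <- site("1", 5, gt6("0/1", "0/1", "0/0", "0/0", "0/0", "0/0"))
  expect_equal(nrow(denovo_candidates(v, ped, quiet = TRUE)), 0L)
})

test_that("sites with an uncalled parent are skipped with a message", {
  ped <- family_ped()
  v <- trio_variant("0/1", father_gt = "./.")
  expect_message(out <- denovo_candidates(v, ped), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("the published trio read profiles pass all three criteria", {
  ped <- family_ped()
  mef2a <- site("15", 100252908,
                gt6("0/0", "0/0", "0/1", "0/0", "0/0", "0/0"),
                ad = list(mother = c(155, 0), father = c(187, 0),
                          child1 = c(73, 65), child2 = c(223, 0),
                          child3 = c(76, 0), child4 = c(196, 3)))
  dst <- site("6", 56485113,
              gt6("0/0", "0/0", "0/0", "0/0", "0/0", "0/1"),
              ad = list(mother = c(221, 0), father = c(333, 1),
                        child1 = c(248, 0), child2 = c(326, 0),
                        child3 = c(145, 0), child4 = c(168, 122)))
  cand <- denovo_qc(denovo_candidates(dplyr::bind_rows(mef2a, dst), ped,
                                      quiet = TRUE))
  expect_equal(nrow(cand), 2L)
  expect_true(all(cand$trio_depth))
  expect_true(all(cand$parent_alt_fraction))
  expect_true(all(cand$child_ref_fraction))
  expect_true(all(cand$qc_pass))
  expect_setequal(cand$child_id, c("child1", "child4"))
})

test_that("each criterion fails on its own boundary", {
  ped <- family_ped()
  qc1 <- function(ad) {
    denovo_qc(denovo_candidates(trio_variant("0/1", ad = ad), ped,
                                quiet = TRUE))
  }
  deep <- list(mother = c(100, 0), father = c(100, 0), child1 = c(50, 50))

  shallow <- deep; shallow$child1 <- c(5, 5)
  out <- qc1(shallow)
  expect_false(out$trio_depth)
  expect_true(out$parent_alt_fraction & out$child_ref_fraction)

  # exactly 10 reads is not "more than 10"
  eleven <- deep; eleven$mother <- c(10, 0)
  expect_false(qc1(eleven)$trio_depth)
  eleven$mother <- c(11, 0)
  expect_true(qc1(eleven)$trio_depth)

  contaminated <- deep; contaminated$father <- c(90, 10)
  out <- qc1(contaminated)
  expect_false(out$parent_alt_fraction)
  expect_true(out$trio_depth & out$child_ref_fraction)
  # 5% exactly is allowed
  at_bound <- deep; at_bound$father <- c(95, 5)
  expect_true(qc1(at_bound)$parent_alt_fraction)

  biased <- deep; biased$child1 <- c(80, 20)
  out <- qc1(biased)
  expect_false(out$child_ref_fraction)
  expect_true(out$trio_depth & out$parent_alt_fraction)
  # 70% exactly is allowed
  at70 <- deep; at70$child1 <- c(70, 30)
  expect_true(qc1(at70)$child_ref_fraction)

  # absent depths fail the depth criterion rather than erroring
  expect_false(qc1(NULL)$trio_depth)
})

test_that("a homozygous-alternate child passes criterion 3 vacuously, flagged", {
  ped <- family_ped()
  v <- trio_variant("1/1", ad = list(mother = c(100, 0), father = c(100, 0),
                                     child1 = c(2, 98)))
  out <- denovo_qc(denovo_candidates(v, ped, quiet = TRUE))
  expect_true(out$child_ref_fraction)
  expect_true(out$atypical_hom_alt)
  expect_true(out$qc_pass)
})

test_that("criteria are monotone in child depth at fixed fractions", {
  ped <- family_ped()
  for (total in c(12, 40, 200, 1000)) {
    ad <- list(mother = c(100, 0), father = c(100, 0),
               child1 = c(round(0.5 * total), total - round(0.5 * total)))
    out <- denovo_qc(denovo_candidates(trio_variant("0/1", ad = ad), ped,
                                       quiet = TRUE))
    expect_true(out$qc_pass, label = paste("total", total))
  }
})

test_that("finalize keeps dbSNP-novel passes and reports mean coverage", {
  fx <- paper_family_fixture()
  annotated <- join_annotation(qc_passed(qc_filter(fx$variants)),
                               fx$annotation, quiet = TRUE)
  cand <- denovo_qc(denovo_candidates(annotated, fx$pedigree, quiet = TRUE))
  fin <- denovo_finalize(cand, annotated, fx$pedigree)
  expect_setequal(fin$final$gene, c("MEF2A", "DST"))
  expect_equal(fin$mean_coverage, 212)

  # a known-dbSNP candidate is dropped even when depth QC passes
  known <- dplyr::mutate(annotated,
                         dbsnp = dplyr::coalesce(dbsnp, "rs1"))
  fin2 <- denovo_finalize(cand, known, fx$pedigree)
  expect_equal(nrow(fin2$final), 0L)
  expect_true(is.na(fin2$mean_coverage))
})

test_that("simulated de novo decoys fail exactly their intended rule", {
  sim <- simulate_family(sim_config(seed = 21))
  res <- run_bundle(sim)
  cand <- res$denovo_candidates
  truth <- sim$truth

  planted <- truth$variant_id[truth$class == "denovo"]
  expect_true(all(cand$qc_pass[cand$variant_id %in% planted]))

  check <- list(
    `denovo_decoy:shallow_trio` = "trio_depth",
    `denovo_decoy:parent_contamination` = "parent_alt_fraction",
    `denovo_decoy:child_allele_bias` = "child_ref_fraction"
  )
  for (cls in names(check)) {
    ids <- truth$variant_id[truth$class == cls]
    rows <- cand[cand$variant_id %in% ids, ]
    expect_equal(nrow(rows), length(ids), label = cls)
    crit <- check[[cls]]
    expect_true(all(!rows[[crit]]), label = cls)
    others <- setdiff(c("trio_depth", "parent_alt_fraction",
                        "child_ref_fraction"), crit)
    for (o in others) expect_true(all(rows[[o]]), label = paste(cls, o))
  }
  dbsnp_ids <- truth$variant_id[truth$class == "denovo_decoy:known_dbsnp"]
  rows <- cand[cand$variant_id %in% dbsnp_ids, ]
  expect_true(all(rows$qc_pass))
  expect_false(any(dbsnp_ids %in% res$denovo$final$variant_id))
})
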