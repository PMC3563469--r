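# Published genotype patterns: CBLB segregates (affecteds het, unaffecteds
# hom-ref); the common ORMDL3 risk allele does not (hom-alt mother, het
# father).
cblb_site <- function() {
  site("3", 105438937, gt6("0/1", "0/0", "0/1", "0/1", "0/0", "0/0"),
       ref = "T", alt = "G")
}
ormdl3_site <- function() {
  site("17", 38069949, gt6("1/1", "0/1", "0/1", "0/1", "0/1", "0/1"),
       ref = "C", alt = "T")
}

test_that("nonref_counts scores het 1, hom-alt 2, hom-ref 0", {
  ped <- family_ped()
  counts <- nonref_counts(cblb_site(), ped)
  expect_equal(tibble::deframe(counts[, c("sample_id", "count")]),
               c(mother = 1L, father = 0L, child1 = 1L, child2 = 1L,
                 child3 = 0L, child4 = 0L))
  counts2 <- nonref_counts(ormdl3_site(), ped)
  expect_equal(counts2$count[counts2$sample_id == "mother"], 2L)
  all_ref <- site("1", 1, gt6("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"))
  expect_true(all(nonref_counts(all_ref, ped)$count == 0L))
})

test_that("segregation requires every affected above every unaffected", {
  ped <- family_ped()
  seg <- segregates(nonref_counts(cblb_site(), ped), ped)
  expect_true(seg$passes)
  expect_equal(seg$margin, 1L)

  # hom-alt mother, het everyone else: margin 0, fails
  seg2 <- segregates(nonref_counts(ormdl3_site(), ped), ped)
  expect_false(seg2$passes)
  expect_equal(seg2$margin, 0L)

  all_ref <- site("1", 1, gt6("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"))
  expect_false(segregates(nonref_counts(all_ref, ped), ped)$passes)

  no_controls <- family_ped()
  no_controls$affection <- "affected"
  expect_error(segregates(nonref_counts(cblb_site(), no_controls),
                          no_controls), "at least one")
})

test_that("an uncalled genotype in a phenotyped member disqualifies the site", {
  ped <- family_ped()
  v <- site("1", 50, gt6("0/1", "./.", "0/1", "0/1", "0/0", "0/0"))
  seg <- segregates(nonref_counts(v, ped), ped)
  expect_false(seg$complete)
  expect_false(seg$passes)
})

test_that("segregation is invariant to permutations within a phenotype class", {
  ped <- family_ped()
  base <- gt6("0/1", "0/0", "0/1", "0/1", "0/0", "0/0")
  swapped_affected <- base[c("child1", "father", "mother", "child2",
                             "child3", "child4")]
  names(swapped_affected) <- samples6
  v1 <- site("1", 10, base)
  v2 <- site("1", 10, swapped_affected)
  expect_equal(segregates(nonref_counts(v1, ped), ped)$passes,
               segregates(nonref_counts(v2, ped), ped)$passes)

  # flipping any affected member to hom-ref always breaks segregation
  for (aff in c("mother", "child1", "child2")) {
    gt <- base
    gt[aff] <- "0/0"
    v <- site("1", 10, gt)
    expect_false(segregates(nonref_counts(v, ped), ped)$passes)
  }
})

test_that("novelty flags distinguish dbSNP and 1000 Genomes status", {
  df <- tibble::tibble(dbsnp = c(NA, NA, "rs7216389"),
                       kg_af = c(NA, 0.004, 0.45))
  out <- flag_novelty(df)
  expect_equal(out$dbsnp_novel, c(TRUE, TRUE, FALSE))
  expect_equal(out$kg_excluded, c(FALSE, TRUE, TRUE))
})

test_that("the cascade filters in order and its stages commute", {
  fx <- paper_family_fixture()
  annotated <- join_annotation(qc_passed(qc_filter(fx$variants)),
                               fx$annotation, quiet = TRUE)
  cas <- run_cascade(annotated, fx$pedigree)
  expect_equal(cas$n_segregating, 14L)
  expect_equal(cas$n_after_kg_exclusion, 10L)
  expect_true(cas$n_input >= cas$n_novel_nonsyn)
  expect_true(cas$n_novel_nonsyn >= cas$n_segregating)

  # segregation first, novelty/nonsyn second: same survivor set
  seg_all <- segregates(nonref_counts(annotated, fx$pedigree), fx$pedigree)
  seg_first <- annotated |>
    dplyr::semi_join(dplyr::filter(seg_all, passes), by = "variant_id") |>
    flag_novelty() |>
    dplyr::filter(region %in% c("exonic", "exonic_splicing"),
                  exonic_function == "nonsynonymous", dbsnp_novel,
                  !kg_excluded)
  expect_setequal(seg_first$variant_id, cas$survivors$variant_id)

  # with no nonsynonymous variants every downstream count is zero
  syn_only <- dplyr::mutate(annotated, exonic_function = "synonymous")
  cas0 <- run_cascade(syn_only, fx$pedigree)
  expect_equal(cas0$n_novel_nonsyn, 0L)
  expect_equal(cas0$n_after_kg_exclusion, 0L)
})

test_that("tidy and glance expose cascade stage counts", {
  fx <- paper_family_fixture()
  annotated <- join_annotation(qc_passed(qc_filter(fx$variants)),
                               fx$annotation, quiet = TRUE)
  cas <- run_cascade(annotated, fx$pedigree)
  td <- tidy(cas)
  expect_equal(td$n[td$stage == "segregating"], 14L)
  expect_equal(glance(cas)$n_after_kg_exclusion, 10L)
  expect_s3_class(autoplot(cas), "ggplot")
})
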