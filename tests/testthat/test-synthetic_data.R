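small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_background_common = 40, n_background_rare = 15,
             ...)
}

test_that("identical seeds give identical bundles, different seeds differ", {
  a <- simulate_family(small_cfg(4))
  b <- simulate_family(small_cfg(4))
  expect_identical(as.data.frame(a$variants), as.data.frame(b$variants))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)

  c <- simulate_family(small_cfg(5))
  expect_false(identical(a$variants, c$variants))

  # byte-identical files on disk from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_family_bundle(simulate_family(small_cfg(4)), d1)
  p2 <- write_family_bundle(simulate_family(small_cfg(4)), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = f)
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(n_planted_kg_flagged = 5,
                          n_planted_segregating = 3), "exceed")
  expect_error(sim_config(mother_affected = FALSE), "affected parent")
  expect_error(sim_config(affected_children = "child9"), "child9")
})

test_that("background transmission is Mendelian except planted de novo", {
  sim <- simulate_family(small_cfg(13))
  g <- geno_long(sim$variants)
  kids <- paste0("child", 1:4)
  mendel_ok <- g |>
    dplyr::select(variant_id, sample_id, a1, a2) |>
    tidyr::pivot_wider(names_from = sample_id,
                       values_from = c(a1, a2)) |>
    dplyr::rowwise() |>
    dplyr::mutate(ok = all(vapply(kids, function(k) {
      ka <- c(get(paste0("a1_", k)), get(paste0("a2_", k)))
      m <- c(a1_mother, a2_mother); f <- c(a1_father, a2_father)
      any(ka[1] == m & ka[2] %in% f) || any(ka[2] == m & ka[1] %in% f)
    }, logical(1)))) |>
    dplyr::ungroup()
  dn_classes <- grepl("^denovo", sim$truth$class)
  dn_ids <- sim$truth$variant_id[dn_classes]
  expect_true(all(mendel_ok$ok[!mendel_ok$variant_id %in% dn_ids]))
  expect_true(all(!mendel_ok$ok[mendel_ok$variant_id %in% dn_ids]))
})

test_that("allelic depths are consistent with genotypes", {
  cfg <- small_cfg(17)
  sim <- simulate_family(cfg)
  decoy_ids <- sim$truth$variant_id[grepl("^denovo_decoy",
                                          sim$truth$class)]
  g <- geno_long(sim$variants) |>
    dplyr::filter(!variant_id %in% decoy_ids) |>
    dplyr::mutate(total = ref_depth + alt_depth,
                  copies = (a1 == 1) + (a2 == 1))
  hom_ref <- g[g$copies == 0, ]
  expect_true(all(hom_ref$alt_depth <=
                    cfg$error_alt_fraction * hom_ref$total))
  het <- g[g$copies == 1, ]
  # pooled het allele balance near 0.5 (decoy bias affects a single site)
  expect_equal(sum(het$alt_depth) / sum(het$total), 0.5, tolerance = 0.05)
})

test_that("planted truth is recovered exactly across many seeds", {
  for (seed in 1:20) {
    sim <- simulate_family(small_cfg(seed))
    res <- run_bundle(sim)
    truth <- sim$truth
    expect_setequal(res$cascade$survivors$variant_id,
                    truth$variant_id[truth$class == "segregating"])
    expect_equal(res$cascade$n_segregating,
                 sum(truth$class %in% c("segregating", "kg_flagged")))
    expect_setequal(res$denovo$final$variant_id,
                    truth$variant_id[truth$class == "denovo"])
    qc_decoys <- truth$variant_id[grepl("^qc_decoy", truth$class)]
    expect_true(all(!res$qc$qc_pass[res$qc$variant_id %in% qc_decoys]))
  }
})

test_that("a configuration with no planted classes is pure background", {
  sim <- simulate_family(small_cfg(
    3, n_planted_segregating = 0, n_planted_kg_flagged = 0,
    n_planted_denovo = 0,
    denovo_decoys = c(shallow_trio = 0, parent_contamination = 0,
                      child_allele_bias = 0, known_dbsnp = 0),
    qc_decoys = c(cluster3in10 = 0, map_ambiguity = 0, min_depth = 0,
                  min_qual = 0, min_qd = 0, strand_bias = 0)))
  expect_true(all(sim$truth$class == "background"))
  res <- run_bundle(sim)
  expect_equal(res$cascade$n_after_kg_exclusion, 0L)
  expect_equal(nrow(res$denovo$final), 0L)
  expect_true(all(res$qc$qc_pass))
})

test_that("the worked-example fixture is deterministic and self-consistent", {
  fx1 <- paper_family_fixture()
  fx2 <- paper_family_fixture()
  expect_identical(as.data.frame(fx1$variants), as.data.frame(fx2$variants))
  # every variant annotated, keys unique
  expect_setequal(fx1$variants$variant_id, fx1$annotation$variant_id)
  expect_equal(anyDuplicated(fx1$variants$variant_id), 0L)
  # truth labels partition the variants
  expect_setequal(fx1$truth$variant_id, fx1$variants$variant_id)
})
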