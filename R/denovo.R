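#' Read-depth thresholds for de novo variant QC
#'
#' Three criteria separate true de novo events from genotyping artifacts:
#' \enumerate{
#'   \item `trio_depth`: more than `min_reads` (10) total reads in the
#'     mother, the father and the carrier child (strict: > 10);
#'   \item `parent_alt_fraction`: neither parent may have more than
#'     `max_parent_alt_fraction` (5%) of their reads from the non-reference
#'     allele (inclusive: <= 0.05);
#'   \item `child_ref_fraction`: a heterozygous carrier child may have no
#'     more than `max_child_ref_fraction` (70%) of reads from the reference
#'     allele (inclusive: <= 0.70; homozygous-alternate children pass
#'     vacuously and are flagged as atypical).
#' }
#'
#' @param min_reads,max_parent_alt_fraction,max_child_ref_fraction Threshold
#'   overrides.
#' @return A named list of thresholds (class `denovo_thresholds`).
#' @export
denovo_thresholds <- function(min_reads = 10, max_parent_alt_fraction = 0.05,
                              max_child_ref_fraction = 0.70) {
  stopifnot(min_reads >= 0,
            max_parent_alt_fraction > 0, max_parent_alt_fraction < 1,
            max_child_ref_fraction > 0, max_child_ref_fraction < 1)
  structure(list(min_reads = min_reads,
                 max_parent_alt_fraction = max_parent_alt_fraction,
                 max_child_ref_fraction = max_child_ref_fraction),
            class = "denovo_thresholds")
}

#' Mendelian-inconsistent candidate de novo calls
#'
#' A child yields a candidate at a site when it carries at least one copy of
#' the focal alternate allele and that allele is absent from both parents'
#' called genotypes. Sites where either parent is uncalled are skipped (and
#' counted in a message); founders never yield candidates.
#'
#' @param variants QC-passed variant tibble.
#' @param pedigree A nuclear-family `pedigree`.
#' @param quiet Suppress the skipped-site message.
#' @return A tibble with one row per (variant, carrier child): trio ids,
#'   genotype class (`"het"`/`"hom_alt"`) and per-person ref/alt read
#'   depths.
#' @export
denovo_candidates <- function(variants, pedigree, quiet = FALSE) {
  fam <- nuclear_family(pedigree)
  if (nrow(variants) == 0L) {
    return(tibble::tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), child_id = character(),
      child_alt_copies = integer(), child_ref_depth = integer(),
      child_alt_depth = integer(), mother_ref_depth = integer(),
      mother_alt_depth = integer(), father_ref_depth = integer(),
      father_alt_depth = integer(), child_gt = character()
    ))
  }
  g <- geno_long(variants)
  wide <- g |>
    dplyr::mutate(alt_copies = dplyr::if_else(
      .data$called, (.data$a1 == 1L) + (.data$a2 == 1L), NA_integer_))
  parents <- wide |>
    dplyr::filter(.data$sample_id %in% c(fam$mother, fam$father)) |>
    dplyr::mutate(role = dplyr::if_else(.data$sample_id == fam$mother,
                                        "mother", "father")) |>
    dplyr::select("variant_id", "role", "called", "alt_copies",
                  "ref_depth", "alt_depth") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("called", "alt_copies",
                                       "ref_depth", "alt_depth"))
  skipped <- parents$variant_id[!parents$called_mother | !parents$called_father]
  if (!quiet && length(skipped) > 0L) {
    rlang::inform(sprintf(
      "de novo scan: %d site(s) skipped (uncalled parent genotype)",
      length(skipped)))
  }
  eligible <- parents |>
    dplyr::filter(.data$called_mother, .data$called_father,
                  .data$alt_copies_mother == 0L, .data$alt_copies_father == 0L)
  kids <- wide |>
    dplyr::filter(.data$sample_id %in% fam$children, .data$called,
                  .data$alt_copies >= 1L) |>
    dplyr::select("variant_id", "chrom", "pos", "ref", "alt",
                  child_id = "sample_id", child_alt_copies = "alt_copies",
                  child_ref_depth = "ref_depth",
                  child_alt_depth = "alt_depth")
  kids |>
    dplyr::inner_join(
      dplyr::select(eligible, "variant_id",
                    mother_ref_depth = "ref_depth_mother",
                    mother_alt_depth = "alt_depth_mother",
                    father_ref_depth = "ref_depth_father",
                    father_alt_depth = "alt_depth_father"),
      by = "variant_id") |>
    dplyr::mutate(child_gt = dplyr::if_else(.data$child_alt_copies == 2L,
                                            "hom_alt", "het")) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$child_id)
}

#' Apply the three de novo QC criteria
#'
#' Fills per-criterion verdicts on each candidate. Candidates with absent
#' allelic depths in any trio member automatically fail `trio_depth`.
#'
#' @param candidates Tibble from [denovo_candidates()].
#' @param thresholds A [denovo_thresholds()] list.
#' @return The candidates with logical columns `trio_depth`,
#'   `parent_alt_fraction`, `child_ref_fraction`, `atypical_hom_alt` and the
#'   conjunction `qc_pass`.
#' @export
denovo_qc <- function(candidates, thresholds = denovo_thresholds()) {
  t <- thresholds
  tot <- function(r, a) {
    dplyr::coalesce(r, 0L) + dplyr::coalesce(a, 0L)
  }
  out <- candidates |>
    dplyr::mutate(
      mother_total = tot(.data$mother_ref_depth, .data$mother_alt_depth),
      father_total = tot(.data$father_ref_depth, .data$father_alt_depth),
      child_total = tot(.data$child_ref_depth, .data$child_alt_depth),
      depths_known = !is.na(.data$mother_ref_depth) &
        !is.na(.data$father_ref_depth) & !is.na(.data$child_ref_depth) &
        !is.na(.data$child_alt_depth),
      trio_depth = .data$depths_known &
        .data$mother_total > t$min_reads &
        .data$father_total > t$min_reads &
        .data$child_total > t$min_reads,
      parent_alt_fraction = .data$depths_known &
        dplyr::coalesce(.data$mother_alt_depth, 0L) <=
          t$max_parent_alt_fraction * .data$mother_total &
        dplyr::coalesce(.data$father_alt_depth, 0L) <=
          t$max_parent_alt_fraction * .data$father_total,
      atypical_hom_alt = .data$child_gt == "hom_alt",
      child_ref_fraction = .data$child_gt != "het" |
        (.data$depths_known &
           .data$child_ref_depth <=
             t$max_child_ref_fraction * .data$child_total),
      qc_pass = .data$trio_depth & .data$parent_alt_fraction &
        .data$child_ref_fraction
    )
  out
}

#' Finalize de novo calls and report mean coverage
#'
#' Restricts QC-passing candidates to dbSNP-novel variants and reports the
#' mean per-sample total read depth over the final variants across all
#' family members (rounded to the nearest integer; `NA` when no variant
#' survives).
#'
#' @param candidates_qc Output of [denovo_qc()].
#' @param annotated Annotated variant tibble (source of `dbsnp` and of the
#'   per-member depths for the coverage summary).
#' @param pedigree A `pedigree`.
#' @return A list with `final` (the surviving candidates, annotation columns
#'   joined) and `mean_coverage`.
#' @export
denovo_finalize <- function(candidates_qc, annotated, pedigree) {
  novelty <- annotated |>
    flag_novelty() |>
    dplyr::select("variant_id", "dbsnp_novel", dplyr::any_of(c(
      "region", "gene", "exonic_function", "aa_change", "dbsnp")))
  final <- candidates_qc |>
    dplyr::filter(.data$qc_pass) |>
    dplyr::inner_join(novelty, by = "variant_id") |>
    dplyr::filter(.data$dbsnp_novel)
  mean_coverage <- if (nrow(final) > 0L) {
    depths <- annotated |>
      dplyr::filter(.data$variant_id %in% final$variant_id) |>
      geno_long() |>
      dplyr::filter(.data$sample_id %in% pedigree$sample_id)
    round(mean(dplyr::coalesce(depths$ref_depth, 0L) +
                 dplyr::coalesce(depths$alt_depth, 0L)))
  } else {
    NA_real_
  }
  list(final = final, mean_coverage = mean_coverage)
}
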