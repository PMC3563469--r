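#' Count non-reference alleles per sample
#'
#' For each decomposed variant row and each pedigree member, counts copies of
#' the focal alternate allele: homozygous reference 0, heterozygous 1,
#' homozygous alternate 2. "Minor allele" here means the non-reference
#' allele, the counting convention used throughout; true sample-frequency
#' minorness is not computed.
#'
#' @param variants Variant tibble.
#' @param pedigree A `pedigree`; counts are returned for its members only.
#' @return A tibble with `variant_id`, `sample_id`, `count` (`NA` when the
#'   genotype is uncalled).
#' @export
nonref_counts <- function(variants, pedigree) {
  g <- geno_long(variants)
  g <- dplyr::filter(g, .data$sample_id %in% pedigree$sample_id)
  dplyr::transmute(
    g, .data$variant_id, .data$sample_id,
    count = dplyr::if_else(.data$called,
                           (.data$a1 == 1L) + (.data$a2 == 1L),
                           NA_integer_)
  )
}

#' Test allele-count segregation with affection status
#'
#' A variant segregates when every affected member carries at least one
#' non-reference allele and every unaffected member carries at least one
#' fewer than any affected member: `max(unaffected) <= min(affected) - 1`.
#' A variant with an uncalled genotype in any phenotyped member is
#' ineligible (`complete = FALSE`, `passes = FALSE`): the criterion
#' presupposes complete genotypes.
#'
#' @param counts Tibble from [nonref_counts()].
#' @param pedigree A `pedigree` with at least one affected and one unaffected
#'   member.
#' @return A tibble with one row per variant: `variant_id`, `complete`,
#'   `passes`, `margin` (min affected count minus max unaffected count).
#' @export
segregates <- function(counts, pedigree) {
  part <- ped_partition(pedigree)
  if (length(part$affected) == 0L || length(part$unaffected) == 0L) {
    stop("segregation requires at least one affected and one unaffected member")
  }
  counts |>
    dplyr::filter(.data$sample_id %in% c(part$affected, part$unaffected)) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      complete = !anyNA(.data$count),
      min_affected = suppressWarnings(
        min(.data$count[.data$sample_id %in% part$affected], na.rm = FALSE)),
      max_unaffected = suppressWarnings(
        max(.data$count[.data$sample_id %in% part$unaffected], na.rm = FALSE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      margin = .data$min_affected - .data$max_unaffected,
      passes = .data$complete & !is.na(.data$margin) &
        .data$min_affected >= 1L & .data$margin >= 1L
    ) |>
    dplyr::select("variant_id", "complete", "passes", "margin")
}

#' Novelty with respect to dbSNP and the 1000 Genomes Project
#'
#' Two independent flags on annotated variants: `dbsnp_novel` (no dbSNP id)
#' and `kg_excluded` (a 1000 Genomes allele frequency is present, so the
#' variant is removed at the frequency-exclusion stage even if dbSNP-novel).
#'
#' @param annotated A tibble carrying `dbsnp` and `kg_af` columns.
#' @return The input with logical columns `dbsnp_novel` and `kg_excluded`.
#' @export
flag_novelty <- function(annotated) {
  dplyr::mutate(annotated,
                dbsnp_novel = is.na(.data$dbsnp),
                kg_excluded = !is.na(.data$kg_af))
}

#' Run the novel/nonsynonymous segregation cascade
#'
#' Reproduces the prioritization cascade on QC-passed, annotated variants:
#' \enumerate{
#'   \item keep exonic nonsynonymous variants with no dbSNP id,
#'   \item keep variants whose allele counts segregate with affection status
#'     ([segregates()]),
#'   \item drop variants with a 1000 Genomes frequency.
#' }
#'
#' @param annotated QC-passed variant tibble with annotation columns (see
#'   [join_annotation()]).
#' @param pedigree A `pedigree`.
#' @param include_stopgain Also admit `stopgain` variants at stage 1
#'   (default `FALSE`: only `exonic_function == "nonsynonymous"`).
#' @return A `cascade_report`: stage counts (`n_input`, `n_novel_nonsyn`,
#'   `n_segregating`, `n_after_kg_exclusion`), the surviving variants with
#'   annotations, and the per-variant segregation table.
#' @export
run_cascade <- function(annotated, pedigree, include_stopgain = FALSE) {
  classes <- c("nonsynonymous", if (include_stopgain) "stopgain")
  stage1 <- annotated |>
    flag_novelty() |>
    dplyr::filter(.data$region %in% c("exonic", "exonic_splicing"),
                  .data$exonic_function %in% classes,
                  .data$dbsnp_novel)
  seg <- if (nrow(stage1) > 0L) {
    segregates(nonref_counts(stage1, pedigree), pedigree)
  } else {
    tibble::tibble(variant_id = character(), complete = logical(),
                   passes = logical(), margin = integer())
  }
  stage2 <- dplyr::semi_join(stage1,
                             dplyr::filter(seg, .data$passes),
                             by = "variant_id")
  stage3 <- dplyr::filter(stage2, !.data$kg_excluded)
  structure(
    list(
      n_input = nrow(annotated),
      n_novel_nonsyn = nrow(stage1),
      n_segregating = nrow(stage2),
      n_after_kg_exclusion = nrow(stage3),
      survivors = stage3,
      segregation = seg
    ),
    class = "cascade_report"
  )
}

#' @exportS3Method base::print
print.cascade_report <- function(x, ...) {
  cat("Segregation cascade\n")
  cat("  input (QC-passed, annotated): ", x$n_input, "\n", sep = "")
  cat("  novel nonsynonymous:          ", x$n_novel_nonsyn, "\n", sep = "")
  cat("  segregating with affection:   ", x$n_segregating, "\n", sep = "")
  cat("  after 1000G exclusion:        ", x$n_after_kg_exclusion, "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.cascade_report <- function(x, ...) {
  tibble::tibble(
    stage = c("input", "novel_nonsynonymous", "segregating",
              "after_kg_exclusion"),
    n = c(x$n_input, x$n_novel_nonsyn, x$n_segregating,
          x$n_after_kg_exclusion)
  )
}

#' @export
glance.cascade_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input, n_novel_nonsyn = x$n_novel_nonsyn,
    n_segregating = x$n_segregating,
    n_after_kg_exclusion = x$n_after_kg_exclusion
  )
}

#' Funnel plot of cascade stage counts
#'
#' @param object A `cascade_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cascade_report <- function(object, ...) {
  df <- tidy.cascade_report(object)
  df$stage <- factor(df$stage, levels = rev(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .12))) +
    ggplot2::labs(x = "variants", y = NULL,
                  title = "Variant prioritization cascade") +
    ggplot2::theme_minimal()
}
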