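burden_tiers <- c("all", "novel", "novel_nonsyn")

#' Per-child rare-allele counts over a candidate-gene set
#'
#' For each child, counts non-reference alleles at QC-passed variants whose
#' annotated gene symbol lies in the candidate set, at three nested tiers:
#' all variants, dbSNP-novel variants, and novel nonsynonymous variants.
#' A variant contributes through its annotation's gene field, so upstream/
#' downstream region classes count via their assigned symbol. The per-child
#' total of QC-passed variants (sites where the child carries at least one
#' non-reference allele) is recorded as the comparison denominator.
#'
#' @param annotated QC-passed variant tibble with annotation columns.
#' @param geneset Character vector of candidate gene symbols.
#' @param pedigree A `pedigree`.
#' @return A `burden_counts` tibble: one row per child with `n_all`,
#'   `n_novel`, `n_novel_nonsyn`, `n_total_qc`.
#' @export
count_burden <- function(annotated, geneset, pedigree) {
  if (length(geneset) == 0L) stop("candidate gene set is empty")
  part <- ped_partition(pedigree)
  counts <- nonref_counts(annotated, pedigree) |>
    dplyr::filter(.data$sample_id %in% part$children)
  flags <- annotated |>
    flag_novelty() |>
    dplyr::transmute(
      .data$variant_id,
      in_geneset = !is.na(.data$gene) & .data$gene %in% geneset,
      tier_novel = .data$dbsnp_novel,
      tier_novel_nonsyn = .data$dbsnp_novel &
        !is.na(.data$exonic_function) &
        .data$exonic_function == "nonsynonymous"
    )
  per_child <- counts |>
    dplyr::left_join(flags, by = "variant_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_all = sum(.data$count[.data$in_geneset], na.rm = TRUE),
      n_novel = sum(.data$count[.data$in_geneset & .data$tier_novel],
                    na.rm = TRUE),
      n_novel_nonsyn = sum(
        .data$count[.data$in_geneset & .data$tier_novel_nonsyn],
        na.rm = TRUE),
      n_total_qc = sum(.data$count >= 1L, na.rm = TRUE),
      .groups = "drop"
    )
  out <- tibble::tibble(sample_id = part$children) |>
    dplyr::left_join(per_child, by = "sample_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ dplyr::coalesce(.x, 0L)))
  class(out) <- c("burden_counts", class(tibble::tibble()))
  out
}

#' Build the case/control 2x2 allele table for one tier
#'
#' `a` = tier alleles summed over affected children, `b` = their summed
#' QC-passed variant totals minus `a`; `c`, `d` likewise for unaffected
#' children. The numerator counts alleles (het 1, hom 2) while the
#' denominator counts variant sites per child; the unit mismatch is
#' deliberate and matches the published arithmetic of this design.
#'
#' @param counts A `burden_counts` tibble (or any tibble with `sample_id`,
#'   the tier columns and `n_total_qc` — printed per-child totals can be
#'   supplied directly).
#' @param pedigree A `pedigree`.
#' @param tier `"all"`, `"novel"` or `"novel_nonsyn"`.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_table <- function(counts, pedigree, tier = c("novel", "novel_nonsyn",
                                                   "all")) {
  tier <- match.arg(tier)
  part <- ped_partition(pedigree)
  aff <- intersect(part$children, part$affected)
  unaff <- intersect(part$children, part$unaffected)
  if (length(aff) == 0L || length(unaff) == 0L) {
    stop("burden test requires at least one affected and one unaffected child")
  }
  tier_col <- paste0("n_", tier)
  tally <- function(ids) {
    rows <- counts[counts$sample_id %in% ids, ]
    num <- sum(rows[[tier_col]])
    rem <- sum(rows$n_total_qc) - num
    if (rem < 0) {
      stop("internal consistency error: tier allele count exceeds per-child ",
           "QC-passed totals")
    }
    c(num, rem)
  }
  a_b <- tally(aff); c_d <- tally(unaff)
  c(a = a_b[1], b = a_b[2], c = c_d[1], d = c_d[2])
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with `N = a+b+c+d`, referred to the chi-square distribution with one
#' degree of freedom. No continuity correction is applied.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return A list with `chi2` and `p`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi-square is undefined: a table margin is zero")
  }
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Odds ratio with a Woolf 95% confidence interval
#'
#' `OR = ad / bc`; interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d))` with `z = 1.96` by default.
#'
#' @param a,b,c,d Positive cell counts (with `correct = TRUE`, 0.5 is added
#'   to every cell first, allowing zeros).
#' @param z Normal quantile for the interval (default 1.96 exactly).
#' @param correct Apply the Haldane-Anscombe 0.5 continuity correction.
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(a, b, c, d, z = 1.96, correct = FALSE) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if (correct) {
    cells <- cells + 0.5
  } else if (any(cells == 0)) {
    stop("odds ratio is undefined with a zero cell; re-run with ",
         "correct = TRUE to add 0.5 to every cell")
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se))
}

#' Candidate-gene burden test across tiers
#'
#' Builds the affected-vs-unaffected 2x2 table for each requested tier and
#' computes the Pearson chi-square p-value and Woolf-interval odds ratio.
#'
#' @param counts A `burden_counts` tibble (see [count_burden()]; printed
#'   per-child counts may be supplied directly).
#' @param pedigree A `pedigree`.
#' @param tiers Tiers to test (default `"novel"` and `"novel_nonsyn"`).
#' @param z Normal quantile for the interval.
#' @return A `burden_result` whose `results` tibble has one row per tier
#'   (`a`, `b`, `c`, `d`, `chi2`, `p`, `odds_ratio`, `ci_low`, `ci_high`).
#' @export
burden_test <- function(counts, pedigree,
                        tiers = c("novel", "novel_nonsyn"), z = 1.96) {
  stopifnot(all(tiers %in% burden_tiers))
  rows <- purrr::map_dfr(tiers, function(tier) {
    tab <- unname(build_table(counts, pedigree, tier))
    chi <- pearson_chi2(tab[1], tab[2], tab[3], tab[4])
    orci <- odds_ratio_ci(tab[1], tab[2], tab[3], tab[4], z = z)
    tibble::tibble(tier = tier, a = tab[1], b = tab[2], c = tab[3],
                   d = tab[4], chi2 = chi$chi2, p = chi$p,
                   odds_ratio = orci$odds_ratio, ci_low = orci$ci_low,
                   ci_high = orci$ci_high)
  })
  structure(list(results = rows, counts = counts, z = z),
            class = "burden_result")
}

#' @exportS3Method base::print
print.burden_result <- function(x, ...) {
  cat("Candidate-gene rare-allele burden (affected vs unaffected children)\n")
  df <- x$results
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-13s a/b = %d/%d, c/d = %d/%d  OR = %.3f (95%% CI %.2f-%.2f), p = %.3f\n",
      df$tier[i], df$a[i], df$b[i], df$c[i], df$d[i], df$odds_ratio[i],
      df$ci_low[i], df$ci_high[i], df$p[i]))
  }
  invisible(x)
}

#' @export
tidy.burden_result <- function(x, ...) {
  x$results
}

#' @export
glance.burden_result <- function(x, ...) {
  tibble::tibble(n_children = nrow(x$counts), n_tiers = nrow(x$results),
                 z = x$z, min_p = min(x$results$p))
}

#' Odds-ratio plot for a burden result
#'
#' @param object A `burden_result`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled odds-ratio axis).
#' @export
autoplot.burden_result <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$tier)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (Woolf 95% CI)", y = NULL,
                  title = "Candidate-gene rare-allele burden") +
    ggplot2::theme_minimal()
}
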