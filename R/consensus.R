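#' Functional-prediction consensus thresholds
#'
#' Per-algorithm cut-offs on the transformed \[0, 1\] score scale (larger =
#' more damaging / conserved / constrained): SIFT 0.95, PolyPhen2 0.85
#' (the "damaging" band only; "possibly damaging" counts as not functional),
#' PhyloP 0.95, MutationTaster 0.95 (1 - p of a disease-causing prediction),
#' LRT 0.95 (codon constraint). Thresholds are applied inclusively (>=),
#' which is what the worked scorecards require at the 0.95 boundary.
#'
#' @param sift,polyphen2,phylop,mutation_taster,lrt Cut-off overrides.
#' @return A named numeric vector of thresholds.
#' @export
consensus_thresholds <- function(sift = 0.95, polyphen2 = 0.85, phylop = 0.95,
                                 mutation_taster = 0.95, lrt = 0.95) {
  c(sift = sift, polyphen2 = polyphen2, phylop = phylop,
    mutation_taster = mutation_taster, lrt = lrt)
}

#' Call one prediction algorithm functional or not
#'
#' @param name Algorithm name: one of `"sift"`, `"polyphen2"`, `"phylop"`,
#'   `"mutation_taster"`, `"lrt"`.
#' @param score Numeric score(s) in \[0, 1\].
#' @param thresholds From [consensus_thresholds()].
#' @return Character vector: `"functional"`, `"not_functional"`, or
#'   `"missing"` for `NA` scores.
#' @export
call_algorithm <- function(name, score, thresholds = consensus_thresholds()) {
  if (!name %in% names(thresholds)) {
    stop("unknown prediction algorithm: '", name, "'")
  }
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("prediction scores must lie in [0, 1]")
  }
  dplyr::case_when(
    is.na(score) ~ "missing",
    score >= thresholds[[name]] ~ "functional",
    .default = "not_functional"
  )
}

#' Consensus over the five prediction algorithms
#'
#' Calls each algorithm on its score column and flags variants supported by
#' two or more algorithms. Missing scores contribute no support and are no
#' error: a variant scored by one algorithm only is judged on that score.
#'
#' @param scored A tibble with columns `sift`, `polyphen2`, `phylop`,
#'   `mutation_taster`, `lrt` (`NA` = absent).
#' @param thresholds From [consensus_thresholds()].
#' @param min_support Algorithms required to flag a variant (default 2).
#' @return The input with per-algorithm call columns (`call_sift`, ...),
#'   `n_support` and `flagged`.
#' @export
consensus <- function(scored, thresholds = consensus_thresholds(),
                      min_support = 2L) {
  out <- scored
  for (alg in names(thresholds)) {
    out[[paste0("call_", alg)]] <- call_algorithm(alg, out[[alg]], thresholds)
  }
  call_cols <- paste0("call_", names(thresholds))
  out$n_support <- rowSums(
    as.matrix(out[call_cols]) == "functional"
  )
  out$flagged <- out$n_support >= min_support
  out
}

#' Flag functionally interesting cascade survivors
#'
#' Applies [consensus()] to cascade survivors and returns the flagged subset
#' sorted by support (descending) then genomic position.
#'
#' @param survivors Survivor tibble from [run_cascade()] (carries the five
#'   score columns).
#' @param thresholds From [consensus_thresholds()].
#' @param min_support Algorithms required to flag (default 2).
#' @return The flagged variants with consensus columns.
#' @export
flag_candidates <- function(survivors, thresholds = consensus_thresholds(),
                            min_support = 2L) {
  scored <- consensus(survivors, thresholds, min_support)
  scored |>
    dplyr::filter(.data$flagged) |>
    dplyr::arrange(dplyr::desc(.data$n_support), .data$chrom, .data$pos)
}

#' Tile plot of per-algorithm consensus calls
#'
#' @param scored Output of [consensus()]; needs a `gene` column for labels.
#' @return A ggplot object.
#' @export
plot_consensus <- function(scored) {
  call_cols <- grep("^call_", names(scored), value = TRUE)
  label <- if ("gene" %in% names(scored)) scored$gene else scored$variant_id
  df <- scored |>
    dplyr::mutate(.label = label) |>
    dplyr::select(".label", dplyr::all_of(call_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(call_cols), names_to = "algorithm",
                        values_to = "call") |>
    dplyr::mutate(algorithm = sub("^call_", "", .data$algorithm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$algorithm, y = .data$.label,
                                   fill = .data$call)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(functional = "firebrick",
                                          not_functional = "grey80",
                                          missing = "grey95")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call",
                  title = "Functional-prediction consensus") +
    ggplot2::theme_minimal()
}
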