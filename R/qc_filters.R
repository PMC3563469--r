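#' Hard-filter thresholds for called variants
#'
#' Six site-level flags mark a variant "low quality"; failing any single one
#' removes it from analysis:
#' \itemize{
#'   \item `cluster3in10`: `cluster_k` (3) or more variant positions within a
#'     `cluster_window` (10 bp) window,
#'   \item `map_ambiguity`: `mq0_max` (4) or more reads mapping equally well
#'     to different locations,
#'   \item `min_depth`: coverage below `min_depth` (5) reads,
#'   \item `min_qual`: Phred site quality below `min_qual` (50),
#'   \item `min_qd`: variant confidence / unfiltered depth below `min_qd`
#'     (1.5),
#'   \item `strand_bias`: Phred-scaled Fisher strand-bias p above `max_fs`
#'     (200).
#' }
#' Boundary orientation is literal: strictly-less-than for depth, quality and
#' QD; strictly-greater-than for FS; at-least for the cluster count and MQ0.
#'
#' @param cluster_k,cluster_window,mq0_max,min_depth,min_qual,min_qd,max_fs
#'   Threshold overrides.
#' @return A named list of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(cluster_k = 3, cluster_window = 10, mq0_max = 4,
                          min_depth = 5, min_qual = 50, min_qd = 1.5,
                          max_fs = 200) {
  t <- list(cluster_k = cluster_k, cluster_window = cluster_window,
            mq0_max = mq0_max, min_depth = min_depth, min_qual = min_qual,
            min_qd = min_qd, max_fs = max_fs)
  stopifnot(all(vapply(t, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(t, class = "qc_thresholds")
}

qc_filter_names <- c("cluster3in10", "map_ambiguity", "min_depth",
                     "min_qual", "min_qd", "strand_bias")

#' Flag variants in dense SNP clusters
#'
#' A site is flagged when some window of `cluster_window` bp on its
#' chromosome contains at least `cluster_k` distinct variant positions
#' including it; "within w bp" means window span <= w (positions p and
#' p + w - 1 share a window, p and p + w do not). Decomposed multi-allelic
#' rows at one position count once.
#'
#' @param variants Variant tibble sorted by (chrom, pos).
#' @param thresholds A [qc_thresholds()] list.
#' @return Logical vector, one element per row of `variants`.
#' @export
flag_clusters <- function(variants, thresholds = qc_thresholds()) {
  if (nrow(variants) == 0L) return(logical())
  chrom_blocks <- rle(variants$chrom)$values
  pos_sorted <- tapply(variants$pos, variants$chrom,
                       function(p) !is.unsorted(p))
  if (anyDuplicated(chrom_blocks) || !all(pos_sorted)) {
    stop("variants must be sorted by (chrom, pos) for cluster flagging")
  }
  k <- thresholds$cluster_k
  span <- thresholds$cluster_window - 1L
  flagged_pos <- variants |>
    dplyr::distinct(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      p <- df$pos
      n <- length(p)
      flag <- rep(FALSE, n)
      if (n >= k) {
        for (j in seq_len(n - k + 1L)) {
          if (p[j + k - 1L] - p[j] <= span) flag[j:(j + k - 1L)] <- TRUE
        }
      }
      df$cluster_flag <- flag
      df
    }) |>
    dplyr::ungroup()
  out <- dplyr::left_join(
    dplyr::select(variants, "chrom", "pos"), flagged_pos,
    by = c("chrom", "pos")
  )
  out$cluster_flag
}

#' Apply the six low-quality flags to a cohort of variants
#'
#' Evaluates each rule per site and partitions the cohort into passed and
#' failed with per-filter reasons. A site with an absent metric is not
#' failed by that metric (the rule is recorded as unevaluated), so VCFs
#' lacking one INFO key are not discarded wholesale.
#'
#' @param variants Variant tibble sorted by (chrom, pos).
#' @param thresholds A [qc_thresholds()] list.
#' @return The variant tibble with added columns `qc_pass` (logical),
#'   `qc_failed` (list of failed filter names) and `qc_unevaluated` (list of
#'   rules whose metric was absent).
#' @seealso [qc_summary()], [qc_passed()]
#' @export
qc_filter <- function(variants, thresholds = qc_thresholds()) {
  t <- thresholds
  clustered <- flag_clusters(variants, t)
  fails <- list(
    cluster3in10 = clustered,
    map_ambiguity = !is.na(variants$mq0) & variants$mq0 >= t$mq0_max,
    min_depth = !is.na(variants$dp) & variants$dp < t$min_depth,
    min_qual = !is.na(variants$qual) & variants$qual < t$min_qual,
    min_qd = !is.na(variants$qd) & variants$qd < t$min_qd,
    strand_bias = !is.na(variants$fs) & variants$fs > t$max_fs
  )
  uneval <- list(
    map_ambiguity = is.na(variants$mq0),
    min_depth = is.na(variants$dp),
    min_qual = is.na(variants$qual),
    min_qd = is.na(variants$qd),
    strand_bias = is.na(variants$fs)
  )
  fail_mat <- do.call(cbind, fails)
  out <- variants
  out$qc_failed <- apply(fail_mat, 1L, function(r) qc_filter_names[r],
                         simplify = FALSE)
  out$qc_unevaluated <- apply(do.call(cbind, uneval), 1L,
                              function(r) names(uneval)[r], simplify = FALSE)
  out$qc_pass <- rowSums(fail_mat) == 0L
  out
}

#' Keep only QC-passing variants
#'
#' @param qc Output of [qc_filter()].
#' @return The passing subset, without the QC bookkeeping columns.
#' @export
qc_passed <- function(qc) {
  dplyr::select(dplyr::filter(qc, .data$qc_pass),
                -dplyr::any_of(c("qc_pass", "qc_failed", "qc_unevaluated")))
}

#' Summarize a QC run
#'
#' @param qc Output of [qc_filter()].
#' @return A list with `n_input`, `n_passed`, `n_failed`, a tibble of
#'   per-filter failure counts, a tibble of per-rule unevaluated counts, and
#'   (when the input carries a `region` column) the region-class distribution
#'   of passing sites.
#' @export
qc_summary <- function(qc) {
  per_filter <- tibble::tibble(
    filter = qc_filter_names,
    n_failed = vapply(qc_filter_names, function(f) {
      sum(vapply(qc$qc_failed, function(x) f %in% x, logical(1)))
    }, integer(1))
  )
  uneval_rules <- setdiff(qc_filter_names, "cluster3in10")
  unevaluated <- tibble::tibble(
    filter = uneval_rules,
    n_unevaluated = vapply(uneval_rules, function(f) {
      sum(vapply(qc$qc_unevaluated, function(x) f %in% x, logical(1)))
    }, integer(1))
  )
  region_dist <- if ("region" %in% names(qc)) {
    dplyr::count(dplyr::filter(qc, .data$qc_pass), .data$region,
                 name = "n_passed")
  } else {
    NULL
  }
  list(
    n_input = nrow(qc),
    n_passed = sum(qc$qc_pass),
    n_failed = sum(!qc$qc_pass),
    per_filter = per_filter,
    unevaluated = unevaluated,
    region_distribution = region_dist
  )
}
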