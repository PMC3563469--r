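#' Run the full prioritization pipeline on input files
#'
#' Orchestrates the stages in order: read and validate inputs (a pre-flight
#' check fails before any stage if the VCF does not cover the pedigree),
#' hard QC filtering, the novel/nonsynonymous segregation cascade, the
#' functional-prediction consensus, the candidate-gene burden test, and de
#' novo detection with depth QC. Returns a machine-readable run report plus
#' every stage's output.
#'
#' @param vcf,ped,annot,genes Paths to the multi-sample VCF, 6-column PED,
#'   annotation TSV and candidate-gene list.
#' @param qc [qc_thresholds()] overrides.
#' @param consensus_cutoffs [consensus_thresholds()] overrides.
#' @param denovo [denovo_thresholds()] overrides.
#' @param z Normal quantile for the burden odds-ratio interval.
#' @param include_stopgain Admit stopgain variants at cascade stage 1.
#' @param quiet Suppress progress messages.
#' @return A `run_report` list: `report` (JSON-serializable: per-stage
#'   counts, thresholds used, package version, input file digests) and
#'   `stages` (QC tibble, cascade report, consensus tibble, burden result,
#'   de novo results).
#' @export
run_pipeline <- function(vcf, ped, annot, genes,
                         qc = qc_thresholds(),
                         consensus_cutoffs = consensus_thresholds(),
                         denovo = denovo_thresholds(),
                         z = 1.96, include_stopgain = FALSE, quiet = TRUE) {
  inputs <- c(vcf = vcf, ped = ped, annot = annot, genes = genes)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0L) {
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "))
  }
  pedigree <- read_ped(ped)
  variants <- read_vcf(vcf, pedigree = pedigree)  # pre-flight sample check
  annotation <- read_annotation(annot)
  geneset <- read_gene_list(genes)

  say <- function(...) if (!quiet) rlang::inform(paste0(...))

  qc_res <- qc_filter(variants, qc)
  passed <- qc_passed(qc_res)
  say("qc: ", nrow(passed), "/", nrow(variants), " variants passed")
  annotated <- join_annotation(passed, annotation, quiet = TRUE)

  cascade <- run_cascade(annotated, pedigree,
                         include_stopgain = include_stopgain)
  say("cascade: ", cascade$n_segregating, " segregating, ",
      cascade$n_after_kg_exclusion, " after 1000G exclusion")
  flagged <- flag_candidates(cascade$survivors, consensus_cutoffs)

  counts <- count_burden(annotated, geneset, pedigree)
  # an empty cohort leaves the 2x2 tables degenerate; report zero counts
  burden <- if (nrow(counts) > 0L && sum(counts$n_total_qc) > 0L) {
    burden_test(counts, pedigree, z = z)
  } else {
    NULL
  }

  candidates <- denovo_candidates(annotated, pedigree, quiet = TRUE)
  candidates_qc <- denovo_qc(candidates, denovo)
  dn <- denovo_finalize(candidates_qc, annotated, pedigree)
  say("de novo: ", nrow(dn$final), " final call(s)")

  report <- list(
    tool = "pedseg",
    version = as.character(utils::packageVersion("pedseg")),
    inputs = as.list(tools::md5sum(inputs)),
    thresholds = list(
      qc = unclass(qc),
      consensus = as.list(consensus_cutoffs),
      denovo = unclass(denovo),
      burden_z = z,
      include_stopgain = include_stopgain
    ),
    stages = list(
      qc = list(n_input = nrow(variants), n_passed = nrow(passed),
                n_failed = nrow(variants) - nrow(passed)),
      cascade = list(n_input = cascade$n_input,
                     n_novel_nonsyn = cascade$n_novel_nonsyn,
                     n_segregating = cascade$n_segregating,
                     n_after_kg_exclusion = cascade$n_after_kg_exclusion),
      consensus = list(n_flagged = nrow(flagged)),
      burden = if (is.null(burden)) list() else {
        lapply(seq_len(nrow(burden$results)), function(i) {
          as.list(burden$results[i, ])
        })
      },
      denovo = list(n_candidates = nrow(candidates),
                    n_qc_pass = sum(candidates_qc$qc_pass),
                    n_final = nrow(dn$final),
                    mean_coverage = dn$mean_coverage)
    )
  )
  structure(
    list(report = report,
         stages = list(qc = qc_res, cascade = cascade, consensus = flagged,
                       burden = burden, denovo = list(
                         candidates = candidates_qc, final = dn$final,
                         mean_coverage = dn$mean_coverage))),
    class = "run_report"
  )
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  r <- x$report$stages
  cat("pedseg run report\n")
  cat("  qc:       ", r$qc$n_passed, "/", r$qc$n_input, " passed\n", sep = "")
  cat("  cascade:  ", r$cascade$n_novel_nonsyn, " novel nonsyn -> ",
      r$cascade$n_segregating, " segregating -> ",
      r$cascade$n_after_kg_exclusion, " after 1000G exclusion\n", sep = "")
  cat("  consensus:", r$consensus$n_flagged, "flagged\n")
  cat("  denovo:   ", r$denovo$n_final, " final (mean coverage ",
      r$denovo$mean_coverage, "x)\n", sep = "")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param x A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(x, path) {
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
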