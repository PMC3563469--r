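#' @importFrom rlang .data
NULL

# Canonical region vocabulary for annotation tables (ANNOVAR-style classes).
region_levels <- c(
  "exonic", "splicing", "exonic_splicing", "UTR5", "UTR3", "intronic",
  "ncRNA_exonic", "ncRNA_intronic", "ncRNA_UTR5", "ncRNA_UTR3",
  "ncRNA_splicing", "upstream", "downstream", "intergenic",
  "upstream_downstream", "UTR5_UTR3"
)

exonic_function_levels <- c(
  "synonymous", "nonsynonymous", "stopgain", "stoploss", "frameshift",
  "nonframeshift", "unknown"
)

score_columns <- c("sift", "polyphen2", "phylop", "mutation_taster", "lrt")

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a multi-sample VCF into a variant tibble
#'
#' Reads a VCF v4.x file (GT required; per-sample AD and INFO keys `DP`,
#' `QD`, `FS` and a mapping-ambiguity read count optional) and returns one
#' row per alternate allele: multi-allelic records are decomposed into
#' per-alternate pseudo-sites with per-sample allele indices remapped, so
#' every downstream rule operates per allele. Coordinates stay 1-based
#' throughout.
#'
#' @param path Path to a VCF file.
#' @param pedigree Optional `pedigree`; when given, every pedigree member
#'   must appear in the VCF sample header.
#' @param mq0_key INFO key holding the count of ambiguously mapped reads
#'   (reads mapping equally well to several locations). Default `"MQ0"`,
#'   the classic convention.
#' @return A tibble with one row per (chrom, pos, ref, alt): columns
#'   `chrom`, `pos`, `ref`, `alt`, site metrics `qual`, `dp`, `qd`, `fs`,
#'   `mq0` (`NA` when absent) and a `genotypes` list-column of per-sample
#'   tibbles (`sample_id`, `called`, `a1`, `a2`, `ref_depth`, `alt_depth`).
#' @seealso [write_vcf()], [geno_long()]
#' @export
read_vcf <- function(path, pedigree = NULL, mq0_key = "MQ0") {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(pedigree)) {
    absent <- setdiff(pedigree$sample_id, samples)
    if (length(absent) > 0L) {
      stop("pedigree member(s) missing from VCF header: ",
           paste(absent, collapse = ", "))
    }
  }
  fix <- vcf@fix
  n <- nrow(fix)
  if (n == 0L) return(empty_variants(samples))

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ad_raw <- if (any(grepl("AD", vcf@gt[, "FORMAT"]))) {
    vcfR::extract.gt(vcf, element = "AD")
  } else {
    matrix(NA_character_, nrow = n, ncol = length(samples))
  }
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }
  dp <- info_num("DP"); qd <- info_num("QD"); fs <- info_num("FS")
  mq0 <- info_num(mq0_key)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- parse_gt_row(unname(gt_raw[i, ]), n_alt = length(alts),
                            record = paste0(fix[i, "CHROM"], ":", fix[i, "POS"]))
    depths <- parse_ad_row(unname(ad_raw[i, ]))
    rows[[i]] <- purrr::map_dfr(seq_along(alts), function(k) {
      geno <- tibble::tibble(
        sample_id = samples,
        called = alleles$called,
        a1 = remap_allele(alleles$a1, k),
        a2 = remap_allele(alleles$a2, k),
        ref_depth = depths$ref,
        alt_depth = purrr::map_int(depths$alt, function(a) {
          if (length(a) >= k) a[[k]] else NA_integer_
        })
      )
      tibble::tibble(
        chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
        ref = unname(fix[i, "REF"]), alt = alts[[k]],
        qual = qual[i], dp = dp[i], qd = qd[i], fs = fs[i], mq0 = mq0[i],
        genotypes = list(geno)
      )
    })
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt)
  out$variant_id <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  dplyr::relocate(out, "variant_id")
}

empty_variants <- function(samples) {
  tibble::tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), qual = double(), dp = double(),
    qd = double(), fs = double(), mq0 = double(), genotypes = list()
  )
}

parse_gt_row <- function(gt, n_alt, record) {
  parts <- strsplit(gt, "[/|]")
  called <- !is.na(gt) & !vapply(parts, function(p) any(p == "."), logical(1))
  a1 <- a2 <- rep(NA_integer_, length(gt))
  idx <- which(called)
  if (length(idx) > 0L) {
    nums <- suppressWarnings(lapply(parts[idx], as.integer))
    if (any(vapply(nums, function(x) any(is.na(x)) || length(x) != 2L, logical(1)))) {
      stop("unparseable GT at record ", record)
    }
    a1[idx] <- vapply(nums, `[`, integer(1), 1L)
    a2[idx] <- vapply(nums, `[`, integer(1), 2L)
    if (any(c(a1[idx], a2[idx]) > n_alt)) {
      stop("GT allele index exceeds alternate allele count at record ", record)
    }
  }
  list(called = called, a1 = a1, a2 = a2)
}

parse_ad_row <- function(ad) {
  parsed <- lapply(ad, function(x) {
    if (is.na(x) || x == ".") return(NULL)
    suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  })
  list(
    ref = vapply(parsed, function(p) {
      if (is.null(p) || length(p) < 1L) NA_integer_ else p[[1]]
    }, integer(1)),
    alt = lapply(parsed, function(p) {
      if (is.null(p) || length(p) < 2L) integer() else p[-1]
    })
  )
}

# Focal-alternate remap: allele index k becomes 1, anything else (reference
# or another alternate) becomes 0.
remap_allele <- function(a, k) {
  out <- rep(NA_integer_, length(a))
  out[!is.na(a)] <- as.integer(a[!is.na(a)] == k)
  out
}

#' Write a variant tibble to a plain-text VCF
#'
#' Emits a minimal, deterministic VCF v4.2 (GT:AD per sample; INFO DP/QD/FS/
#' MQ0 where present). Rows must be biallelic pseudo-sites as produced by
#' [read_vcf()] or the simulator.
#'
#' @param variants A variant tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- if (nrow(variants) > 0L) {
    variants$genotypes[[1]]$sample_id
  } else {
    character()
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pedseg",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant confidence by unfiltered depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand-bias Fisher p\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads mapping equally well elsewhere\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  body <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info_parts <- c(
      if (!is.na(v$dp)) paste0("DP=", fmt_num(v$dp)),
      if (!is.na(v$qd)) paste0("QD=", fmt_num(v$qd)),
      if (!is.na(v$fs)) paste0("FS=", fmt_num(v$fs)),
      if (!is.na(v$mq0)) paste0("MQ0=", fmt_num(v$mq0))
    )
    info <- if (length(info_parts) == 0L) "." else paste(info_parts, collapse = ";")
    g <- v$genotypes[[1]]
    cells <- purrr::pmap_chr(g, function(sample_id, called, a1, a2,
                                         ref_depth, alt_depth, ...) {
      gt <- if (!called) "./." else paste0(a1, "/", a2)
      ad <- if (is.na(ref_depth) && is.na(alt_depth)) {
        "."
      } else {
        paste0(ifelse(is.na(ref_depth), ".", ref_depth), ",",
               ifelse(is.na(alt_depth), ".", alt_depth))
      }
      paste(gt, ad, sep = ":")
    })
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt,
            if (is.na(v$qual)) "." else fmt_num(v$qual), ".", info, "GT:AD",
            cells), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Unnest genotypes into a long per-sample table
#'
#' @param variants A variant tibble with a `genotypes` list-column.
#' @return A tibble with one row per (variant, sample).
#' @export
geno_long <- function(variants) {
  if (nrow(variants) == 0L) {
    return(tibble::tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), sample_id = character(),
      called = logical(), a1 = integer(), a2 = integer(),
      ref_depth = integer(), alt_depth = integer()
    ))
  }
  tidyr::unnest(
    dplyr::select(variants, "variant_id", "chrom", "pos", "ref", "alt",
                  "genotypes"),
    "genotypes"
  )
}

#' Read a per-variant annotation table
#'
#' Tab-delimited with a header naming at least `chrom`, `pos`, `ref`, `alt`,
#' `region`, `gene`, `exonic_function`, `aa_change`, `dbsnp`, `kg_af` and
#' the five prediction scores `sift`, `polyphen2`, `phylop`,
#' `mutation_taster`, `lrt` (the shape ANNOVAR emits after score
#' transformation: all scores in \[0, 1\], larger = more damaging or more
#' conserved). Empty cells or `"."` mean absent.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble keyed by (chrom, pos, ref, alt).
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "."), progress = FALSE)
  mandatory <- c("chrom", "pos", "ref", "alt", "region", "gene",
                 "exonic_function", "aa_change", "dbsnp", "kg_af",
                 score_columns)
  missing_cols <- setdiff(mandatory, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ann <- dplyr::mutate(
    ann,
    pos = as.integer(.data$pos),
    dplyr::across(dplyr::all_of(c("kg_af", score_columns)), as.numeric)
  )
  if (any(!is.na(ann$kg_af) & (ann$kg_af < 0 | ann$kg_af > 1))) {
    stop("kg_af outside [0, 1] in annotation table")
  }
  bad_region <- setdiff(unique(stats::na.omit(ann$region)), region_levels)
  if (length(bad_region) > 0L) {
    stop("unknown region class(es) in annotation table: ",
         paste(bad_region, collapse = ", "))
  }
  bad_fn <- setdiff(unique(stats::na.omit(ann$exonic_function)),
                    exonic_function_levels)
  if (length(bad_fn) > 0L) {
    stop("unknown exonic_function value(s): ", paste(bad_fn, collapse = ", "))
  }
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, ref, alt) key(s) in annotation table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  ann$variant_id <- key
  dplyr::relocate(tibble::as_tibble(ann), "variant_id")
}

#' Join annotations onto variant sites
#'
#' Left-joins the annotation table onto the variant tibble by
#' (chrom, pos, ref, alt). Every site keeps a row; sites without a matching
#' annotation are marked `annotated = FALSE` and counts of both groups are
#' reported as a message.
#'
#' @param variants A variant tibble.
#' @param annotation Tibble from [read_annotation()].
#' @param quiet Suppress the coverage message.
#' @return The variant tibble with annotation columns and an `annotated`
#'   flag.
#' @export
join_annotation <- function(variants, annotation, quiet = FALSE) {
  ann <- dplyr::select(annotation, -dplyr::any_of("variant_id"))
  out <- dplyr::left_join(variants, ann,
                          by = c("chrom", "pos", "ref", "alt"))
  out$annotated <- !is.na(out$region) | !is.na(out$gene)
  if (!quiet) {
    rlang::inform(sprintf("annotation join: %d annotated, %d unannotated",
                          sum(out$annotated), sum(!out$annotated)))
  }
  out
}

#' Read a candidate-gene list
#'
#' One gene symbol per line; `#` comments and blank lines are ignored;
#' duplicates are dropped.
#'
#' @param path Path to the gene-list file.
#' @return A character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(sub("#.*$", "", readLines(path)))
  genes <- unique(lines[nzchar(lines)])
  if (length(genes) == 0L) {
    stop("gene list '", path, "' is empty; an empty candidate set is almost ",
         "surely a user error")
  }
  genes
}
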