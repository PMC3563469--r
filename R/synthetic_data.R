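#' Build one variant row for a variant tibble
#'
#' Low-level constructor shared by the simulator, the worked-example fixture
#' and tests: one biallelic site with per-sample genotypes and allelic
#' depths.
#'
#' @param chrom,pos,ref,alt Site coordinates and alleles.
#' @param gt Named character vector of genotypes per sample (`"0/0"`,
#'   `"0/1"`, `"1/1"`, `"./."`).
#' @param ad Optional named list of `c(ref, alt)` integer depths per sample;
#'   samples without an entry get `NA` depths.
#' @param qual,dp,qd,fs,mq0 Site metrics (`NA` = absent).
#' @return A one-row variant tibble.
#' @export
make_variant <- function(chrom, pos, ref, alt, gt, ad = NULL, qual = 900,
                         dp = 300, qd = 3, fs = 1.2, mq0 = 0) {
  samples <- names(gt)
  parts <- strsplit(unname(gt), "/", fixed = TRUE)
  called <- vapply(parts, function(p) !any(p == "."), logical(1))
  a1 <- a2 <- rep(NA_integer_, length(gt))
  a1[called] <- as.integer(vapply(parts[called], `[`, character(1), 1L))
  a2[called] <- as.integer(vapply(parts[called], `[`, character(1), 2L))
  ref_depth <- alt_depth <- rep(NA_integer_, length(gt))
  if (!is.null(ad)) {
    for (s in names(ad)) {
      i <- match(s, samples)
      ref_depth[i] <- as.integer(ad[[s]][1])
      alt_depth[i] <- as.integer(ad[[s]][2])
    }
  }
  geno <- tibble::tibble(sample_id = samples, called = called, a1 = a1,
                         a2 = a2, ref_depth = ref_depth,
                         alt_depth = alt_depth)
  tibble::tibble(
    variant_id = variant_key(chrom, pos, ref, alt),
    chrom = as.character(chrom), pos = as.integer(pos), ref = ref, alt = alt,
    qual = as.numeric(qual), dp = as.numeric(dp), qd = as.numeric(qd),
    fs = as.numeric(fs), mq0 = as.numeric(mq0), genotypes = list(geno)
  )
}

#' Simulation configuration for a synthetic nuclear family
#'
#' Defaults emulate the study design the package reproduces: a two-parent,
#' four-child family with an affected mother and two affected children, 14
#' planted affected-segregating novel nonsynonymous variants of which 4
#' carry a 1000 Genomes frequency (so the cascade yields 14 then 10), two
#' planted de novo events with conforming read-depth profiles, one de novo
#' decoy per failure mode and one QC decoy per hard filter, on a Mendelian
#' background of common (dbSNP/1000G) and rare novel variants. Read totals
#' follow a negative binomial with mean `depth_mean` and dispersion
#' `depth_dispersion`; heterozygous allele balance is 0.5.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_children Number of children.
#' @param affected_children Ids of affected children (children are named
#'   `child1`, `child2`, ...).
#' @param mother_affected Is the mother affected? (The father is always
#'   unaffected; planted segregating variants are transmitted from an
#'   affected parent, so one is required when `n_planted_segregating > 0`.)
#' @param n_background_common Common Mendelian background variants (dbSNP id
#'   and 1000 Genomes frequency present).
#' @param n_background_rare Rare novel background variants (one carrier
#'   parent, Mendelian transmission, no dbSNP id).
#' @param n_candidate_genes Genes in the candidate set; background and
#'   planted variants are assigned to candidate genes at random.
#' @param n_planted_segregating Planted affected-segregating novel
#'   nonsynonymous variants.
#' @param n_planted_kg_flagged Subset of the planted segregating variants
#'   carrying a 1000 Genomes frequency (removed at the exclusion stage).
#' @param n_planted_denovo Planted de novo events passing all depth criteria.
#' @param denovo_decoys Named counts per failure mode: `shallow_trio`,
#'   `parent_contamination`, `child_allele_bias`, `known_dbsnp`.
#' @param qc_decoys Named counts per hard filter: `cluster3in10` (plants a
#'   3-site cluster per unit), `map_ambiguity`, `min_depth`, `min_qual`,
#'   `min_qd`, `strand_bias`.
#' @param depth_mean,depth_dispersion Negative-binomial read-total model.
#' @param error_alt_fraction Maximum alternate-read fraction generated for
#'   homozygous-reference calls.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_children = 4L,
                       affected_children = c("child1", "child2"),
                       mother_affected = TRUE,
                       n_background_common = 120L,
                       n_background_rare = 40L,
                       n_candidate_genes = 25L,
                       n_planted_segregating = 14L,
                       n_planted_kg_flagged = 4L,
                       n_planted_denovo = 2L,
                       denovo_decoys = c(shallow_trio = 1L,
                                         parent_contamination = 1L,
                                         child_allele_bias = 1L,
                                         known_dbsnp = 1L),
                       qc_decoys = c(cluster3in10 = 1L, map_ambiguity = 1L,
                                     min_depth = 1L, min_qual = 1L,
                                     min_qd = 1L, strand_bias = 1L),
                       depth_mean = 150, depth_dispersion = 8,
                       error_alt_fraction = 0.01) {
  cfg <- list(seed = as.integer(seed), n_children = as.integer(n_children),
              affected_children = affected_children,
              mother_affected = isTRUE(mother_affected),
              n_background_common = as.integer(n_background_common),
              n_background_rare = as.integer(n_background_rare),
              n_candidate_genes = as.integer(n_candidate_genes),
              n_planted_segregating = as.integer(n_planted_segregating),
              n_planted_kg_flagged = as.integer(n_planted_kg_flagged),
              n_planted_denovo = as.integer(n_planted_denovo),
              denovo_decoys = denovo_decoys, qc_decoys = qc_decoys,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              error_alt_fraction = error_alt_fraction)
  if (cfg$n_planted_kg_flagged > cfg$n_planted_segregating) {
    stop("n_planted_kg_flagged cannot exceed n_planted_segregating")
  }
  if (cfg$n_planted_segregating > 0L && !cfg$mother_affected) {
    stop("planted segregating variants require an affected parent to ",
         "transmit them (set mother_affected = TRUE)")
  }
  bad_children <- setdiff(cfg$affected_children,
                          paste0("child", seq_len(cfg$n_children)))
  if (length(bad_children) > 0L) {
    stop("affected_children not in the family: ",
         paste(bad_children, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

# Positions spaced >= 20 bp apart on chromosomes 1..22 so no accidental
# 3-in-10bp cluster arises; cluster decoys plant their own tight positions.
draw_positions <- function(n) {
  chrom <- sort(sample(as.character(1:22), n, replace = TRUE))
  pos <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 100000L + cumsum(sample(20:5000, length(idx), replace = TRUE))
  }
  tibble::tibble(chrom = chrom, pos = pos)
}

draw_total_depth <- function(n, cfg, min_total = 20L) {
  pmax(stats::rnbinom(n, size = cfg$depth_dispersion, mu = cfg$depth_mean),
       min_total)
}

# Allelic depths consistent with a genotype string.
draw_ad <- function(gt, total, error_frac, het_balance = 0.5) {
  if (gt == "0/0") {
    alt <- sample.int(floor(error_frac * total) + 1L, 1L) - 1L
    c(total - alt, alt)
  } else if (gt == "1/1") {
    ref <- sample.int(floor(error_frac * total) + 1L, 1L) - 1L
    c(ref, total - ref)
  } else {
    alt <- stats::rbinom(1L, total, het_balance)
    c(total - alt, alt)
  }
}

# Mendelian transmission: one allele from each parent, uniformly.
transmit <- function(mother_gt, father_gt, n_children) {
  m <- as.integer(strsplit(mother_gt, "/", fixed = TRUE)[[1]])
  f <- as.integer(strsplit(father_gt, "/", fixed = TRUE)[[1]])
  vapply(seq_len(n_children), function(i) {
    a <- sample(m, 1L); b <- sample(f, 1L)
    paste(sort(c(a, b)), collapse = "/")
  }, character(1))
}

count_from_gt <- function(gt) {
  vapply(strsplit(gt, "/", fixed = TRUE),
         function(p) sum(p == "1"), integer(1))
}

segregating_pattern <- function(gts, affected, unaffected) {
  counts <- count_from_gt(gts)
  names(counts) <- names(gts)
  min_aff <- min(counts[affected])
  max_unaff <- max(counts[unaffected])
  min_aff >= 1L && max_unaff <= min_aff - 1L
}

#' Generate a synthetic nuclear-family input bundle with planted truth
#'
#' Produces mutually consistent pedigree, variant, annotation and
#' candidate-gene tables plus a truth table labelling every variant:
#' `background`, `segregating`, `kg_flagged`, `denovo`,
#' `denovo_decoy:<mode>` or `qc_decoy:<filter>`. Background genotypes obey
#' Mendelian transmission (zero Mendelian errors outside the planted de novo
#' classes); planted segregating variants are heterozygous in every affected
#' member and homozygous reference in every unaffected member; planted de
#' novo events carry read-depth profiles passing all three depth criteria
#' while each decoy violates exactly its intended rule. Background novel
#' nonsynonymous variants whose random transmission would satisfy the
#' segregation rule are redrawn, so the cascade's survivor set equals the
#' planted truth exactly. Identical seeds give identical bundles.
#'
#' @param config A [sim_config()].
#' @return A `family_bundle` list: `pedigree`, `variants`, `annotation`,
#'   `genes` (candidate symbols), `truth` (tibble with `variant_id`,
#'   `class`, `carrier`), and the `config`.
#' @seealso [write_family_bundle()], [paper_family_fixture()]
#' @export
simulate_family <- function(config = sim_config()) {
  cfg <- config
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  children <- paste0("child", seq_len(cfg$n_children))
  samples <- c("mother", "father", children)
  affected <- c(if (cfg$mother_affected) "mother", cfg$affected_children)
  unaffected <- setdiff(samples, affected)
  ped <- new_pedigree(tibble::tibble(
    family_id = "FAM1",
    sample_id = samples,
    father_id = c(NA, NA, rep("father", cfg$n_children)),
    mother_id = c(NA, NA, rep("mother", cfg$n_children)),
    sex = c("female", "male",
            rep(c("male", "female"), length.out = cfg$n_children)),
    affection = ifelse(samples %in% affected, "affected", "unaffected")
  ))

  n_denovo_decoy <- sum(cfg$denovo_decoys)
  n_qc_single <- sum(cfg$qc_decoys[setdiff(names(cfg$qc_decoys),
                                           "cluster3in10")])
  n_cluster_sites <- 3L * sum(cfg$qc_decoys[intersect("cluster3in10",
                                                      names(cfg$qc_decoys))])
  n_spread <- cfg$n_background_common + cfg$n_background_rare +
    cfg$n_planted_segregating + cfg$n_planted_denovo + n_denovo_decoy +
    n_qc_single
  loci <- draw_positions(n_spread)
  loci <- loci[sample.int(nrow(loci)), ]  # decouple class from genome order

  genes <- sprintf("GENE%04d", seq_len(cfg$n_candidate_genes + 40L))
  candidate_genes <- genes[seq_len(cfg$n_candidate_genes)]
  bases <- c("A", "C", "G", "T")

  rows <- list()
  ann_rows <- list()
  truth <- list()
  locus_i <- 0L
  next_locus <- function() {
    locus_i <<- locus_i + 1L
    loci[locus_i, ]
  }
  rs_counter <- 0L

  site_metrics <- function() {
    dp <- draw_total_depth(1L, cfg, min_total = 25L)
    qd <- round(stats::runif(1, 2, 20), 2)
    list(dp = dp, qd = qd, qual = round(qd * dp, 1),
         fs = round(stats::runif(1, 0, 30), 2), mq0 = 0)
  }

  add_variant <- function(locus, gt, class, carrier = NA_character_,
                          region = "exonic", exonic_function = "nonsynonymous",
                          gene = NULL, dbsnp = NA_character_,
                          kg_af = NA_real_, ad = NULL, metrics = NULL,
                          het_balance = 0.5) {
    refalt <- sample(bases, 2L)
    if (is.null(metrics)) metrics <- site_metrics()
    if (is.null(ad)) {
      totals <- draw_total_depth(length(gt), cfg)
      ad <- stats::setNames(purrr::map2(unname(gt), totals, function(g, t) {
        draw_ad(g, t, cfg$error_alt_fraction, het_balance)
      }), names(gt))
    }
    if (is.null(gene)) gene <- sample(genes, 1L)
    v <- make_variant(locus$chrom, locus$pos, refalt[1], refalt[2], gt,
                      ad = ad, qual = metrics$qual, dp = metrics$dp,
                      qd = metrics$qd, fs = metrics$fs, mq0 = metrics$mq0)
    rows[[length(rows) + 1L]] <<- v
    ann_rows[[length(ann_rows) + 1L]] <<- tibble::tibble(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      region = region,
      gene = gene,
      exonic_function = if (region %in% c("exonic", "exonic_splicing")) {
        exonic_function
      } else {
        NA_character_
      },
      aa_change = if (!is.na(exonic_function) &&
                      identical(exonic_function, "nonsynonymous") &&
                      region %in% c("exonic", "exonic_splicing")) {
        paste0(sample(LETTERS, 1), sample(50:900, 1), sample(LETTERS, 1))
      } else {
        NA_character_
      },
      dbsnp = dbsnp, kg_af = kg_af,
      sift = round(stats::runif(1), 2), polyphen2 = round(stats::runif(1), 2),
      phylop = round(stats::runif(1), 2),
      mutation_taster = round(stats::runif(1), 2),
      lrt = round(stats::runif(1), 2)
    )
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      variant_id = v$variant_id, class = class, carrier = carrier)
    invisible(v)
  }

  hom_ref_all <- stats::setNames(rep("0/0", length(samples)), samples)

  # --- common Mendelian background: dbSNP id + 1000G frequency ------------
  for (i in seq_len(cfg$n_background_common)) {
    af <- stats::runif(1, 0.05, 0.5)
    draw_parent <- function() {
      paste(sort(stats::rbinom(2, 1, af)), collapse = "/")
    }
    m_gt <- draw_parent(); f_gt <- draw_parent()
    gt <- c(stats::setNames(c(m_gt, f_gt), c("mother", "father")),
            stats::setNames(transmit(m_gt, f_gt, cfg$n_children), children))
    rs_counter <- rs_counter + 1L
    add_variant(next_locus(), gt, "background",
                region = sample(c("exonic", "exonic", "UTR3", "intronic",
                                  "UTR5", "ncRNA_exonic"), 1L),
                exonic_function = sample(c("synonymous", "nonsynonymous"), 1L),
                dbsnp = sprintf("rs9%06d", rs_counter),
                kg_af = round(af, 4))
  }

  # --- rare novel background: one carrier parent, Mendelian ----------------
  for (i in seq_len(cfg$n_background_rare)) {
    carrier_parent <- sample(c("mother", "father"), 1L)
    m_gt <- if (carrier_parent == "mother") "0/1" else "0/0"
    f_gt <- if (carrier_parent == "father") "0/1" else "0/0"
    exonic_fn <- sample(c("synonymous", "nonsynonymous"), 1L)
    for (try in 1:100) {
      kid_gt <- transmit(m_gt, f_gt, cfg$n_children)
      gt <- c(stats::setNames(c(m_gt, f_gt), c("mother", "father")),
              stats::setNames(kid_gt, children))
      # a novel nonsynonymous background variant must not mimic the planted
      # segregating class, or truth recovery would be ambiguous
      if (!(exonic_fn == "nonsynonymous" &&
            segregating_pattern(gt, affected, unaffected))) break
    }
    add_variant(next_locus(), gt, "background",
                region = "exonic", exonic_function = exonic_fn,
                gene = sample(c(candidate_genes, genes), 1L))
  }

  # --- planted segregating: affected het, unaffected hom-ref ---------------
  seg_gt <- stats::setNames(
    ifelse(samples %in% affected, "0/1", "0/0"), samples)
  for (i in seq_len(cfg$n_planted_segregating)) {
    kg_flagged <- i <= cfg$n_planted_kg_flagged
    add_variant(next_locus(), seg_gt,
                if (kg_flagged) "kg_flagged" else "segregating",
                kg_af = if (kg_flagged) round(stats::runif(1, 0.001, 0.01), 4)
                        else NA_real_)
  }

  # --- planted de novo: parents clean and deep, child het, balanced --------
  denovo_trio_ad <- function(child, mode = "pass") {
    ad <- stats::setNames(purrr::map(samples, function(s) {
      tot <- draw_total_depth(1L, cfg)
      c(tot, 0L)
    }), samples)
    child_tot <- draw_total_depth(1L, cfg)
    repeat {
      alt <- stats::rbinom(1L, child_tot, if (mode == "biased") 0.2 else 0.5)
      ref <- child_tot - alt
      bad_bias <- ref > 0.70 * child_tot
      if ((mode == "biased" && bad_bias && alt >= 1L) ||
          (mode != "biased" && !bad_bias && alt >= 1L)) break
    }
    ad[[child]] <- c(ref, alt)
    if (mode == "shallow") ad[[child]] <- c(4L, 4L)
    if (mode == "contaminated") {
      tot <- ad[["father"]][1]
      bad_alt <- max(ceiling(0.05 * tot) + 2L, 2L)
      ad[["father"]] <- c(tot - bad_alt, bad_alt)
    }
    ad
  }
  denovo_gt <- function(child) {
    gt <- hom_ref_all
    gt[child] <- "0/1"
    gt
  }
  denovo_children <- rep(children, length.out =
                           max(cfg$n_planted_denovo, 1L))
  for (i in seq_len(cfg$n_planted_denovo)) {
    ch <- denovo_children[i]
    add_variant(next_locus(), denovo_gt(ch), "denovo", carrier = ch,
                ad = denovo_trio_ad(ch, "pass"))
  }

  # --- de novo decoys: each violates exactly one rule ----------------------
  decoy_modes <- rep(names(cfg$denovo_decoys), times = cfg$denovo_decoys)
  for (mode in decoy_modes) {
    ch <- sample(children, 1L)
    ad <- switch(mode,
      shallow_trio = denovo_trio_ad(ch, "shallow"),
      parent_contamination = denovo_trio_ad(ch, "contaminated"),
      child_allele_bias = denovo_trio_ad(ch, "biased"),
      known_dbsnp = denovo_trio_ad(ch, "pass"))
    rs <- if (mode == "known_dbsnp") {
      rs_counter <- rs_counter + 1L
      sprintf("rs9%06d", rs_counter)
    } else {
      NA_character_
    }
    add_variant(next_locus(), denovo_gt(ch),
                paste0("denovo_decoy:", mode), carrier = ch, ad = ad,
                dbsnp = rs)
  }

  # --- QC decoys: each fails exactly one hard filter -----------------------
  decoy_gt <- function() {
    gt <- hom_ref_all
    gt["father"] <- "0/1"
    gt[sample(children, 1L)] <- "0/1"
    gt
  }
  qc_metric_sets <- list(
    map_ambiguity = list(dp = 100, qd = 5, qual = 500, fs = 5, mq0 = 6),
    min_depth = list(dp = 3, qd = 20, qual = 60, fs = 5, mq0 = 0),
    min_qual = list(dp = 20, qd = 2, qual = 40, fs = 5, mq0 = 0),
    min_qd = list(dp = 100, qd = 1.0, qual = 100, fs = 5, mq0 = 0),
    strand_bias = list(dp = 100, qd = 5, qual = 500, fs = 250, mq0 = 0)
  )
  for (f in names(qc_metric_sets)) {
    n_f <- if (f %in% names(cfg$qc_decoys)) cfg$qc_decoys[[f]] else 0L
    for (i in seq_len(n_f)) {
      add_variant(next_locus(), decoy_gt(), paste0("qc_decoy:", f),
                  metrics = qc_metric_sets[[f]])
    }
  }
  n_clusters <- if ("cluster3in10" %in% names(cfg$qc_decoys)) {
    cfg$qc_decoys[["cluster3in10"]]
  } else {
    0L
  }
  for (i in seq_len(n_clusters)) {
    base <- 900000L + 100L * i
    for (off in c(0L, 4L, 8L)) {
      add_variant(tibble::tibble(chrom = "22", pos = base + off), decoy_gt(),
                  "qc_decoy:cluster3in10")
    }
  }

  variants <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  annotation <- dplyr::bind_rows(ann_rows)
  annotation$variant_id <- variant_key(annotation$chrom, annotation$pos,
                                       annotation$ref, annotation$alt)
  annotation <- dplyr::relocate(
    dplyr::arrange(annotation, .data$chrom, .data$pos), "variant_id")

  structure(
    list(pedigree = ped, variants = variants, annotation = annotation,
         genes = candidate_genes, truth = dplyr::bind_rows(truth),
         config = cfg),
    class = "family_bundle"
  )
}

#' Write a family bundle to plain-text files
#'
#' Emits `data.vcf`, `family.ped`, `annotation.tsv`, `genes.txt` and (when a
#' truth table is present) `truth.tsv` into `dir`.
#'
#' @param bundle A `family_bundle` from [simulate_family()] or
#'   [paper_family_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_family_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "data.vcf"),
             ped = file.path(dir, "family.ped"),
             annotation = file.path(dir, "annotation.tsv"),
             genes = file.path(dir, "genes.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(bundle$variants, paths["vcf"])
  write_ped(bundle$pedigree, paths["ped"])
  ann <- dplyr::select(bundle$annotation, -dplyr::any_of("variant_id"))
  readr::write_tsv(ann, paths["annotation"], na = ".")
  writeLines(bundle$genes, paths["genes"])
  if (!is.null(bundle$truth)) {
    readr::write_tsv(bundle$truth, paths["truth"], na = ".")
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}
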