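# Shared builders and independent oracles for the test suite.

samples6 <- c("mother", "father", "child1", "child2", "child3", "child4")

# The worked-example pedigree: affected mother, unaffected father,
# children 1-2 affected, 3-4 unaffected.
family_ped <- function() {
  new_pedigree(tibble::tibble(
    family_id = "FAM1",
    sample_id = samples6,
    father_id = c(NA, NA, rep("father", 4)),
    mother_id = c(NA, NA, rep("mother", 4)),
    sex = c("female", "male", "male", "female", "male", "female"),
    affection = c("affected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected")
  ))
}

write_family_ped <- function(path = withr::local_tempfile(
                               fileext = ".ped",
                               .local_envir = parent.frame())) {
  write_ped(family_ped(), path)
  path
}

gt6 <- function(...) stats::setNames(c(...), samples6)

# A bare site with good metrics and no depths, genotypes per sample.
site <- function(chrom, pos, gt, ref = "A", alt = "G", ...) {
  make_variant(chrom, pos, ref, alt, gt, ...)
}

# Brute-force cluster oracle: a position is flagged iff >= k distinct
# positions on its chromosome (itself included) fall inside some window of
# span <= w - 1 containing it. Enumerates all candidate window starts.
cluster_oracle <- function(chrom, pos, k = 3, w = 10) {
  vapply(seq_along(pos), function(i) {
    on_chr <- unique(pos[chrom == chrom[i]])
    starts <- (pos[i] - w + 1L):pos[i]
    any(vapply(starts, function(s) {
      inside <- on_chr >= s & on_chr <= s + w - 1L
      pos[i] >= s && pos[i] <= s + w - 1L && sum(inside) >= k
    }, logical(1)))
  }, logical(1))
}

# Expected-counts chi-square oracle: sum (O - E)^2 / E over the 2x2 table.
chi2_oracle <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# A small annotation row in the table shape read_annotation() produces.
ann_row <- function(v, gene = "GENE1", region = "exonic",
                    exonic_function = "nonsynonymous",
                    aa_change = "A1T", dbsnp = NA_character_,
                    kg_af = NA_real_, sift = NA_real_, polyphen2 = NA_real_,
                    phylop = NA_real_, mutation_taster = NA_real_,
                    lrt = NA_real_) {
  tibble::tibble(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos, ref = v$ref,
    alt = v$alt, region = region, gene = gene,
    exonic_function = exonic_function, aa_change = aa_change, dbsnp = dbsnp,
    kg_af = kg_af, sift = sift, polyphen2 = polyphen2, phylop = phylop,
    mutation_taster = mutation_taster, lrt = lrt
  )
}

# Run the full in-memory pipeline on a bundle; returns the stage outputs.
run_bundle <- function(bundle, ...) {
  qc <- qc_filter(bundle$variants)
  passed <- qc_passed(qc)
  annotated <- join_annotation(passed, bundle$annotation, quiet = TRUE)
  cascade <- run_cascade(annotated, bundle$pedigree, ...)
  candidates <- denovo_qc(denovo_candidates(annotated, bundle$pedigree,
                                            quiet = TRUE))
  dn <- denovo_finalize(candidates, annotated, bundle$pedigree)
  list(qc = qc, annotated = annotated, cascade = cascade,
       denovo_candidates = candidates, denovo = dn)
}
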