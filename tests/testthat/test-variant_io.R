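vcf_lines <- function(body, samples = samples6) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body)
}

write_vcf_text <- function(body) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(vcf_lines(body), path)
  path
}

test_that("read_vcf parses sites, metrics and per-sample depths", {
  body <- paste(c("1", "144930802", ".", "A", "C", "900", ".",
                  "DP=300;QD=3.0;FS=1.2;MQ0=0", "GT:AD",
                  "0/1:75,70", "0/0:150,0", "0/1:80,61", "0/1:70,72",
                  "0/0:140,1", "0/0:155,0"), collapse = "\t")
  v <- read_vcf(write_vcf_text(body), pedigree = family_ped())
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 144930802L)
  expect_equal(v$dp, 300)
  expect_equal(v$qd, 3)
  expect_equal(v$fs, 1.2)
  expect_equal(v$mq0, 0)
  g <- v$genotypes[[1]]
  expect_equal(g$sample_id, samples6)
  expect_equal(g$alt_depth[g$sample_id == "mother"], 70L)
  expect_equal(g$a1[g$sample_id == "father"], 0L)
})

test_that("read_vcf handles absent AD and INFO keys as missing, not errors", {
  body <- paste(c("2", "1000", ".", "G", "T", "500", ".", "DP=100", "GT",
                  rep("0/1", 6)), collapse = "\t")
  v <- read_vcf(write_vcf_text(body))
  g <- v$genotypes[[1]]
  expect_true(all(is.na(g$ref_depth)))
  expect_true(all(is.na(g$alt_depth)))
  expect_true(all(g$called))
  expect_true(is.na(v$qd))
  expect_true(is.na(v$mq0))
})

test_that("multi-allelic records decompose into per-alternate rows", {
  body <- paste(c("3", "500", ".", "A", "C,T", "800", ".", "DP=200", "GT:AD",
                  "1/2:10,20,30", "0/1:50,40,0", "0/0:90,0,1", "0/2:60,0,33",
                  "2/2:1,0,99", "0/0:80,0,0"), collapse = "\t")
  v <- read_vcf(write_vcf_text(body))
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("C", "T"))
  gC <- v$genotypes[[which(v$alt == "C")]]
  gT <- v$genotypes[[which(v$alt == "T")]]
  # mother is 1/2: one copy of each alternate after remapping
  expect_equal(gC$a1[1] + gC$a2[1], 1L)
  expect_equal(gT$a1[1] + gT$a2[1], 1L)
  # focal alternate depth follows the allele
  expect_equal(gC$alt_depth[1], 20L)
  expect_equal(gT$alt_depth[1], 30L)
  # child3 is 2/2: hom-alt for T, hom-ref for C
  expect_equal(gT$a1[5] + gT$a2[5], 2L)
  expect_equal(gC$a1[5] + gC$a2[5], 0L)
})

test_that("invalid GT indices and absent pedigree members are errors", {
  body <- paste(c("1", "10", ".", "A", "G", "50", ".", "DP=10", "GT",
                  "0/2", rep("0/0", 5)), collapse = "\t")
  expect_error(read_vcf(write_vcf_text(body)), "exceeds alternate")

  body2 <- paste(c("1", "10", ".", "A", "G", "50", ".", "DP=10", "GT",
                   rep("0/0", 5)), collapse = "\t")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(body2, samples = samples6[-1]), path)
  expect_error(read_vcf(path, pedigree = family_ped()), "mother")
})

test_that("write-then-read VCF round trip preserves everything", {
  sim <- simulate_family(sim_config(seed = 11, n_background_common = 30,
                                    n_background_rare = 10))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$variants, path)
  back <- read_vcf(path, pedigree = sim$pedigree)
  expect_equal(as.data.frame(back), as.data.frame(sim$variants))
})

test_that("read_annotation parses scores and enforces the contract", {
  hdr <- paste(c("chrom", "pos", "ref", "alt", "region", "gene",
                 "exonic_function", "aa_change", "dbsnp", "kg_af", "sift",
                 "polyphen2", "phylop", "mutation_taster", "lrt"),
               collapse = "\t")
  cblb <- paste(c("3", "105438937", "T", "G", "exonic", "CBLB",
                  "nonsynonymous", "D454A", ".", ".", "0.37", "0.78", "0.99",
                  "0.99", "0.99"), collapse = "\t")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, cblb), path)
  ann <- read_annotation(path)
  expect_equal(ann$sift, 0.37)
  expect_equal(ann$lrt, 0.99)
  expect_true(is.na(ann$dbsnp))
  expect_true(is.na(ann$kg_af))

  writeLines(c(hdr, cblb, cblb), path)
  expect_error(read_annotation(path), "duplicate")

  writeLines(c(hdr, sub("\\t\\.\\t\\.", "\t.\t1.5", cblb)), path)
  expect_error(read_annotation(path), "kg_af")

  writeLines(c(sub("\tlrt", "", hdr),
               sub("\t0\\.99$", "", cblb)), path)
  expect_error(read_annotation(path), "lrt")
})

test_that("join_annotation marks unannotated sites and keeps every row", {
  v <- dplyr::bind_rows(
    site("1", 100, gt6("0/1", "0/0", "0/1", "0/1", "0/0", "0/0")),
    site("1", 200, gt6("0/0", "0/1", "0/0", "0/0", "0/1", "0/0"))
  )
  ann <- ann_row(v[1, ])
  joined <- join_annotation(v, ann, quiet = TRUE)
  expect_equal(nrow(joined), 2L)
  expect_equal(joined$annotated, c(TRUE, FALSE))
  expect_message(join_annotation(v, ann), "1 annotated, 1 unannotated")
})

test_that("gene lists are deduplicated and empty lists rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# asthma candidates", "ORMDL3", "IL13", "ORMDL3", "",
               "PDE4D # replicated"), path)
  expect_setequal(read_gene_list(path), c("ORMDL3", "IL13", "PDE4D"))

  writeLines(c("# nothing", ""), path)
  expect_error(read_gene_list(path), "empty")
})
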