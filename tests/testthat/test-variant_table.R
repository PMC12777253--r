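freq_kb <- function() {
  knowledge_base(
    list(finding_def("f1", background_rate = 0.01)),
    list(
      disease_def("rec_dx", incidence = 1 / 40000,
                  gene_links = list(gene_link("RECG", "biallelic")),
                  associations = list(finding_association("f1", 0.5))),
      disease_def("dom_dx", incidence = 1 / 10000,
                  gene_links = list(gene_link("DOMG", "monoallelic")),
                  associations = list(finding_association("f1", 0.5)))
    ))
}

test_that("frequency filter implements the Hardy-Weinberg threshold", {
  kb <- freq_kb()
  vt <- variant_table(
    chrom = c("1", "1", "2", "2", "3"), pos = 1:5,
    gene_id = c("RECG", "RECG", "DOMG", "DOMG", "UNLINKED"),
    consequence = "lof",
    population_af = c(0.02, 0.004, 1e-5, 2e-4, 0.9),
    gt_proband = 1)
  kept <- filter_by_frequency(vt, kb)
  # recessive incidence 1/40000 -> expected allele frequency sqrt(I) = 0.005
  expect_false(any(kept$population_af == 0.02 & kept$gene_id == "RECG"))
  expect_true(any(kept$population_af == 0.004 & kept$gene_id == "RECG"))
  # dominant incidence 1e-4: af 1e-5 retained, af 2e-4 filtered
  expect_true(any(kept$gene_id == "DOMG" & kept$population_af == 1e-5))
  expect_false(any(kept$gene_id == "DOMG" & kept$population_af == 2e-4))
  # unlinked genes are never filtered
  expect_true(any(kept$gene_id == "UNLINKED"))
  # missing population_af is retained
  vt_na <- variant_table("1", 9, gene_id = "RECG", consequence = "lof",
                         population_af = NA, gt_proband = 1)
  expect_equal(nrow(filter_by_frequency(vt_na, kb)), 1)
})

test_that("filtering is monotone in the multiplier", {
  kb <- freq_kb()
  set.seed(11)
  vt <- variant_table(
    chrom = "1", pos = 1:60,
    gene_id = sample(c("RECG", "DOMG", "OTHER"), 60, replace = TRUE),
    consequence = "missense_damaging",
    population_af = 10 ^ runif(60, -6, -1), gt_proband = 1)
  mults <- c(0.1, 0.5, 1, 2, 10, 100)
  kept <- lapply(mults, function(m) {
    k <- filter_by_frequency(vt, kb, multiplier = m)
    paste(k$chrom, k$pos)
  })
  for (i in seq_len(length(mults) - 1))
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("severity maps consequences to the 0-5 scale with aggregation", {
  mono_lof <- make_gz("G", "monoallelic")
  mono_lof$supporting_variants <- variant_table(
    "1", 1, gene_id = "G", consequence = "lof", gt_proband = 1)
  expect_equal(severity_of(mono_lof), 5)

  # biallelic compound het: mean of top two allele scores
  bi <- make_gz("G", "biallelic")
  bi$supporting_variants <- variant_table(
    "1", 1:2, gene_id = "G",
    consequence = c("lof", "missense_damaging"), gt_proband = c(1, 1))
  expect_equal(severity_of(bi), 4)

  # homozygous lof counts its allele score twice
  bi_hom <- make_gz("G", "biallelic")
  bi_hom$supporting_variants <- variant_table(
    "1", 1, gene_id = "G", consequence = "lof", gt_proband = 2)
  expect_equal(severity_of(bi_hom), 5)

  # known_pathogenic forces 5 whatever the consequence
  kp <- make_gz("G", "monoallelic")
  kp$supporting_variants <- variant_table(
    "1", 1, gene_id = "G", consequence = "missense_benign",
    known_pathogenic = TRUE, gt_proband = 1)
  expect_equal(severity_of(kp), 5)

  empty <- make_gz("G", "monoallelic")
  empty$supporting_variants <- mono_lof$supporting_variants[0, ]
  expect_error(severity_of(empty), "empty")
})

test_that("VCF plus annotation table reads into dosage records", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "trio.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "proband", "mother", "father", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", "PASS", ".", "GT:DP",
          "0/1:40", "0/0:35", "0/0:38", sep = "\t"),
    paste("2", "200", ".", "G", "C,A", ".", "PASS", ".", "GT:DP",
          "1|2:22", "0/1:30", "0/2:31", sep = "\t"),
    paste("X", "300", ".", "T", "G", ".", "PASS", ".", "GT:DP",
          "1:18", "0/1:25", "0:26", sep = "\t"),
    paste("3", "400", ".", "C", "T", ".", "PASS", ".", "GT:DP",
          "0/1:10", "0/0:12", "0/0:12", sep = "\t")), vcf)
  ann <- file.path(dir, "ann.tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tgene\tconsequence\tpopulation_af\tknown_pathogenic",
    "1\t100\tA\tT\tGA\tlof\t\t0",
    "2\t200\tG\tC\tGB\tmissense_damaging\t1e-4\t0",
    "2\t200\tG\tA\tGB\tmissense_benign\t\t1",
    "X\t300\tT\tG\tGX\tlof\t\t0"), ann)
  ped <- pedigree("male")
  expect_message(vt <- read_variant_table(vcf, ann, ped), "1 variant")
  expect_equal(nrow(vt), 4)  # multi-allelic expanded, chr3 row dropped
  expect_equal(vt$gt_proband[vt$chrom == "1"], 1)
  expect_equal(vt$gt_mother[vt$chrom == "1"], 0)
  # each alt allele of the multi-allelic site counted separately
  expect_equal(vt$gt_proband[vt$alt == "C" & vt$chrom == "2"], 1)
  expect_equal(vt$gt_father[vt$alt == "A" & vt$chrom == "2"], 1)
  expect_true(vt$known_pathogenic[vt$alt == "A" & vt$chrom == "2"])
  # hemizygous male X "1"
  expect_equal(vt$gt_proband[vt$chrom == "X"], 1)
  expect_equal(vt$population_af[vt$alt == "C" & vt$chrom == "2"], 1e-4)

  # pedigree declaring a parent the VCF lacks is an error
  ped2 <- pedigree("male", samples = c(proband = "proband",
                                       mother = "mother",
                                       father = "papa"))
  expect_error(read_variant_table(vcf, ann, ped2), "pedigree error")
  expect_error(read_variant_table("nope.vcf", ann, ped), "not found")
})
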