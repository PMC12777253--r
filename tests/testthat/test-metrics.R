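test_that("total variation distance behaves on the canonical examples", {
  mk <- function(p) {
    structure(list(entries = data.frame(disease_id = c("A", "B"),
                                        posterior = p)),
              class = "differential_diagnosis")
  }
  expect_equal(differential_distance(mk(c(0.9, 0.1)), mk(c(0.9, 0.1))), 0)
  expect_equal(differential_distance(mk(c(1, 0)), mk(c(0, 1))), 1)
  expect_equal(differential_distance(mk(c(0.9, 0.1)), mk(c(0.5, 0.5))), 0.4)
  bad <- structure(list(entries = data.frame(disease_id = c("A", "C"),
                                             posterior = c(1, 0))),
                   class = "differential_diagnosis")
  expect_error(differential_distance(mk(c(1, 0)), bad), "disease sets")
})

test_that("an uninformative finding has zero pertinence and the only
           informative item takes 100", {
  kb <- knowledge_base(
    list(finding_def("flat", background_rate = 0.3),
         finding_def("other", background_rate = 0.01)),
    list(disease_def("A", incidence = 1e-5,
                     gene_links = list(gene_link("G1", "monoallelic")),
                     associations = list(finding_association("flat", 0.3))),
         disease_def("B", incidence = 1e-5,
                     associations = list(finding_association("flat", 0.3)))))
  phen <- patient_phenotype("p", 5,
                            list(patient_finding("flat", "present", 1)))
  zyg <- list(make_gz("G1", "monoallelic", 5))
  pr <- pertinence_ranking(kb, phen, zyg)
  expect_equal(pr$percent[pr$item_id == "G1"], 100)
  expect_equal(pr$raw_distance[pr$item_id == "flat"], 0)
  expect_equal(pr$percent[pr$item_id == "flat"], 0)
})

test_that("pertinence matches the brute-force leave-one-out oracle", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    got <- pertinence_ranking(inst$kb, inst$phenotype, inst$zygosities)
    want <- oracle_pertinence(inst$kb, inst$phenotype, inst$zygosities)
    expect_equal(got$item_id, want$item_id)
    expect_equal(got$raw_distance, want$raw_distance, tolerance = 1e-12)
    expect_equal(got$percent, want$percent, tolerance = 1e-10)
    expect_true(all(got$raw_distance >= 0 & got$raw_distance <= 1))
    if (max(got$raw_distance) > 0)
      expect_equal(max(got$percent), 100)
  }
})

test_that("usefulness matches the outcome-enumeration oracle", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    genes <- unique(kb_gene_table_pub(inst$kb)$gene_id)
    ascertained_g <- vapply(inst$zygosities, `[[`, "", "gene_id")
    cand <- c(setdiff(genes, ascertained_g),
              setdiff(names(inst$kb$findings),
                      names(inst$phenotype$findings))[1:3])
    got <- usefulness_ranking(inst$kb, inst$phenotype, inst$zygosities,
                              cand)
    want <- oracle_usefulness(inst$kb, inst$phenotype, inst$zygosities,
                              cand)
    expect_equal(got$test_id, want$test_id)
    expect_equal(got$expected_change, want$expected_change,
                 tolerance = 1e-12)
    expect_true(all(got$expected_change >= 0))
  }
})

test_that("a candidate that cannot move the differential scores zero", {
  kb <- knowledge_base(
    list(finding_def("flat", background_rate = 0.3),
         finding_def("seen", background_rate = 0.01)),
    list(disease_def("A", incidence = 1e-5,
                     associations = list(
                       finding_association("flat", 0.3),
                       finding_association("seen", 0.9))),
         disease_def("B", incidence = 1e-5,
                     associations = list(finding_association("flat", 0.3)))))
  phen <- patient_phenotype("p", 5,
                            list(patient_finding("seen", "present", 1)))
  u <- usefulness_ranking(kb, phen, list(), "flat")
  expect_equal(u$expected_change, 0)
})

test_that("already-ascertained candidates are skipped with a message", {
  inst <- random_instance(7)
  fid <- names(inst$phenotype$findings)[1]
  genes <- setdiff(unique(kb_gene_table_pub(inst$kb)$gene_id),
                   vapply(inst$zygosities, `[[`, "", "gene_id"))
  expect_message(
    u <- usefulness_ranking(inst$kb, inst$phenotype, inst$zygosities,
                            c(fid, genes[1])),
    "skipping")
  expect_false(fid %in% u$test_id)
  expect_error(
    usefulness_ranking(inst$kb, inst$phenotype, inst$zygosities, "nope"),
    "unknown candidate")
})

test_that("gene-test usefulness rises with the posterior of its disease", {
  kb <- tiny_kb()
  zyg <- list()
  # scale support for myopathy_rec (GENEB) upward via its hallmark finding
  phen_weak <- patient_phenotype("p", 5,
                                 list(patient_finding("ataxia", "present", 1)))
  phen_strong <- patient_phenotype("p", 5, list(
    patient_finding("high_ck", "present", 1),
    patient_finding("hypotonia", "present", 1)))
  u_weak <- usefulness_ranking(kb, phen_weak, zyg, "GENEB")
  u_strong <- usefulness_ranking(kb, phen_strong, zyg, "GENEB")
  expect_gt(u_strong$expected_change, u_weak$expected_change)
})

test_that("contradicting negatives sink the zygosity they disfavor", {
  kb <- tiny_kb()
  zyg <- list(make_gz("GENEA", "monoallelic", 5),
              make_gz("GENEB", "biallelic", 5))
  # phenotype initially supports the recessive myopathy (GENEB's disease)
  phen <- patient_phenotype("p", 6, list(
    patient_finding("high_ck", "present", 2),
    patient_finding("cardiomyopathy", "present", 3)))
  before <- pertinence_ranking(kb, phen, zyg)
  expect_equal(before$item_id[before$item_type == "zygosity"][1], "GENEB")
  # chart review overturns both supporting findings (the MRI-style move)
  phen2 <- merge_correlation_findings(phen, list(
    patient_finding("high_ck", "absent"),
    patient_finding("cardiomyopathy", "absent"),
    patient_finding("hypotonia", "absent")))
  after <- pertinence_ranking(kb, phen2, zyg)
  pct <- function(pr, id) pr$percent[pr$item_id == id]
  expect_lt(pct(after, "GENEB"), pct(before, "GENEB"))
  expect_equal(after$item_id[after$item_type == "zygosity"][1], "GENEA")
})

test_that("rankings are deterministic and independent of input order", {
  inst <- random_instance(11)
  set.seed(2)
  phen_perm <- patient_phenotype(
    inst$phenotype$patient_id, inst$phenotype$current_age,
    sample(unname(inst$phenotype$findings)))
  zyg_perm <- sample(inst$zygosities)
  a <- pertinence_ranking(inst$kb, inst$phenotype, inst$zygosities)
  b <- pertinence_ranking(inst$kb, phen_perm, zyg_perm)
  expect_equal(a, b)
})
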