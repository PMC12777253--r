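# Shared fixtures: a tiny hand-built knowledge base, quick constructors for
# gene zygosities, and a randomized small-instance generator used by the
# oracle-equivalence tests.

tiny_kb <- function() {
  findings <- list(
    finding_def("seizures", background_rate = 0.02),
    finding_def("hypotonia", background_rate = 0.03),
    finding_def("cardiomyopathy", background_rate = 0.01, category = "imaging"),
    finding_def("high_ck", background_rate = 0.02, category = "lab"),
    finding_def("ataxia", background_rate = 0.01),
    finding_def("deafness", background_rate = 0.01)
  )
  diseases <- list(
    disease_def("epileptic_enc", incidence = 1e-5,
                gene_links = list(gene_link("GENEA", "monoallelic")),
                associations = list(
                  finding_association("seizures", 0.9, c(0, 3)),
                  finding_association("hypotonia", 0.5))),
    disease_def("myopathy_rec", incidence = 2.5e-5,
                gene_links = list(gene_link("GENEB", "biallelic")),
                associations = list(
                  finding_association("high_ck", 0.95),
                  finding_association("hypotonia", 0.7),
                  finding_association("cardiomyopathy", 0.4))),
    disease_def("nongenetic_dx", incidence = 1e-4,
                associations = list(
                  finding_association("ataxia", 0.8),
                  finding_association("deafness", 0.3)))
  )
  knowledge_base(findings, diseases, version_tag = "tiny-1")
}

# lightweight gene_zygosity for engine-level tests (no variant provenance)
make_gz <- function(gene_id, zygosity_class, severity = 5,
                    de_novo = "yes", flags = character()) {
  structure(
    list(gene_id = gene_id, zygosity_class = zygosity_class,
         de_novo = de_novo, severity = severity,
         supporting_variants = NULL, consistency_flags = flags),
    class = "gene_zygosity"
  )
}

# randomized small instance: 10-disease 15-finding KB, a phenotype and up to
# 5 zygosities (classes may or may not match the gene's link)
random_instance <- function(seed, n_diseases = 10, n_findings = 15,
                            max_zyg = 5) {
  kb <- random_knowledge_base(n_diseases, n_findings, seed = seed)
  set.seed(seed + 500000)
  fids <- sample(names(kb$findings), sample(3:7, 1))
  findings <- lapply(fids, function(fid) {
    if (stats::runif(1) < 0.6)
      patient_finding(fid, "present",
                      onset_age = round(stats::runif(1, 0, 12), 2))
    else patient_finding(fid, "absent")
  })
  phen <- patient_phenotype("px", 20, findings)
  genes <- unique(kb_gene_table_pub(kb)$gene_id)
  nz <- sample(0:max_zyg, 1)
  zyg <- list()
  if (nz > 0 && length(genes) > 0) {
    for (g in sample(genes, min(nz, length(genes)))) {
      zyg[[length(zyg) + 1L]] <- make_gz(
        g, sample(c("monoallelic", "biallelic", "x_linked"), 1),
        severity = round(stats::runif(1, 0.5, 5), 2),
        de_novo = sample(c("yes", "no", "unknown"), 1))
    }
  }
  list(kb = kb, phenotype = phen, zygosities = zyg)
}

# access to the internal gene-link table without triple-colon noise in tests
kb_gene_table_pub <- function(kb) reanalyzr:::kb_gene_table(kb)
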