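#' Run the full reanalysis pipeline on one case
#'
#' Loads the knowledge base, phenotype, pedigree and annotated variant
#' table; applies the incidence-based frequency filter; calls gene
#' zygosities; computes the differential diagnosis; ranks all ascertained
#' evidence by leave-one-out pertinence; and ranks candidate further gene
#' tests by usefulness -- including genes with no variants in the table.
#'
#' @param kb_path Knowledge-base JSON file.
#' @param phenotype_path Findings TSV.
#' @param vcf_path Multi-sample VCF.
#' @param annotation_path Annotation TSV.
#' @param pedigree_path Pedigree JSON.
#' @param config A [reanalysis_config()].
#' @param top_n Number of differential entries retained in the report
#'   (the full differential is used internally). Default 10.
#' @param candidates Candidate test ids for the usefulness ranking;
#'   defaults to every knowledge-base-linked gene not ascertained from the
#'   variant table.
#' @return A `reanalysis_report`.
#' @export
reanalyze <- function(kb_path, phenotype_path, vcf_path, annotation_path,
                      pedigree_path, config = reanalysis_config(),
                      top_n = 10, candidates = NULL) {
  kb <- load_knowledge_base(kb_path)
  phen <- read_phenotype(phenotype_path, kb)
  ped <- read_pedigree(pedigree_path)
  vt <- read_variant_table(vcf_path, annotation_path, ped)
  n_before <- nrow(vt)
  vt <- filter_by_frequency(vt, kb, config$af_multiplier)
  if (n_before > nrow(vt))
    message(n_before - nrow(vt),
            " variant(s) removed by the frequency filter")
  zyg <- call_zygosities(vt, ped, config)
  diff <- compute_differential(kb, phen, zyg, config)
  pert <- pertinence_ranking(kb, phen, zyg, config)

  zyg_by_gene <- stats::setNames(zyg, vapply(zyg, `[[`, "", "gene_id"))
  zr <- pert[pert$item_type == "zygosity", , drop = FALSE]
  zygosity_ranking <- data.frame(
    gene_id = zr$item_id,
    zygosity_class = vapply(zyg_by_gene[zr$item_id], `[[`, "",
                            "zygosity_class"),
    de_novo = vapply(zyg_by_gene[zr$item_id], `[[`, "", "de_novo"),
    severity = vapply(zyg_by_gene[zr$item_id], `[[`, 0, "severity"),
    raw_distance = zr$raw_distance,
    pertinence = zr$percent,
    flags = vapply(zyg_by_gene[zr$item_id], function(z)
      paste(z$consistency_flags, collapse = ","), "")
  )
  rownames(zygosity_ranking) <- NULL

  if (is.null(candidates)) {
    candidates <- setdiff(unique(kb_gene_table(kb)$gene_id),
                          names(zyg_by_gene))
  }
  add_tests <- if (length(candidates))
    usefulness_ranking(kb, phen, zyg, candidates, config)
  else data.frame(test_id = character(), test_type = character(),
                  expected_change = numeric(),
                  top_disease_supported = character())

  structure(
    list(case_id = phen$patient_id,
         kb_version_tag = kb$version_tag,
         differential = utils::head(diff$entries, top_n),
         zygosity_ranking = zygosity_ranking,
         pertinence = pert,
         add_tests = add_tests,
         provenance = list(
           inputs = vapply(c(kb = kb_path, phenotype = phenotype_path,
                             vcf = vcf_path, annotations = annotation_path,
                             pedigree = pedigree_path),
                           function(p) unname(tools::md5sum(p)), ""),
           config = unclass(config)[setdiff(names(config),
                                            "severity_table")],
           n_variants_analyzed = nrow(vt),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "reanalysis_report"
  )
}

#' Re-run a case with clinical-correlation findings and diff the rankings
#'
#' Clinical correlation adds chart-review findings (typically pertinent
#' negatives suggested by the usefulness ranking) after the variant table
#' has been imported. Returns the reports before and after the additions
#' plus the per-zygosity change in pertinence percent.
#'
#' @inheritParams reanalyze
#' @param additions_path Findings TSV of correlation findings; entries
#'   override the base phenotype on conflict.
#' @return A list with `before`, `after` (both `reanalysis_report`) and
#'   `pertinence_diff` (data frame `gene_id`, `before`, `after`, `delta`).
#' @export
rerank_with_correlation <- function(kb_path, phenotype_path, vcf_path,
                                    annotation_path, pedigree_path,
                                    additions_path,
                                    config = reanalysis_config(),
                                    top_n = 10) {
  before <- reanalyze(kb_path, phenotype_path, vcf_path, annotation_path,
                      pedigree_path, config, top_n)
  kb <- load_knowledge_base(kb_path)
  base <- read_phenotype(phenotype_path, kb)
  adds <- read_phenotype(additions_path, kb)
  merged <- merge_correlation_findings(base, unname(adds$findings))
  merged_path <- tempfile(fileext = ".tsv")
  on.exit(unlink(merged_path))
  write_phenotype(merged, merged_path)
  after <- reanalyze(kb_path, merged_path, vcf_path, annotation_path,
                     pedigree_path, config, top_n)
  after$case_id <- before$case_id
  genes <- union(before$zygosity_ranking$gene_id,
                 after$zygosity_ranking$gene_id)
  pb <- stats::setNames(before$zygosity_ranking$pertinence,
                        before$zygosity_ranking$gene_id)
  pa <- stats::setNames(after$zygosity_ranking$pertinence,
                        after$zygosity_ranking$gene_id)
  diff <- data.frame(gene_id = genes,
                     before = unname(pb[genes]),
                     after = unname(pa[genes]))
  diff$delta <- diff$after - diff$before
  diff <- diff[order(-abs(diff$delta), diff$gene_id), , drop = FALSE]
  rownames(diff) <- NULL
  list(before = before, after = after, pertinence_diff = diff)
}

#' Write a reanalysis report as a structured JSON document
#'
#' @param report A `reanalysis_report`.
#' @param path Output path.
#' @param include_timestamp Write the timestamp field (set `FALSE` for
#'   byte-reproducible output). Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_timestamp = TRUE) {
  doc <- unclass(report)
  if (!include_timestamp) doc$provenance$timestamp <- NULL
  doc$provenance$inputs <- as.list(doc$provenance$inputs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a structured reanalysis report
#'
#' @param path Path written by [write_report()].
#' @return A `reanalysis_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("differential", "zygosity_ranking", "pertinence",
              "add_tests"))
    doc[[f]] <- as.data.frame(doc[[f]])
  doc$provenance$inputs <- unlist(doc$provenance$inputs)
  structure(doc, class = "reanalysis_report")
}

bar <- function(pct, width = 20) {
  n <- round(width * pct / 100)
  paste0(strrep("#", n), strrep(".", width - n))
}

#' @export
print.reanalysis_report <- function(x, ...) {
  cat("Reanalysis report -- case", x$case_id,
      "(KB", paste0(x$kb_version_tag, ")"), "\n\n")
  cat("Differential diagnosis (top", nrow(x$differential), "):\n")
  for (i in seq_len(nrow(x$differential)))
    cat(sprintf("  %2d. %-22s %8.4f%%\n", i, x$differential$disease_id[i],
                100 * x$differential$posterior[i]))
  cat("\nGene zygosities ranked by pertinence (not severity):\n")
  z <- x$zygosity_ranking
  for (i in seq_len(min(15, nrow(z))))
    cat(sprintf("  %2d. %-14s %-11s sev %.1f  de novo: %-7s %s %5.1f%%%s\n",
                i, z$gene_id[i], z$zygosity_class[i], z$severity[i],
                z$de_novo[i], bar(z$pertinence[i]), z$pertinence[i],
                if (nzchar(z$flags[i])) paste0("  [", z$flags[i], "]")
                else ""))
  if (nrow(x$add_tests)) {
    cat("\nMost useful further tests:\n")
    a <- utils::head(x$add_tests, 5)
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %2d. %-14s (%s)  usefulness %.3g  supports %s\n",
                  i, a$test_id[i], a$test_type[i], a$expected_change[i],
                  a$top_disease_supported[i]))
  }
  invisible(x)
}
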