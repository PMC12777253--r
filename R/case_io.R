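#' Write a pedigree description to JSON
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  jsonlite::write_json(
    list(proband_sex = ped$proband_sex,
         mother_present = ped$mother_present,
         father_present = ped$father_present,
         affected_roles = as.list(ped$affected_roles),
         samples = as.list(ped$samples)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a pedigree description from JSON
#'
#' @param path Path to a pedigree JSON file.
#' @return A `pedigree` object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path))
    stop("pedigree file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pedigree(doc$proband_sex, isTRUE(doc$mother_present),
           isTRUE(doc$father_present),
           affected_roles = unlist(doc$affected_roles),
           samples = unlist(doc$samples))
}

dosage_to_gt <- function(dos, hemi = FALSE) {
  if (length(hemi) == 1L) hemi <- rep(hemi, length(dos))
  mapply(function(d, h) {
    if (is.na(d)) "./."
    else if (h && d >= 1) "1"
    else if (d == 0) "0/0"
    else if (d == 1) "0/1"
    else "1/1"
  }, dos, hemi, USE.NAMES = FALSE)
}

# minimal VCFv4.2 writer for simulator output (GT:DP per role sample)
write_trio_vcf <- function(vt, ped, path) {
  roles <- c("proband",
             if (ped$mother_present) "mother",
             if (ped$father_present) "father")
  samples <- unname(ped$samples[roles])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(vt) > 0) {
    ord <- order(vt$chrom, vt$pos)
    vt <- vt[ord, , drop = FALSE]
    hemi <- is_chr_x(vt$chrom) & ped$proband_sex == "male"
    cols <- lapply(roles, function(r) {
      gt <- dosage_to_gt(vt[[paste0("gt_", r)]],
                         hemi = if (r == "proband") hemi else FALSE)
      dp <- vt[[paste0("dp_", r)]]
      paste0(gt, ":", ifelse(is.na(dp), ".", as.character(dp)))
    })
    writeLines(do.call(paste, c(
      list(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".",
           "GT:DP"), cols, list(sep = "\t"))), con)
  }
  invisible(path)
}

write_annotations <- function(vt, path) {
  ann <- data.frame(chrom = vt$chrom, pos = vt$pos, ref = vt$ref,
                    alt = vt$alt, gene = vt$gene_id,
                    consequence = vt$consequence,
                    population_af = ifelse(is.na(vt$population_af), "",
                                           sprintf("%.17g",
                                                   vt$population_af)),
                    known_pathogenic = ifelse(vt$known_pathogenic, "1", "0"))
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic case to disk in the pipeline's input formats
#'
#' Emits exactly the files [reanalyze()] consumes -- trio VCF, annotation
#' TSV, findings TSV, pedigree JSON -- plus a ground-truth JSON with the
#' simulated disease and causal gene zygosity.
#'
#' @param case A `synthetic_case`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the five file paths.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, paste0(case$case_id, ".vcf")),
    annotations = file.path(dir, paste0(case$case_id, ".annotations.tsv")),
    findings = file.path(dir, paste0(case$case_id, ".findings.tsv")),
    pedigree = file.path(dir, paste0(case$case_id, ".pedigree.json")),
    truth = file.path(dir, paste0(case$case_id, ".truth.json"))
  )
  write_trio_vcf(case$variant_table, case$pedigree, paths[["vcf"]])
  write_annotations(case$variant_table, paths[["annotations"]])
  write_phenotype(case$phenotype, paths[["findings"]])
  write_pedigree(case$pedigree, paths[["pedigree"]])
  jsonlite::write_json(
    list(case_id = case$case_id,
         true_disease_id = case$true_disease_id,
         true_gene_zygosity = case$true_gene_zygosity),
    paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  paths
}
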