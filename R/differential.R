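#' Likelihood of a patient finding under a disease
#'
#' With a curated association of frequency `f`: a present finding
#' contributes `f` times an onset weight (1 inside the association's onset
#' window or when no window is curated, `epsilon_onset` outside); an absent
#' finding contributes `1 - f`. Without an association the finding is scored
#' at its population background rate: `background_rate` when present,
#' `1 - background_rate` when absent.
#'
#' @param disease A `disease_def`.
#' @param pf A [patient_finding()].
#' @param kb The `knowledge_base` (supplies background rates).
#' @param config A [reanalysis_config()].
#' @return A probability.
#' @export
finding_likelihood <- function(disease, pf, kb,
                               config = reanalysis_config()) {
  assoc <- NULL
  for (a in disease$associations)
    if (a$finding_id == pf$finding_id) { assoc <- a; break }
  if (is.null(assoc)) {
    bg <- kb$findings[[pf$finding_id]]$background_rate
    return(if (pf$state == "present") bg else 1 - bg)
  }
  if (pf$state == "absent") return(1 - assoc$frequency)
  w <- 1
  if (!is.null(assoc$onset_window) && !is.null(pf$onset_age) &&
      (pf$onset_age < assoc$onset_window[1] ||
       pf$onset_age > assoc$onset_window[2]))
    w <- config$epsilon_onset
  assoc$frequency * w
}

#' Likelihood of an ascertained gene zygosity under a disease
#'
#' If the disease has a gene link matching both the gene and the zygosity
#' class (monoallelic/biallelic must match exactly; x_linked matches
#' x_linked), the likelihood is the calibrated value
#' `lambda_min + (lambda_max - lambda_min) * (severity / 5) * penetrance`.
#' Otherwise the zygosity is an incidental damaged gene under that disease
#' and the likelihood is the false-positive rate `phi`.
#'
#' @param disease A `disease_def`.
#' @param gz A `gene_zygosity`.
#' @param config A [reanalysis_config()].
#' @return A probability.
#' @export
zygosity_likelihood <- function(disease, gz,
                                config = reanalysis_config()) {
  for (gl in disease$gene_links) {
    if (gl$gene_id == gz$gene_id && gl$inheritance == gz$zygosity_class) {
      return(config$lambda_min +
               (config$lambda_max - config$lambda_min) *
               (gz$severity / 5) * gl$penetrance)
    }
  }
  config$phi
}

# log-likelihood matrix: diseases x ascertained items. Column names are
# "f:<finding_id>" for patient findings and "z:<gene_id>" for zygosities.
# The naive-Bayes log posterior is log incidence + row sums.
loglik_matrix <- function(kb, phenotype, zygosities,
                          config = reanalysis_config()) {
  diseases <- kb$diseases
  nf <- length(phenotype$findings)
  nz <- length(zygosities)
  m <- matrix(0, nrow = length(diseases), ncol = nf + nz,
              dimnames = list(
                names(diseases),
                c(if (nf) paste0("f:", vapply(phenotype$findings, `[[`, "",
                                              "finding_id")),
                  if (nz) paste0("z:", vapply(zygosities, `[[`, "",
                                              "gene_id")))))
  for (i in seq_along(diseases)) {
    d <- diseases[[i]]
    if (nf) m[i, seq_len(nf)] <-
        vapply(phenotype$findings, function(pf)
          log(finding_likelihood(d, pf, kb, config)), 0)
    if (nz) m[i, nf + seq_len(nz)] <-
        vapply(zygosities, function(gz)
          log(zygosity_likelihood(d, gz, config)), 0)
  }
  m
}

# normalize a vector of log weights into probabilities (log-sum-exp guard)
softmax_log <- function(lw) {
  w <- exp(lw - max(lw))
  w / sum(w)
}

new_differential <- function(disease_ids, posterior, ascertained) {
  ord <- order(-posterior, disease_ids)
  entries <- data.frame(disease_id = disease_ids[ord],
                        posterior = unname(posterior[ord]))
  rownames(entries) <- NULL
  structure(
    list(entries = entries,
         ascertained = ascertained),
    class = "differential_diagnosis"
  )
}

#' Compute the differential diagnosis
#'
#' Naive-Bayes posterior over all knowledge-base diseases:
#' `posterior(d) proportional to incidence(d) * prod(finding likelihoods) *
#' prod(zygosity likelihoods)`, accumulated in log space and normalized.
#' Entries are sorted by descending posterior, ties broken by disease_id;
#' no disease is truncated, however small its posterior, so that
#' leave-one-out comparisons are always over the same disease set.
#'
#' @param kb A `knowledge_base` with at least one disease.
#' @param phenotype A `patient_phenotype` (may have zero findings).
#' @param zygosities List of `gene_zygosity` objects (may be empty).
#' @param config A [reanalysis_config()].
#' @return A `differential_diagnosis` with `entries`
#'   (data frame `disease_id`, `posterior`) and `ascertained` (the item ids
#'   used).
#' @export
compute_differential <- function(kb, phenotype, zygosities = list(),
                                 config = reanalysis_config()) {
  if (length(kb$diseases) == 0)
    stop("compute_differential: knowledge base has no diseases",
         call. = FALSE)
  m <- loglik_matrix(kb, phenotype, zygosities, config)
  lw <- log(kb_incidences(kb)) + rowSums(m)
  new_differential(names(kb$diseases), softmax_log(lw), colnames(m))
}

#' @export
print.differential_diagnosis <- function(x, n = 10, ...) {
  cat("<differential_diagnosis> top", min(n, nrow(x$entries)), "of",
      nrow(x$entries), "diseases\n")
  top <- utils::head(x$entries, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %-24s %8.4f%%\n", i, top$disease_id[i],
                100 * top$posterior[i]))
  invisible(x)
}
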