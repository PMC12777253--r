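#' Total variation distance between two differential diagnoses
#'
#' `0.5 * sum(|p1(d) - p2(d)|)` over the common disease set; lies in
#' \[0, 1\], is 0 iff the distributions coincide and 1 iff they place their
#' mass on disjoint diseases.
#'
#' @param d1,d2 `differential_diagnosis` objects over the same disease set.
#' @return A nonnegative real in \[0, 1\].
#' @export
differential_distance <- function(d1, d2) {
  p1 <- stats::setNames(d1$entries$posterior, d1$entries$disease_id)
  p2 <- stats::setNames(d2$entries$posterior, d2$entries$disease_id)
  if (!setequal(names(p1), names(p2)))
    stop("differential_distance: disease sets differ", call. = FALSE)
  0.5 * sum(abs(p1 - p2[names(p1)]))
}

tv_dist <- function(p1, p2) 0.5 * sum(abs(p1 - p2))

#' Leave-one-out pertinence ranking of ascertained evidence
#'
#' For every ascertained item -- each patient finding and each gene
#' zygosity -- the item is removed in turn, the differential diagnosis is
#' recomputed, and the raw pertinence is the total variation distance
#' between the full differential and the one without the item. Raw
#' distances are reported as a percent of the maximum over all items
#' (findings and zygosities normalized jointly), so the most pertinent item
#' scores 100. When every raw distance is 0 (a completely flat effect) all
#' percents are 0.
#'
#' The ranking is by pertinence, not by severity: a highly damaging variant
#' in a gene that fits no disease supported by the phenotype moves the
#' differential little and ranks low.
#'
#' @param kb A `knowledge_base`.
#' @param phenotype A `patient_phenotype`.
#' @param zygosities List of `gene_zygosity` objects.
#' @param config A [reanalysis_config()].
#' @return A data frame with columns `item_id`, `item_type` (`"finding"` or
#'   `"zygosity"`), `raw_distance`, `percent`, sorted by percent descending
#'   with ties broken by item_id.
#' @export
pertinence_ranking <- function(kb, phenotype, zygosities = list(),
                               config = reanalysis_config()) {
  m <- loglik_matrix(kb, phenotype, zygosities, config)
  if (ncol(m) == 0)
    return(data.frame(item_id = character(), item_type = character(),
                      raw_distance = numeric(), percent = numeric()))
  lw0 <- log(kb_incidences(kb)) + rowSums(m)
  p0 <- softmax_log(lw0)
  raw <- vapply(seq_len(ncol(m)), function(j) {
    tv_dist(p0, softmax_log(lw0 - m[, j]))
  }, 0)
  item_type <- ifelse(startsWith(colnames(m), "f:"), "finding", "zygosity")
  item_id <- substring(colnames(m), 3)
  pct <- if (max(raw) > 0) 100 * raw / max(raw) else rep(0, length(raw))
  out <- data.frame(item_id = item_id, item_type = item_type,
                    raw_distance = raw, percent = pct)
  out <- out[order(-out$percent, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-disease likelihood vectors for one candidate outcome pair.
# Findings: present/absent under the curated association or background rate.
# Gene tests: a matching-class zygosity of severity 5 found / not found.
candidate_outcome_liks <- function(kb, candidate, config) {
  diseases <- kb$diseases
  if (candidate %in% names(kb$findings)) {
    pf_yes <- patient_finding(candidate, "present")
    pf_no <- patient_finding(candidate, "absent")
    lik_yes <- vapply(diseases, function(d)
      finding_likelihood(d, pf_yes, kb, config), 0)
    lik_no <- vapply(diseases, function(d)
      finding_likelihood(d, pf_no, kb, config), 0)
    type <- "finding"
  } else {
    lik_yes <- vapply(diseases, function(d) {
      for (gl in d$gene_links)
        if (gl$gene_id == candidate)
          return(config$lambda_min +
                   (config$lambda_max - config$lambda_min) * gl$penetrance)
      config$phi
    }, 0)
    lik_no <- 1 - lik_yes
    type <- "gene"
  }
  list(yes = lik_yes, no = lik_no, type = type)
}

#' Usefulness ranking of candidate further tests
#'
#' Usefulness is the expected change of the differential diagnosis from
#' ascertaining a not-yet-tested item: for each candidate test `t` with
#' outcomes `o` (present/absent for findings; matching-zygosity found at
#' full severity / not found for gene tests),
#' `expected_change(t) = sum_o P(o | current differential) *
#' TV(current, updated with o)`, where
#' `P(o) = sum_d posterior(d) * likelihood(o | d)`. Gene candidates need
#' not appear in the variant table at all -- this is how the engine
#' recommends sequencing or re-examining a gene absent from the table when
#' the phenotype strongly supports a disease linked to it.
#'
#' @param kb A `knowledge_base`.
#' @param phenotype A `patient_phenotype`.
#' @param zygosities List of ascertained `gene_zygosity` objects.
#' @param candidates Character vector of finding_ids and/or gene_ids. A
#'   candidate already ascertained is skipped with a `message()`; an
#'   identifier matching neither a knowledge-base finding nor a linked gene
#'   is an error.
#' @param config A [reanalysis_config()].
#' @return A data frame with columns `test_id`, `test_type`,
#'   `expected_change`, `top_disease_supported` (the leading disease of the
#'   differential updated with the positive outcome), sorted by
#'   `expected_change` descending with ties broken by test_id.
#' @export
usefulness_ranking <- function(kb, phenotype, zygosities = list(),
                               candidates, config = reanalysis_config()) {
  genes <- unique(kb_gene_table(kb)$gene_id)
  known <- candidates %in% names(kb$findings) | candidates %in% genes
  if (any(!known))
    stop("unknown candidate test id(s): ",
         paste(candidates[!known], collapse = ", "), call. = FALSE)
  ascertained_f <- vapply(phenotype$findings, `[[`, "", "finding_id")
  ascertained_g <- vapply(zygosities, `[[`, "", "gene_id")
  skip <- (candidates %in% ascertained_f) |
    (candidates %in% ascertained_g & !candidates %in% names(kb$findings))
  if (any(skip))
    message("skipping already-ascertained candidate(s): ",
            paste(candidates[skip], collapse = ", "))
  candidates <- unique(candidates[!skip])
  d_full <- compute_differential(kb, phenotype, zygosities, config)
  p0 <- stats::setNames(d_full$entries$posterior, d_full$entries$disease_id)
  p0 <- p0[names(kb$diseases)]
  rows <- lapply(candidates, function(t) {
    cl <- candidate_outcome_liks(kb, t, config)
    ec <- 0
    top_yes <- NA_character_
    for (o in c("yes", "no")) {
      lik <- cl[[o]]
      prob_o <- sum(p0 * lik)
      p_o <- p0 * lik / sum(p0 * lik)
      ec <- ec + prob_o * tv_dist(p0, p_o)
      if (o == "yes") {
        ord <- order(-p_o, names(p_o))
        top_yes <- names(p_o)[ord[1]]
      }
    }
    data.frame(test_id = t, test_type = cl$type, expected_change = ec,
               top_disease_supported = top_yes)
  })
  if (length(rows) == 0)
    return(data.frame(test_id = character(), test_type = character(),
                      expected_change = numeric(),
                      top_disease_supported = character()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$expected_change, out$test_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
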