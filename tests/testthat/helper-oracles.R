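# Brute-force leave-one-out oracle: for every ascertained item, rebuild the
# inputs without it and rerun compute_differential from scratch.
oracle_pertinence <- function(kb, phen, zyg, config = reanalysis_config()) {
  d_full <- compute_differential(kb, phen, zyg, config)
  items <- list()
  for (f in phen$findings)
    items[[length(items) + 1L]] <-
      list(id = f$finding_id, type = "finding")
  for (z in zyg)
    items[[length(items) + 1L]] <- list(id = z$gene_id, type = "zygosity")
  raw <- vapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (it$type == "finding") {
      keep <- Filter(function(f) f$finding_id != it$id, phen$findings)
      phen2 <- patient_phenotype(phen$patient_id, phen$current_age,
                                 unname(keep))
      d2 <- compute_differential(kb, phen2, zyg, config)
    } else {
      zyg2 <- Filter(function(z) z$gene_id != it$id, zyg)
      d2 <- compute_differential(kb, phen, zyg2, config)
    }
    differential_distance(d_full, d2)
  }, 0)
  out <- data.frame(
    item_id = vapply(items, `[[`, "", "id"),
    item_type = vapply(items, `[[`, "", "type"),
    raw_distance = raw,
    percent = if (max(raw) > 0) 100 * raw / max(raw) else 0 * raw)
  out <- out[order(-out$percent, out$item_id), ]
  rownames(out) <- NULL
  out
}

# Outcome-enumeration oracle for usefulness: recompute the updated
# differential for each outcome by independent arithmetic on the posterior.
oracle_usefulness <- function(kb, phen, zyg, candidates,
                              config = reanalysis_config()) {
  d_full <- compute_differential(kb, phen, zyg, config)
  p0 <- setNames(d_full$entries$posterior, d_full$entries$disease_id)
  p0 <- p0[names(kb$diseases)]
  rows <- lapply(candidates, function(t) {
    if (t %in% names(kb$findings)) {
      lik_yes <- vapply(kb$diseases, function(d)
        finding_likelihood(d, patient_finding(t, "present"), kb, config), 0)
      lik_no <- vapply(kb$diseases, function(d)
        finding_likelihood(d, patient_finding(t, "absent"), kb, config), 0)
    } else {
      lik_yes <- vapply(kb$diseases, function(d) {
        hit <- Filter(function(gl) gl$gene_id == t, d$gene_links)
        if (length(hit))
          config$lambda_min + (config$lambda_max - config$lambda_min) *
            hit[[1]]$penetrance
        else config$phi
      }, 0)
      lik_no <- 1 - lik_yes
    }
    ec <- 0
    for (lik in list(lik_yes, lik_no)) {
      po <- sum(p0 * lik)
      ec <- ec + po * 0.5 * sum(abs(p0 - p0 * lik / po))
    }
    data.frame(test_id = t, expected_change = ec)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$expected_change, out$test_id), ]
  rownames(out) <- NULL
  out
}


# Independent oracle for single-variant trio zygosity calls, written as a
# direct transcription of Mendelian transmission logic. Dosages are alt
# allele counts; NA means the parent was not genotyped.
oracle_single <- function(pro, mo, fa, on_x, sex) {
  if (pro == 0) return(NULL)
  if (on_x && sex == "male") {
    dn <- if (is.na(mo)) "unknown" else if (mo >= 1) "no" else "yes"
    return(list(class = "x_linked", dn = dn, flags = character()))
  }
  if (pro == 2) {
    flags <- character()
    if (!is.na(mo) && !is.na(fa)) {
      carriers <- (mo >= 1) + (fa >= 1)
      if (carriers == 2) dn <- "no"
      else if (carriers == 0) {
        dn <- "yes"; flags <- "biallelic_without_carrier_parents"
      } else {
        dn <- "no"; flags <- "transmission_inconsistent"
      }
    } else {
      dn <- "unknown"
      genotyped <- c(mo, fa)[!is.na(c(mo, fa))]
      if (length(genotyped) == 1 && genotyped == 0)
        flags <- "transmission_inconsistent"
    }
    return(list(class = "biallelic", dn = dn, flags = flags))
  }
  # heterozygous
  if ((!is.na(mo) && mo >= 1) || (!is.na(fa) && fa >= 1))
    dn <- "no"
  else if (is.na(mo) || is.na(fa))
    dn <- "unknown"
  else dn <- "yes"
  list(class = "monoallelic", dn = dn, flags = character())
}

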