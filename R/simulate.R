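#' Generate a random fixture knowledge base
#'
#' Builds a small synthetic disease-finding-gene knowledge base for
#' simulation and testing: diseases with log-uniform rare-disease
#' incidences, mostly monogenic gene links across the three inheritance
#' modes, and per-disease finding associations with beta-distributed
#' frequencies and optional onset windows. It emulates the *shape* of a
#' curated diagnostic database at desk scale, not its content.
#'
#' @param n_diseases,n_findings Numbers of diseases and findings.
#' @param genetic_fraction Fraction of diseases given a gene link
#'   (the rest are nongenetic). Default 0.85.
#' @param seed Integer seed.
#' @return A validated `knowledge_base`.
#' @export
random_knowledge_base <- function(n_diseases = 30, n_findings = 40,
                                  genetic_fraction = 0.85, seed = 1) {
  set.seed(seed)
  findings <- lapply(seq_len(n_findings), function(i) {
    finding_def(sprintf("F%03d", i), sprintf("finding %d", i),
                sample(c("clinical", "lab", "imaging"), 1,
                       prob = c(0.6, 0.25, 0.15)),
                background_rate = stats::runif(1, 0.005, 0.05))
  })
  n_genetic <- round(genetic_fraction * n_diseases)
  diseases <- lapply(seq_len(n_diseases), function(i) {
    links <- list()
    if (i <= n_genetic) {
      inh <- sample(c("monoallelic", "biallelic", "x_linked"), 1,
                    prob = c(0.5, 0.35, 0.15))
      links <- list(gene_link(sprintf("G%03d", i), inh, penetrance = 1))
    }
    n_assoc <- sample(5:12, 1)
    fidx <- sample(n_findings, n_assoc)
    assoc <- lapply(fidx, function(j) {
      freq <- min(1, max(0.05, stats::rbeta(1, 2, 2)))
      win <- NULL
      if (stats::runif(1) < 0.5) {
        lo <- stats::runif(1, 0, 5)
        win <- c(lo, lo + stats::runif(1, 1, 10))
      }
      finding_association(sprintf("F%03d", j), freq, win)
    })
    disease_def(sprintf("D%03d", i), sprintf("disease %d", i),
                incidence = 10 ^ stats::runif(1, -6, -4),
                gene_links = links, associations = assoc)
  })
  knowledge_base(findings, diseases,
                 version_tag = sprintf("fixture-kb-seed%d", seed))
}

#' Simulation configuration for synthetic trio cohorts
#'
#' Defines the study conditions a cohort is generated under. The false de
#' novo mean reflects the calling pipeline: about 3.2 spurious de novo
#' calls per trio with BAM-aware joint calling, about 71 when the caller
#' sees the BAM files but calls samples separately, and about 406 when only
#' single-sample VCFs are available.
#'
#' @param kb A `knowledge_base` (typically [random_knowledge_base()]).
#' @param n_cases Number of trio cases.
#' @param false_de_novo_mean Poisson mean of spurious de novo variant calls
#'   per trio. Default 71.
#' @param noise_zygosity_mean Poisson mean of incidental damaged-gene
#'   zygosities in disease-linked genes (inherited carrier alleles and the
#'   like). Default 18.6.
#' @param finding_dropout Probability that a true finding goes unrecorded.
#'   Default 0.1.
#' @param negative_sampling_k Number of pertinent negatives recorded per
#'   case. Default 3.
#' @param single_parent_rate Probability that a case lacks the father.
#'   Default 0.1.
#' @param include_causal If `FALSE`, phenotypes are still drawn from a true
#'   disease but no causal variant is placed in the table (the unsolved-case
#'   arm). Default `TRUE`.
#' @param kb_gene_fraction Probability that a spurious de novo call lands
#'   in a disease-linked gene rather than elsewhere in the exome; default
#'   0.25, the approximate fraction of genes with known disease
#'   associations.
#' @param seed Integer master seed; per-case seeds derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(kb, n_cases, false_de_novo_mean = 71,
                              noise_zygosity_mean = 18.6,
                              finding_dropout = 0.1,
                              negative_sampling_k = 3,
                              single_parent_rate = 0.1,
                              include_causal = TRUE,
                              kb_gene_fraction = 0.25, seed = 1) {
  stopifnot(n_cases >= 1, false_de_novo_mean >= 0, noise_zygosity_mean >= 0,
            finding_dropout >= 0, finding_dropout <= 1,
            negative_sampling_k >= 0,
            single_parent_rate >= 0, single_parent_rate <= 1,
            kb_gene_fraction >= 0, kb_gene_fraction <= 1)
  structure(
    list(kb = kb, n_cases = as.integer(n_cases),
         false_de_novo_mean = false_de_novo_mean,
         noise_zygosity_mean = noise_zygosity_mean,
         finding_dropout = finding_dropout,
         negative_sampling_k = as.integer(negative_sampling_k),
         single_parent_rate = single_parent_rate,
         include_causal = include_causal,
         kb_gene_fraction = kb_gene_fraction,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic chromosome per gene: X when the gene has any x_linked link,
# otherwise an autosome fixed by the gene's index in the link table.
gene_chrom_map <- function(kb) {
  gt <- kb_gene_table(kb)
  genes <- unique(gt$gene_id)
  vapply(seq_along(genes), function(i) {
    inh <- gt$inheritance[gt$gene_id == genes[i]]
    if ("x_linked" %in% inh) "X" else as.character(1 + (i - 1) %% 22)
  }, "", USE.NAMES = TRUE) |> stats::setNames(genes)
}

noise_consequence <- function(n) {
  sample(c("synonymous", "noncoding", "missense_benign", "other",
           "missense_damaging", "lof"), n, replace = TRUE,
         prob = c(0.25, 0.25, 0.22, 0.10, 0.14, 0.04))
}

#' Simulate a single trio case
#'
#' Draws a phenotype from the true disease (findings Bernoulli at their
#' association frequencies, thinned by dropout, onsets uniform in the onset
#' window), records pertinent negatives preferentially from findings
#' frequent in competitor diseases, injects the causal variant(s) according
#' to the gene link's inheritance mode, and adds Poisson-distributed
#' spurious de novo variants and incidental carrier zygosities.
#'
#' @param config A [simulation_config()].
#' @param disease_id Disease to simulate; must have a gene link when a
#'   causal case is requested.
#' @param case_seed Integer seed for this case.
#' @param case_id Identifier; default derived from the seed.
#' @return A `synthetic_case` list with fields `case_id`,
#'   `true_disease_id`, `true_gene_zygosity`, `phenotype`, `variant_table`,
#'   `pedigree`.
#' @export
simulate_case <- function(config, disease_id, case_seed,
                          case_id = sprintf("case_%d", case_seed)) {
  kb <- config$kb
  disease <- kb$diseases[[disease_id]]
  if (is.null(disease))
    stop("unknown disease_id: ", disease_id, call. = FALSE)
  if (config$include_causal && length(disease$gene_links) == 0)
    stop("disease ", disease_id,
         " has no gene link; cannot simulate a causal genetic case",
         call. = FALSE)
  set.seed(case_seed)
  chrom_of <- gene_chrom_map(kb)

  link <- if (length(disease$gene_links)) disease$gene_links[[1]] else NULL
  x_case <- config$include_causal && !is.null(link) &&
    link$inheritance == "x_linked"
  sex <- if (x_case) "male" else sample(c("male", "female"), 1)
  father_present <- stats::runif(1) >= config$single_parent_rate
  ped <- pedigree(sex, mother_present = TRUE,
                  father_present = father_present)

  # --- phenotype: positives from the true disease's associations
  pos <- list()
  for (a in disease$associations) {
    if (stats::runif(1) < a$frequency &&
        stats::runif(1) >= config$finding_dropout) {
      onset <- if (!is.null(a$onset_window))
        stats::runif(1, a$onset_window[1], a$onset_window[2])
      else stats::runif(1, 0, 10)
      pos[[length(pos) + 1L]] <-
        patient_finding(a$finding_id, "present", round(onset, 2))
    }
  }
  if (length(pos) == 0 && length(disease$associations) > 0) {
    # a patient is ascertained because something presented: guarantee one
    # positive by taking the disease's most frequent finding
    freqs <- vapply(disease$associations, `[[`, 0, "frequency")
    a <- disease$associations[[which.max(freqs)]]
    onset <- if (!is.null(a$onset_window))
      stats::runif(1, a$onset_window[1], a$onset_window[2])
    else stats::runif(1, 0, 10)
    pos <- list(patient_finding(a$finding_id, "present", round(onset, 2)))
  }
  pos_ids <- vapply(pos, `[[`, "", "finding_id")

  # --- pertinent negatives: findings frequent in competitor diseases
  neg <- list()
  if (config$negative_sampling_k > 0) {
    competitors <- setdiff(names(kb$diseases), disease_id)
    pool <- unique(unlist(lapply(kb$diseases[competitors], function(d) {
      vapply(Filter(function(a) a$frequency >= 0.3, d$associations),
             `[[`, "", "finding_id")
    })))
    pool <- setdiff(pool, pos_ids)
    if (length(pool) > 0) {
      take <- sample(pool, min(config$negative_sampling_k, length(pool)))
      neg <- lapply(take, function(fid) patient_finding(fid, "absent"))
    }
  }
  onsets <- unlist(lapply(pos, `[[`, "onset_age"))
  current_age <- if (length(onsets)) max(onsets) + 1 else 10
  phen <- patient_phenotype(case_id, current_age, c(pos, neg))

  # --- variant table
  rows <- list()
  pos_counter <- 0L
  add_variant <- function(gene, chrom, consequence, af, gp, gm, gf,
                          dp = 50, known_path = FALSE) {
    pos_counter <<- pos_counter + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = 10000L + pos_counter * 37L,
      ref = "A", alt = "T", gene_id = gene, consequence = consequence,
      population_af = af, known_pathogenic = known_path,
      gt_proband = gp, gt_mother = gm,
      gt_father = if (father_present) gf else NA_real_,
      dp_proband = dp, dp_mother = dp,
      dp_father = if (father_present) dp else NA_real_
    )
  }

  true_gz <- NULL
  if (config$include_causal) {
    g <- link$gene_id
    cons <- sample(c("lof", "missense_damaging"), 1, prob = c(0.6, 0.4))
    known_path <- cons == "missense_damaging" && stats::runif(1) < 0.25
    if (link$inheritance == "monoallelic") {
      de_novo <- stats::runif(1) < 0.8
      add_variant(g, chrom_of[[g]], cons, NA_real_, 1,
                  if (de_novo) 0 else 1, 0, known_path = known_path)
      true_gz <- list(gene_id = g, zygosity_class = "monoallelic")
    } else if (link$inheritance == "biallelic") {
      if (stats::runif(1) < 0.3) {
        add_variant(g, chrom_of[[g]], cons, NA_real_, 2, 1, 1,
                    known_path = known_path)
      } else {
        add_variant(g, chrom_of[[g]], cons, NA_real_, 1, 1, 0,
                    known_path = known_path)
        add_variant(g, chrom_of[[g]],
                    sample(c("lof", "missense_damaging"), 1), NA_real_,
                    1, 0, 1)
      }
      true_gz <- list(gene_id = g, zygosity_class = "biallelic")
    } else {
      carrier_mother <- stats::runif(1) < 0.5
      add_variant(g, "X", cons, NA_real_, 1,
                  if (carrier_mother) 1 else 0, 0, known_path = known_path)
      true_gz <- list(gene_id = g, zygosity_class = "x_linked")
    }
  }

  # --- incidental carrier zygosities in disease-linked genes.
  # The true disease's gene is excluded from the noise pools: in a causal
  # case its variants are the injected ones, and in the causal-free arm the
  # defining feature is that the causative gene is absent from the table.
  gt_tab <- kb_gene_table(kb)
  withheld <- vapply(disease$gene_links, `[[`, "", "gene_id")
  other_genes <- setdiff(unique(gt_tab$gene_id), withheld)
  n_noise_z <- stats::rpois(1, config$noise_zygosity_mean)
  if (n_noise_z > 0 && length(other_genes) > 0) {
    picks <- sample(other_genes, n_noise_z, replace = TRUE)
    for (g in picks) {
      chrom <- chrom_of[[g]]
      inh <- gt_tab$inheritance[match(g, gt_tab$gene_id)]
      af <- if (stats::runif(1) < 0.5) NA_real_
            else 10 ^ stats::runif(1, -5, -2.5)
      if (stats::runif(1) < 0.3 && inh == "biallelic") {
        # class-matching compound het: a genuinely competing signal
        add_variant(g, chrom, noise_consequence(1), af, 1, 1, 0,
                    dp = sample(12:60, 1))
        add_variant(g, chrom, noise_consequence(1), NA_real_, 1, 0, 1,
                    dp = sample(12:60, 1))
      } else {
        from_mother <- stats::runif(1) < 0.5
        add_variant(g, chrom, noise_consequence(1), af, 1,
                    if (from_mother) 1 else 0,
                    if (from_mother) 0 else 1,
                    dp = sample(12:60, 1))
      }
    }
  }

  # --- spurious de novo calls from non-joint variant calling
  n_fdn <- stats::rpois(1, config$false_de_novo_mean)
  if (n_fdn > 0) {
    in_kb <- stats::runif(n_fdn) < config$kb_gene_fraction
    kb_pool <- other_genes
    cons <- noise_consequence(n_fdn)
    for (i in seq_len(n_fdn)) {
      if (in_kb[i] && length(kb_pool) > 0) {
        g <- sample(kb_pool, 1)
        chrom <- chrom_of[[g]]
      } else {
        g <- sprintf("%s_BG%04d", case_id, i)
        chrom <- as.character(sample(22, 1))
      }
      af <- if (stats::runif(1) < 0.7) NA_real_
            else 10 ^ stats::runif(1, -5, -2)
      add_variant(g, chrom, cons[i], af, 1, 0, 0,
                  dp = sample(4:60, 1))
    }
  }

  vt <- if (length(rows)) do.call(rbind, rows) else
    variant_table(character(), integer(), gene_id = character(),
                  consequence = character(), gt_proband = numeric())[0, ]
  class(vt) <- c("variant_table", "data.frame")
  structure(
    list(case_id = case_id, true_disease_id = disease_id,
         true_gene_zygosity = true_gz, phenotype = phen,
         variant_table = vt, pedigree = ped),
    class = "synthetic_case"
  )
}

#' Simulate a cohort of trio cases
#'
#' Diseases are sampled proportional to incidence (among diseases with a
#' gene link when causal cases are requested); per-case seeds derive
#' deterministically from `config$seed`, so the same configuration always
#' yields the same cohort.
#'
#' @param config A [simulation_config()].
#' @return A list of `synthetic_case` objects of length `config$n_cases`.
#' @export
simulate_cohort <- function(config) {
  kb <- config$kb
  eligible <- names(kb$diseases)
  if (config$include_causal) {
    has_gene <- vapply(kb$diseases, function(d) length(d$gene_links) > 0,
                       TRUE)
    eligible <- eligible[has_gene]
  }
  if (length(eligible) == 0)
    stop("no eligible diseases in knowledge base", call. = FALSE)
  inc <- kb_incidences(kb)[eligible]
  set.seed(config$seed)
  picks <- sample(eligible, config$n_cases, replace = TRUE,
                  prob = inc / sum(inc))
  case_seeds <- (as.numeric(config$seed) * 7919 +
                   seq_len(config$n_cases) * 104729) %% 2147483647
  lapply(seq_len(config$n_cases), function(i) {
    simulate_case(config, picks[i], as.integer(case_seeds[i]),
                  case_id = sprintf("case_%03d", i))
  })
}

# number of variant-level de novo calls in a table: proband carries the
# allele, both parents genotyped reference
count_de_novo <- function(vt) {
  sum(!is.na(vt$gt_proband) & vt$gt_proband >= 1 &
        !is.na(vt$gt_mother) & vt$gt_mother == 0 &
        !is.na(vt$gt_father) & vt$gt_father == 0)
}

#' Run the engine over a synthetic cohort and score recovery
#'
#' For each case: frequency-filter the variant table, call zygosities,
#' compute the joint pertinence ranking, and locate the causal gene
#' zygosity. Reports the top-1 rate (causal zygosity ranked first among
#' zygosities), the mean pertinence percent of the causal zygosity, the
#' mean pertinence of the top zygosity (the relevant summary for cohorts
#' simulated without a causal variant), and the mean de novo variant count
#' per case.
#'
#' @param cases List of `synthetic_case` objects.
#' @param kb The `knowledge_base` the cases were simulated from.
#' @param config A [reanalysis_config()].
#' @return A `recovery_report` list with per-case detail and cohort
#'   summaries.
#' @export
evaluate_recovery <- function(cases, kb, config = reanalysis_config()) {
  per_case <- lapply(cases, function(cs) {
    vt <- filter_by_frequency(cs$variant_table, kb, config$af_multiplier)
    zyg <- call_zygosities(vt, cs$pedigree, config)
    pr <- pertinence_ranking(kb, cs$phenotype, zyg, config)
    zr <- pr[pr$item_type == "zygosity", , drop = FALSE]
    causal_gene <- if (!is.null(cs$true_gene_zygosity))
      cs$true_gene_zygosity$gene_id else NA_character_
    causal_rank <- if (!is.na(causal_gene) && causal_gene %in% zr$item_id)
      match(causal_gene, zr$item_id) else NA_integer_
    data.frame(
      case_id = cs$case_id, true_disease_id = cs$true_disease_id,
      causal_gene = causal_gene, causal_rank = causal_rank,
      causal_pertinence = if (!is.na(causal_rank))
        zr$percent[causal_rank] else NA_real_,
      top_zygosity_pertinence = if (nrow(zr)) zr$percent[1] else NA_real_,
      n_zygosities = nrow(zr),
      # zygosities in genes with a curated disease link ("known phenotype")
      n_zygosities_known = sum(zr$item_id %in% kb_gene_table(kb)$gene_id),
      # de novo counts are defined for full trios only
      de_novo_count = if (cs$pedigree$mother_present &&
                            cs$pedigree$father_present)
        count_de_novo(cs$variant_table) else NA_real_
    )
  })
  per_case <- do.call(rbind, per_case)
  has_causal <- !is.na(per_case$causal_gene)
  structure(
    list(
      per_case = per_case,
      n_cases = nrow(per_case),
      top1_rate = if (any(has_causal)) {
        r <- per_case$causal_rank[has_causal]
        mean(!is.na(r) & r == 1)
      } else NA_real_,
      mean_causal_pertinence = if (any(has_causal))
        mean(per_case$causal_pertinence[has_causal], na.rm = TRUE)
        else NA_real_,
      mean_top_zygosity_pertinence =
        mean(per_case$top_zygosity_pertinence, na.rm = TRUE),
      mean_de_novo_count = mean(per_case$de_novo_count, na.rm = TRUE)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$n_cases, "cases\n")
  if (!is.na(x$top1_rate))
    cat(sprintf("  top-1 causal zygosity rate : %.3f\n", x$top1_rate))
  if (!is.na(x$mean_causal_pertinence))
    cat(sprintf("  mean causal pertinence     : %.1f%%\n",
                x$mean_causal_pertinence))
  cat(sprintf("  mean top zygosity pertinence: %.1f%%\n",
              x$mean_top_zygosity_pertinence))
  cat(sprintf("  mean de novo count          : %.1f\n",
              x$mean_de_novo_count))
  invisible(x)
}
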