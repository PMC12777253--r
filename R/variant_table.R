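#' Construct a pedigree description
#'
#' @param proband_sex `"male"` or `"female"`.
#' @param mother_present,father_present Whether each parent was sequenced.
#' @param affected_roles Character subset of
#'   `c("proband", "mother", "father")` who are affected.
#' @param samples Named character vector mapping roles to VCF sample names;
#'   defaults to the role names themselves.
#' @return A `pedigree` list.
#' @export
pedigree <- function(proband_sex, mother_present = TRUE,
                     father_present = TRUE,
                     affected_roles = "proband",
                     samples = NULL) {
  proband_sex <- match.arg(proband_sex, c("male", "female"))
  roles <- c("proband",
             if (mother_present) "mother",
             if (father_present) "father")
  if (is.null(samples)) samples <- stats::setNames(roles, roles)
  if (!all(affected_roles %in% c("proband", "mother", "father")))
    stop("affected_roles must be a subset of proband/mother/father",
         call. = FALSE)
  structure(
    list(proband_sex = proband_sex, mother_present = mother_present,
         father_present = father_present, affected_roles = affected_roles,
         samples = samples),
    class = "pedigree"
  )
}

# genotype string -> alt-allele dosage (0/1/2); "1" (hemizygous) -> 1 allele
# counted once; missing ("./.", ".", NA) -> NA. alt_index selects which alt
# allele of a multi-allelic site is being counted.
gt_dosage <- function(gt, alt_index = 1L) {
  if (length(alt_index) == 1L) alt_index <- rep(alt_index, length(gt))
  mapply(function(g, k) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == as.character(k))
  }, gt, alt_index, USE.NAMES = FALSE)
}

is_chr_x <- function(chrom) toupper(sub("^chr", "", chrom)) == "X"

#' Read an annotated trio variant table
#'
#' Joins a multi-sample VCF with an annotation table keyed by
#' chrom/pos/ref/alt. The annotation TSV has header
#' `chrom pos ref alt gene consequence population_af known_pathogenic`
#' (`population_af` may be blank; `known_pathogenic` is 0/1 or blank).
#' Variants present in the VCF but missing from the annotation table are
#' dropped, and the dropped count is reported via `message()`.
#'
#' @param vcf_path Path to a VCF (v4.x) covering the pedigree roles.
#' @param annotation_path Path to the annotation TSV.
#' @param pedigree A [pedigree()]; its declared-present roles must map to
#'   VCF sample columns.
#' @return A `variant_table` data frame with one row per annotated alt
#'   allele: columns `chrom, pos, ref, alt, gene_id, consequence,
#'   population_af, known_pathogenic, gt_proband, gt_mother, gt_father,
#'   dp_proband, dp_mother, dp_father`.
#' @export
read_variant_table <- function(vcf_path, annotation_path, pedigree) {
  if (!file.exists(vcf_path))
    stop("VCF file not found: ", vcf_path, call. = FALSE)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", vcf_path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  roles <- c("proband",
             if (pedigree$mother_present) "mother",
             if (pedigree$father_present) "father")
  want <- pedigree$samples[roles]
  missing_samples <- setdiff(want, samples)
  if (length(missing_samples) > 0)
    stop("pedigree error: VCF lacks sample(s) ",
         paste(missing_samples, collapse = ", "),
         " declared present in the pedigree", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  get_col <- function(mat, role) {
    if (!role %in% roles || is.null(mat)) return(rep(NA, nrow(fix)))
    s <- pedigree$samples[[role]]
    if (!s %in% colnames(mat)) return(rep(NA, nrow(fix)))
    mat[, s]
  }
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  if (!all(needed %in% names(ann)))
    stop("annotation table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  # expand multi-allelic ALT into one candidate row per alt allele
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], alt_index = k, row = i
      )
    }
  }
  cand <- do.call(rbind, rows)
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  ann_key <- key(ann$chrom, ann$pos, ann$ref, ann$alt)
  idx <- match(key(cand$chrom, cand$pos, cand$ref, cand$alt), ann_key)
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(dropped, " variant allele(s) without annotation dropped")
  keep <- !is.na(idx)
  cand <- cand[keep, , drop = FALSE]
  idx <- idx[keep]
  af <- if ("population_af" %in% names(ann))
    suppressWarnings(as.numeric(ann$population_af[idx])) else
    rep(NA_real_, length(idx))
  kp <- if ("known_pathogenic" %in% names(ann))
    !is.na(ann$known_pathogenic[idx]) &
      ann$known_pathogenic[idx] %in% c("1", "TRUE", "true", "yes") else
    rep(FALSE, length(idx))
  out <- data.frame(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
    gene_id = ann$gene[idx], consequence = ann$consequence[idx],
    population_af = af, known_pathogenic = kp,
    gt_proband = unname(gt_dosage(get_col(gt, "proband")[cand$row],
                                  cand$alt_index)),
    gt_mother = unname(gt_dosage(get_col(gt, "mother")[cand$row],
                                 cand$alt_index)),
    gt_father = unname(gt_dosage(get_col(gt, "father")[cand$row],
                                 cand$alt_index)),
    dp_proband = as.numeric(get_col(dp, "proband")[cand$row]),
    dp_mother = as.numeric(get_col(dp, "mother")[cand$row]),
    dp_father = as.numeric(get_col(dp, "father")[cand$row])
  )
  if (any(is.na(out$gt_proband)))
    out <- out[!is.na(out$gt_proband), , drop = FALSE]
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Build a variant table directly from vectors
#'
#' Programmatic constructor used by the simulator and tests; produces the
#' same `variant_table` data frame as [read_variant_table()]. Genotypes are
#' given as alt-allele dosages (0, 1, 2; `NA` for a missing or ungenotyped
#' parent).
#'
#' @param chrom,pos,ref,alt,gene_id,consequence Vectors, one entry per
#'   variant.
#' @param population_af Population allele frequency, `NA` when unknown.
#' @param known_pathogenic Logical flag per variant.
#' @param gt_proband,gt_mother,gt_father Alt-allele dosages.
#' @param dp_proband,dp_mother,dp_father Read depths (optional).
#' @return A `variant_table` data frame.
#' @export
variant_table <- function(chrom, pos, ref = "A", alt = "T", gene_id,
                          consequence, population_af = NA_real_,
                          known_pathogenic = FALSE,
                          gt_proband, gt_mother = NA_real_,
                          gt_father = NA_real_,
                          dp_proband = NA_real_, dp_mother = NA_real_,
                          dp_father = NA_real_) {
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, gene_id = gene_id, consequence = consequence,
                    population_af = as.numeric(population_af),
                    known_pathogenic = known_pathogenic,
                    gt_proband = as.numeric(gt_proband),
                    gt_mother = as.numeric(gt_mother),
                    gt_father = as.numeric(gt_father),
                    dp_proband = as.numeric(dp_proband),
                    dp_mother = as.numeric(dp_mother),
                    dp_father = as.numeric(dp_father))
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Incidence-based variant frequency filter
#'
#' A variant too common in the population to be compatible with the
#' incidence of the diseases its gene can cause is ignored. Under
#' Hardy-Weinberg equilibrium with full penetrance, the expected pathogenic
#' allele frequency is the incidence `I` for a monoallelic (dominant)
#' disease, `sqrt(I)` for a biallelic (recessive) disease, and the male
#' incidence `I` for an X-linked disease. A variant in gene `g` is retained
#' iff its population allele frequency is missing or does not exceed
#' `multiplier` times the maximum expected allele frequency over all
#' diseases linked to `g`. Variants in genes with no knowledge-base link are
#' always retained.
#'
#' @param variants A `variant_table`.
#' @param kb A `knowledge_base`.
#' @param multiplier Positive slack multiplier (default 1).
#' @return The filtered `variant_table`.
#' @export
filter_by_frequency <- function(variants, kb, multiplier = 1) {
  stopifnot(multiplier > 0)
  if (nrow(variants) == 0) return(variants)
  gt <- kb_gene_table(kb)
  if (nrow(gt) == 0) return(variants)
  expected <- ifelse(gt$inheritance == "biallelic",
                     sqrt(gt$incidence), gt$incidence)
  thr <- tapply(expected, gt$gene_id, max)
  gene_thr <- thr[variants$gene_id]
  keep <- is.na(variants$population_af) | is.na(gene_thr) |
    variants$population_af <= multiplier * gene_thr
  out <- variants[keep, , drop = FALSE]
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Severity of a gene zygosity on the 0-5 scale
#'
#' Each supporting variant gets a base score from the consequence class
#' (`lof` 5, `missense_damaging` 3, `missense_benign` 1, `synonymous` 0.5,
#' `noncoding` 0.5, `other` 1); a `known_pathogenic` annotation forces 5.
#' For monoallelic and X-linked zygosities the gene severity is the maximum
#' allele score; for biallelic zygosities it is the mean of the top two
#' allele scores, a homozygous variant contributing its score twice.
#'
#' @param zygosity A `gene_zygosity` with nonempty `supporting_variants`.
#' @param config A [reanalysis_config()] (supplies the severity table).
#' @return Severity in \[0, 5\].
#' @export
severity_of <- function(zygosity, config = reanalysis_config()) {
  sv <- zygosity$supporting_variants
  if (is.null(sv) || nrow(sv) == 0)
    stop("severity_of: supporting_variants is empty", call. = FALSE)
  base <- unname(config$severity_table[sv$consequence])
  base[is.na(base)] <- config$severity_table[["other"]]
  base[sv$known_pathogenic] <- 5
  if (zygosity$zygosity_class == "biallelic") {
    copies <- ifelse(!is.na(sv$gt_proband) & sv$gt_proband >= 2, 2L, 1L)
    alleles <- sort(rep(base, copies), decreasing = TRUE)
    mean(alleles[seq_len(min(2L, length(alleles)))])
  } else {
    max(base)
  }
}

# de novo status of a single inherited-allele variant given parental dosages
# (NA = not genotyped): yes only when both parents are genotyped reference.
dn_single <- function(mo, fa) {
  if (!is.na(mo) && mo >= 1) return("no")
  if (!is.na(fa) && fa >= 1) return("no")
  if (is.na(mo) || is.na(fa)) return("unknown")
  "yes"
}

#' Deduce gene zygosities from a variant table
#'
#' Collapses a (filtered) variant table into one abnormal gene-zygosity
#' finding per gene carrying at least one alternate allele in the proband:
#'
#' * autosomal heterozygous with both parents reference: monoallelic, de
#'   novo;
#' * autosomal heterozygous inherited from a carrier parent: monoallelic,
#'   not de novo;
#' * homozygous alternate, or two heterozygotes with distinct parental
#'   origins (trans): biallelic;
#' * two heterozygotes inherited from the same parent (cis): monoallelic,
#'   with flag `possible_cis_pair`;
#' * chrX variant in a male proband: X-linked hemizygous, de novo status
#'   from the mother;
#' * a missing parent makes de novo status `unknown` wherever that parent's
#'   genotype is needed;
#' * a biallelic call in which no genotyped parent carries any supporting
#'   allele gets flag `biallelic_without_carrier_parents`; a homozygote with
#'   only one carrier parent gets `transmission_inconsistent`; unresolvable
#'   compound-heterozygote phase gets `phase_unknown`; any supporting
#'   variant with read depth below `config$min_depth` gets `low_depth`.
#'
#' Ambiguities become flags, never silent drops.
#'
#' @param variants A `variant_table` (typically after
#'   [filter_by_frequency()]).
#' @param pedigree A [pedigree()].
#' @param config A [reanalysis_config()].
#' @return A list of `gene_zygosity` objects, one per gene, ordered by
#'   gene_id.
#' @export
call_zygosities <- function(variants, pedigree,
                            config = reanalysis_config()) {
  if (nrow(variants) == 0) return(list())
  carrier <- variants$gt_proband >= 1 & !is.na(variants$gt_proband)
  variants <- variants[carrier, , drop = FALSE]
  if (nrow(variants) == 0) return(list())
  if (!pedigree$mother_present) variants$gt_mother <- NA_real_
  if (!pedigree$father_present) variants$gt_father <- NA_real_
  out <- lapply(split(variants, variants$gene_id), function(sv) {
    call_gene_zygosity(sv, pedigree, config)
  })
  out <- out[order(names(out))]
  unname(out)
}

call_gene_zygosity <- function(sv, pedigree, config) {
  flags <- character()
  on_x <- all(is_chr_x(sv$chrom))
  mo <- sv$gt_mother
  fa <- sv$gt_father

  if (on_x && pedigree$proband_sex == "male") {
    zclass <- "x_linked"
    dn <- if (all(is.na(mo))) "unknown"
          else if (any(!is.na(mo) & mo >= 1)) "no" else "yes"
  } else {
    hom <- !is.na(sv$gt_proband) & sv$gt_proband >= 2
    if (any(hom)) {
      zclass <- "biallelic"
      h <- which(hom)[1]
      n_genotyped <- sum(!is.na(c(mo[h], fa[h])))
      n_carrier <- sum(c(mo[h], fa[h]) >= 1, na.rm = TRUE)
      if (n_genotyped == 2) {
        if (n_carrier == 2) dn <- "no"
        else if (n_carrier == 0) {
          dn <- "yes"
          flags <- c(flags, "biallelic_without_carrier_parents")
        } else {
          dn <- "no"
          flags <- c(flags, "transmission_inconsistent")
        }
      } else {
        dn <- "unknown"
        if (n_genotyped == 1 && n_carrier == 0)
          flags <- c(flags, "transmission_inconsistent")
      }
    } else if (nrow(sv) >= 2) {
      # compound heterozygote: assign parental origin per variant
      origin <- vapply(seq_len(nrow(sv)), function(i) {
        m <- mo[i]; f <- fa[i]
        if (is.na(m) || is.na(f)) return("unknown")
        mc <- m >= 1; fc <- f >= 1
        if (mc && !fc) "mother"
        else if (fc && !mc) "father"
        else if (!mc && !fc) "denovo"
        else "ambiguous"
      }, "")
      if ("mother" %in% origin && "father" %in% origin) {
        zclass <- "biallelic"; dn <- "no"
      } else if (all(origin == "denovo")) {
        zclass <- "biallelic"; dn <- "yes"
        flags <- c(flags, "biallelic_without_carrier_parents")
      } else if ("denovo" %in% origin &&
                 any(origin %in% c("mother", "father"))) {
        zclass <- "biallelic"; dn <- "yes"
      } else if (any(origin %in% c("unknown", "ambiguous"))) {
        zclass <- "biallelic"
        dn <- if (any(origin == "unknown")) "unknown" else "no"
        flags <- c(flags, "phase_unknown")
      } else {
        # all inherited from the same parent: presumed cis, one damaged allele
        zclass <- "monoallelic"; dn <- "no"
        flags <- c(flags, "possible_cis_pair")
      }
    } else {
      zclass <- "monoallelic"
      dn <- dn_single(mo[1], fa[1])
    }
  }

  depths <- c(sv$dp_proband,
              if (pedigree$mother_present) sv$dp_mother,
              if (pedigree$father_present) sv$dp_father)
  if (any(!is.na(depths) & depths < config$min_depth))
    flags <- c(flags, "low_depth")

  gz <- structure(
    list(gene_id = sv$gene_id[1], zygosity_class = zclass, de_novo = dn,
         severity = NA_real_, supporting_variants = sv,
         consistency_flags = unique(flags)),
    class = "gene_zygosity"
  )
  gz$severity <- severity_of(gz, config)
  gz
}

#' @export
print.gene_zygosity <- function(x, ...) {
  cat(sprintf("<gene_zygosity> %s %s severity=%.1f de_novo=%s%s\n",
              x$gene_id, x$zygosity_class, x$severity, x$de_novo,
              if (length(x$consistency_flags))
                paste0(" [", paste(x$consistency_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
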