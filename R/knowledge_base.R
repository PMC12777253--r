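#' Construct a finding definition
#'
#' A finding is any clinical, laboratory or imaging observation that can be
#' asserted present or absent in a patient. `background_rate` is the
#' probability of observing the finding in an unaffected individual; it is
#' the likelihood used when a disease carries no curated association for the
#' finding.
#'
#' @param finding_id Opaque identifier, unique within a knowledge base.
#' @param name Human-readable name.
#' @param category One of `"clinical"`, `"lab"`, `"imaging"`.
#' @param background_rate Probability in (0, 1) of the finding in an
#'   unaffected individual. Default 0.01.
#' @return A `finding_def` list.
#' @export
finding_def <- function(finding_id, name = finding_id, category = "clinical",
                        background_rate = 0.01) {
  structure(
    list(finding_id = as.character(finding_id), name = as.character(name),
         category = as.character(category),
         background_rate = as.numeric(background_rate)),
    class = "finding_def"
  )
}

#' Construct a disease-finding association
#'
#' @param finding_id Identifier of a finding defined in the knowledge base.
#' @param frequency Probability in (0, 1] that the finding is present in
#'   affected individuals.
#' @param onset_window Optional numeric length-2 vector
#'   `c(earliest, latest)` in decimal years; `NULL` if onset is not curated.
#' @return A `finding_association` list.
#' @export
finding_association <- function(finding_id, frequency, onset_window = NULL) {
  if (!is.null(onset_window)) onset_window <- as.numeric(onset_window)
  structure(
    list(finding_id = as.character(finding_id),
         frequency = as.numeric(frequency),
         onset_window = onset_window),
    class = "finding_association"
  )
}

#' Construct a gene-disease link
#'
#' @param gene_id Gene symbol.
#' @param inheritance One of `"monoallelic"`, `"biallelic"`, `"x_linked"`.
#' @param penetrance Probability in (0, 1]; default 1.
#' @return A `gene_link` list.
#' @export
gene_link <- function(gene_id, inheritance, penetrance = 1) {
  structure(
    list(gene_id = as.character(gene_id),
         inheritance = as.character(inheritance),
         penetrance = as.numeric(penetrance)),
    class = "gene_link"
  )
}

#' Construct a disease entry
#'
#' @param disease_id Unique identifier.
#' @param name Human-readable name.
#' @param incidence Prior probability per individual, in (0, 1).
#' @param gene_links List of [gene_link()] objects; may be empty
#'   (nongenetic diseases are allowed).
#' @param associations List of [finding_association()] objects.
#' @return A `disease_def` list.
#' @export
disease_def <- function(disease_id, name = disease_id, incidence,
                        gene_links = list(), associations = list()) {
  structure(
    list(disease_id = as.character(disease_id), name = as.character(name),
         incidence = as.numeric(incidence),
         gene_links = gene_links, associations = associations),
    class = "disease_def"
  )
}

#' Assemble a knowledge base
#'
#' The knowledge base is the engine's curated model of diseases: for each
#' disease an incidence prior, the genes that can cause it (with inheritance
#' mode and penetrance), and the findings associated with it (with frequency
#' in affected individuals and, optionally, an onset window).
#'
#' @param findings List of [finding_def()] objects.
#' @param diseases List of [disease_def()] objects.
#' @param version_tag Free-text version label.
#' @return A `knowledge_base` object.
#' @export
knowledge_base <- function(findings, diseases, version_tag = "unversioned") {
  names(findings) <- vapply(findings, `[[`, "", "finding_id")
  names(diseases) <- vapply(diseases, `[[`, "", "disease_id")
  structure(
    list(findings = findings, diseases = diseases,
         version_tag = as.character(version_tag)),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  n_assoc <- sum(vapply(x$diseases, function(d) length(d$associations), 0L))
  n_links <- sum(vapply(x$diseases, function(d) length(d$gene_links), 0L))
  cat(sprintf(
    "<knowledge_base '%s'> %d diseases, %d findings, %d associations, %d gene links\n",
    x$version_tag, length(x$diseases), length(x$findings), n_assoc, n_links))
  invisible(x)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: identifier uniqueness, referential
#' integrity of associations, probability ranges, inheritance vocabulary and
#' onset-window ordering. Validation never throws; it returns a data frame of
#' violations (zero rows when the knowledge base is well formed).
#'
#' @param kb A `knowledge_base` object.
#' @return A data frame with columns `entity`, `field`, `rule`, one row per
#'   violation.
#' @export
validate_knowledge_base <- function(kb) {
  v <- list()
  bad <- function(entity, field, rule) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, field = field,
                                       rule = rule)
  }
  fids <- vapply(kb$findings, `[[`, "", "finding_id")
  if (anyDuplicated(fids))
    bad(paste(unique(fids[duplicated(fids)]), collapse = ","),
        "finding_id", "finding_id must be unique")
  for (f in kb$findings) {
    if (!is.finite(f$background_rate) || f$background_rate <= 0 ||
        f$background_rate >= 1)
      bad(f$finding_id, "background_rate", "background_rate out of (0,1)")
    if (!f$category %in% c("clinical", "lab", "imaging"))
      bad(f$finding_id, "category", "category not in {clinical, lab, imaging}")
  }
  dids <- vapply(kb$diseases, `[[`, "", "disease_id")
  if (anyDuplicated(dids))
    bad(paste(unique(dids[duplicated(dids)]), collapse = ","),
        "disease_id", "disease_id must be unique")
  for (d in kb$diseases) {
    if (!is.finite(d$incidence) || d$incidence <= 0 || d$incidence >= 1)
      bad(d$disease_id, "incidence", "incidence out of (0,1)")
    gpairs <- vapply(d$gene_links, `[[`, "", "gene_id")
    if (anyDuplicated(gpairs))
      bad(d$disease_id, "gene_links", "one link per (gene, disease) pair")
    for (gl in d$gene_links) {
      if (!gl$inheritance %in% c("monoallelic", "biallelic", "x_linked"))
        bad(paste0(d$disease_id, "/", gl$gene_id), "inheritance",
            "inheritance not in {monoallelic, biallelic, x_linked}")
      if (!is.finite(gl$penetrance) || gl$penetrance <= 0 ||
          gl$penetrance > 1)
        bad(paste0(d$disease_id, "/", gl$gene_id), "penetrance",
            "penetrance out of (0,1]")
    }
    for (a in d$associations) {
      if (!a$finding_id %in% fids)
        bad(paste0(d$disease_id, "/", a$finding_id), "finding_id",
            "association references undefined finding_id")
      if (!is.finite(a$frequency) || a$frequency <= 0 || a$frequency > 1)
        bad(paste0(d$disease_id, "/", a$finding_id), "frequency",
            "frequency out of (0,1]")
      if (!is.null(a$onset_window)) {
        if (length(a$onset_window) != 2 || anyNA(a$onset_window) ||
            a$onset_window[1] > a$onset_window[2])
          bad(paste0(d$disease_id, "/", a$finding_id), "onset_window",
              "onset_window must be ordered (earliest <= latest)")
      }
    }
  }
  if (length(v) == 0)
    return(data.frame(entity = character(), field = character(),
                      rule = character()))
  do.call(rbind, v)
}

#' Write a knowledge base to a JSON document
#'
#' The on-disk format is a UTF-8 JSON document with top-level `version_tag`,
#' `findings` and `diseases` arrays; ages are decimal years and probabilities
#' decimals. The format round-trips exactly through [load_knowledge_base()].
#'
#' @param kb A validated `knowledge_base`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_knowledge_base <- function(kb, path) {
  doc <- list(
    version_tag = kb$version_tag,
    findings = lapply(unname(kb$findings), function(f) {
      f[!vapply(f, is.null, TRUE)]
    }),
    diseases = lapply(unname(kb$diseases), function(d) {
      list(disease_id = d$disease_id, name = d$name, incidence = d$incidence,
           gene_links = lapply(d$gene_links, unclass),
           associations = lapply(d$associations, function(a) {
             a[!vapply(a, is.null, TRUE)]
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a knowledge base from a JSON document
#'
#' Parses the documented JSON format and enforces every invariant; a
#' knowledge base that fails validation is rejected with a message listing
#' all violations, not just the first.
#'
#' @param path Path to a knowledge-base JSON file.
#' @return A validated `knowledge_base` object.
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path))
    stop("knowledge base file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("knowledge base parse failure in '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  for (key in c("findings", "diseases"))
    if (is.null(doc[[key]]))
      stop("knowledge base format error: missing top-level '", key,
           "' array in ", path, call. = FALSE)
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  findings <- lapply(doc$findings, function(f) {
    finding_def(f$finding_id, f$name %||% f$finding_id,
                f$category %||% "clinical",
                num_or_null(f$background_rate) %||% 0.01)
  })
  diseases <- lapply(doc$diseases, function(d) {
    disease_def(
      d$disease_id, d$name %||% d$disease_id, as.numeric(d$incidence),
      gene_links = lapply(d$gene_links, function(gl) {
        gene_link(gl$gene_id, gl$inheritance,
                  num_or_null(gl$penetrance) %||% 1)
      }),
      associations = lapply(d$associations, function(a) {
        finding_association(a$finding_id, as.numeric(a$frequency),
                            num_or_null(unlist(a$onset_window)))
      })
    )
  })
  kb <- knowledge_base(findings, diseases,
                       version_tag = doc$version_tag %||% "unversioned")
  viol <- validate_knowledge_base(kb)
  if (nrow(viol) > 0)
    stop("knowledge base validation failed:\n",
         paste0("  [", viol$entity, "] ", viol$field, ": ", viol$rule,
                collapse = "\n"), call. = FALSE)
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flat lookup tables used by the engine: one row per gene link and a named
# incidence vector. Rebuilt on demand; cheap relative to any analysis.
kb_gene_table <- function(kb) {
  rows <- lapply(kb$diseases, function(d) {
    if (length(d$gene_links) == 0) return(NULL)
    data.frame(
      disease_id = d$disease_id,
      gene_id = vapply(d$gene_links, `[[`, "", "gene_id"),
      inheritance = vapply(d$gene_links, `[[`, "", "inheritance"),
      penetrance = vapply(d$gene_links, `[[`, 0, "penetrance"),
      incidence = d$incidence
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(disease_id = character(), gene_id = character(),
                      inheritance = character(), penetrance = numeric(),
                      incidence = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

kb_incidences <- function(kb) {
  vapply(kb$diseases, `[[`, 0, "incidence")
}
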