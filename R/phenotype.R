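#' Construct a patient finding
#'
#' @param finding_id Identifier of a finding defined in the knowledge base.
#' @param state `"present"` (pertinent positive) or `"absent"` (pertinent
#'   negative).
#' @param onset_age Onset in decimal years; only meaningful when
#'   `state = "present"`.
#' @return A `patient_finding` list.
#' @export
patient_finding <- function(finding_id, state, onset_age = NULL) {
  state <- match.arg(state, c("present", "absent"))
  if (state == "absent" && !is.null(onset_age))
    stop("absent findings carry no onset", call. = FALSE)
  if (!is.null(onset_age)) {
    onset_age <- as.numeric(onset_age)
    if (!is.finite(onset_age) || onset_age < 0)
      stop("onset_age must be >= 0", call. = FALSE)
  }
  structure(
    list(finding_id = as.character(finding_id), state = state,
         onset_age = onset_age),
    class = "patient_finding"
  )
}

#' Assemble a patient phenotype
#'
#' @param patient_id Identifier of the patient.
#' @param current_age Current age in decimal years.
#' @param findings List of [patient_finding()] objects, at most one per
#'   finding_id.
#' @return A `patient_phenotype` object.
#' @export
patient_phenotype <- function(patient_id, current_age, findings = list()) {
  ids <- vapply(findings, `[[`, "", "finding_id")
  if (anyDuplicated(ids))
    stop("duplicate finding_id in phenotype: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  for (f in findings)
    if (!is.null(f$onset_age) && f$onset_age > current_age)
      stop("onset_age exceeds current_age for finding ", f$finding_id,
           call. = FALSE)
  names(findings) <- ids
  structure(
    list(patient_id = as.character(patient_id),
         current_age = as.numeric(current_age), findings = findings),
    class = "patient_phenotype"
  )
}

#' Read a patient phenotype from a findings file
#'
#' The findings file is tab-separated with header
#' `finding_id  state  onset_age`; `state` is `present` or `absent` and
#' `onset_age` may be blank (and must be blank for absent findings). Every
#' finding_id must resolve against the knowledge base.
#'
#' @param path Path to the findings TSV.
#' @param kb A `knowledge_base` the finding identifiers resolve against.
#' @param patient_id Identifier for the patient (default: file basename).
#' @param current_age Patient age in years; defaults to the largest onset
#'   plus one year when not given.
#' @return A `patient_phenotype` object.
#' @export
read_phenotype <- function(path, kb, patient_id = NULL, current_age = NULL) {
  if (!file.exists(path))
    stop("findings file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "character"))
  needed <- c("finding_id", "state", "onset_age")
  if (!all(needed %in% names(tab)))
    stop("findings file must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  unknown <- setdiff(tab$finding_id, names(kb$findings))
  if (length(unknown) > 0)
    stop("finding_id not in knowledge base: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$finding_id))
    stop("duplicate finding_id in findings file: ",
         paste(unique(tab$finding_id[duplicated(tab$finding_id)]),
               collapse = ", "), call. = FALSE)
  findings <- lapply(seq_len(nrow(tab)), function(i) {
    onset <- tab$onset_age[i]
    onset <- if (is.na(onset) || !nzchar(trimws(onset))) NULL
             else as.numeric(onset)
    patient_finding(tab$finding_id[i], tab$state[i], onset)
  })
  if (is.null(current_age)) {
    onsets <- unlist(lapply(findings, `[[`, "onset_age"))
    current_age <- if (length(onsets)) max(onsets) + 1 else 1
  }
  default_id <- sub("\\.(findings\\.)?tsv$", "", basename(path))
  patient_phenotype(patient_id %||% default_id, current_age, findings)
}

#' Write a patient phenotype to a findings file
#'
#' Inverse of [read_phenotype()]; emits the tab-separated
#' `finding_id  state  onset_age` format.
#'
#' @param phenotype A `patient_phenotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  tab <- data.frame(
    finding_id = vapply(phenotype$findings, `[[`, "", "finding_id"),
    state = vapply(phenotype$findings, `[[`, "", "state"),
    onset_age = vapply(phenotype$findings, function(f) {
      if (is.null(f$onset_age)) "" else format(f$onset_age)
    }, "")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge clinical-correlation findings into a phenotype
#'
#' Clinical correlation is the post-sequencing chart review in which the
#' clinician adds findings (typically pertinent negatives) suggested as
#' useful by the engine. Additions override the base phenotype on conflict;
#' the operation is pure (neither input is modified) and idempotent.
#'
#' @param base A `patient_phenotype`.
#' @param additions List of [patient_finding()] objects.
#' @return A new `patient_phenotype`.
#' @export
merge_correlation_findings <- function(base, additions) {
  merged <- base$findings
  for (f in additions) merged[[f$finding_id]] <- f
  patient_phenotype(base$patient_id, base$current_age, unname(merged))
}
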