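# Admission-level registry input, validation, exclusion cascade and
# diagnosis subgroups.

DIAGNOSIS_GROUPS <- c("NONTRAUMATIC_ICH", "SAH", "TBI_MULTITRAUMA",
                      "TBI_ISOLATED", "OTHER")
NEURO_GROUPS <- setdiff(DIAGNOSIS_GROUPS, "OTHER")

SUBGROUP_LABELS <- c(DIAGNOSIS_GROUPS, "NEURO_ALL", "NON_NEURO", "ALL")

EXCLUSION_REASONS <- c("TRANSFER", "NON_EMERGENCY", "UNKNOWN_DISCHARGE",
                       "READMISSION", "MISSING_TISS", "MISSING_SEX",
                       "MISSING_GCS", "ORGAN_DONOR")

ADMISSION_COLUMNS <- c("admission_id", "unit_id", "year", "diagnosis_group",
                       "admission_type", "saps2", "gcs", "age", "sex",
                       "operative", "premorbid_status", "los_days",
                       "tiss_total", "died_in_hospital", "organ_donor",
                       "readmission", "icu_transfer_in")

#' Supported diagnosis groups
#'
#' The five diagnosis groups the benchmarking distinguishes: the four
#' neurosurgical emergencies (nontraumatic intracerebral haemorrhage,
#' subarachnoid haemorrhage, traumatic brain injury with and without
#' multitrauma) and \code{OTHER} for all remaining emergency admissions.
#'
#' @return Character vector of the five group labels.
#' @export
diagnosis_groups <- function() DIAGNOSIS_GROUPS

#' Subgroup labels accepted by subgroup selection
#'
#' In addition to the five diagnosis groups, \code{NEURO_ALL} selects the
#' union of the four neurosurgical groups, \code{NON_NEURO} the
#' \code{OTHER} group, and \code{ALL} the whole cohort.
#'
#' @return Character vector of subgroup labels.
#' @export
subgroup_labels <- function() SUBGROUP_LABELS

.parse_logical <- function(x) {
  v <- rep(NA, length(x))
  v[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  v[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  bad <- !is.na(x) & x != "" & x != "NA" & is.na(v)
  if (any(bad)) stop("unparseable logical value: ", x[which(bad)[1]])
  v
}

.check <- function(ok, row, field, msg) {
  bad <- which(!ok)
  if (length(bad)) {
    stop(sprintf("validation error at row %d, field '%s': %s",
                 row[bad[1]], field, msg), call. = FALSE)
  }
}

#' Validate a data frame of ICU admissions
#'
#' Checks ranges and enumerations for every admission field. Missing values
#' are allowed only where the data model permits them (gcs, sex, age,
#' premorbid_status, tiss_total, died_in_hospital); out-of-range values
#' (e.g. a GCS of 16, non-positive length of stay) raise an error naming
#' the offending row and field.
#'
#' @param adm Data frame with the admission columns (see
#'   \code{\link{read_admissions}}).
#' @return The validated data frame, invisibly coerced to canonical types.
#' @export
validate_admissions <- function(adm) {
  missing_cols <- setdiff(ADMISSION_COLUMNS, names(adm))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  adm <- adm[ADMISSION_COLUMNS]
  n <- nrow(adm)
  if (n == 0) return(adm)
  row <- seq_len(n)

  adm$admission_id <- as.character(adm$admission_id)
  adm$unit_id <- as.character(adm$unit_id)
  .check(!is.na(adm$admission_id) & adm$admission_id != "", row,
         "admission_id", "must be non-empty")
  .check(!duplicated(adm$admission_id), row, "admission_id",
         "duplicate identifier")
  .check(!is.na(adm$unit_id) & adm$unit_id != "", row, "unit_id",
         "must be non-empty")

  adm$year <- as.integer(adm$year)
  .check(!is.na(adm$year), row, "year", "must be an integer year")

  adm$diagnosis_group <- as.character(adm$diagnosis_group)
  .check(adm$diagnosis_group %in% DIAGNOSIS_GROUPS, row, "diagnosis_group",
         paste("must be one of", paste(DIAGNOSIS_GROUPS, collapse = "/")))
  adm$admission_type <- as.character(adm$admission_type)
  .check(adm$admission_type %in% c("EMERGENCY", "ELECTIVE"), row,
         "admission_type", "must be EMERGENCY or ELECTIVE")

  adm$saps2 <- as.integer(adm$saps2)
  .check(!is.na(adm$saps2) & adm$saps2 >= 0, row, "saps2",
         "must be a non-negative integer")
  adm$gcs <- as.integer(adm$gcs)
  .check(is.na(adm$gcs) | (adm$gcs >= 3 & adm$gcs <= 15), row, "gcs",
         "must be in 3..15 or missing")
  adm$age <- as.numeric(adm$age)
  .check(is.na(adm$age) | (adm$age >= 0 & adm$age <= 130), row, "age",
         "implausible age")
  adm$sex <- as.character(adm$sex)
  adm$sex[!is.na(adm$sex) & adm$sex == ""] <- NA_character_
  .check(is.na(adm$sex) | adm$sex %in% c("F", "M"), row, "sex",
         "must be F, M or missing")
  adm$premorbid_status <- as.character(adm$premorbid_status)
  adm$premorbid_status[!is.na(adm$premorbid_status) &
                         adm$premorbid_status == ""] <- NA_character_
  .check(is.na(adm$premorbid_status) |
           adm$premorbid_status %in% c("NORMAL", "LIGHT", "MODERATE", "SEVERE"),
         row, "premorbid_status", "unknown level")

  adm$los_days <- as.numeric(adm$los_days)
  .check(!is.na(adm$los_days) & adm$los_days > 0, row, "los_days",
         "must be > 0")
  adm$tiss_total <- as.numeric(adm$tiss_total)
  .check(is.na(adm$tiss_total) | adm$tiss_total >= 0, row, "tiss_total",
         "must be >= 0 or missing")

  for (f in c("operative", "organ_donor", "readmission", "icu_transfer_in")) {
    if (!is.logical(adm[[f]])) adm[[f]] <- .parse_logical(as.character(adm[[f]]))
    .check(!is.na(adm[[f]]), row, f, "must be TRUE/FALSE")
  }
  if (!is.logical(adm$died_in_hospital)) {
    adm$died_in_hospital <- .parse_logical(as.character(adm$died_in_hospital))
  }
  rownames(adm) <- NULL
  adm
}

#' Read ICU admissions from a delimited registry file
#'
#' Reads a CSV or TSV file (UTF-8, header row, one row per ICU admission)
#' with the columns of the admission data model in snake_case:
#' \code{admission_id, unit_id, year, diagnosis_group, admission_type,
#' saps2, gcs, age, sex, operative, premorbid_status, los_days, tiss_total,
#' died_in_hospital, organ_donor, readmission, icu_transfer_in}.
#' Empty fields and the literal token \code{NA} are read as missing; they
#' are never silently replaced by defaults.
#'
#' @param path Path to the file. The delimiter is taken from the extension
#'   (\code{.tsv} = tab, otherwise comma) unless \code{sep} is given.
#' @param sep Optional field separator override.
#' @return A validated data frame of admissions, in file order.
#' @seealso \code{\link{apply_exclusions}}, \code{\link{validate_admissions}}
#' @export
read_admissions <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cannot read admissions file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  adm <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8")
  validate_admissions(adm)
}

#' Read unit profiles from YAML or JSON
#'
#' A unit profile document is keyed by unit id; each entry carries the
#' structural attributes of one ICU (\code{beds},
#' \code{fte_physicians_per_bed}, \code{independent_org}), its cost
#' bookkeeping (\code{currency} EUR or CHF, \code{ppp_factor}) and a map
#' \code{annual_direct_costs} from calendar year to the annual direct ICU
#' costs (salaries, drugs, fluids, disposables) in the native currency.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{unit_profiles} object; see \code{\link{unit_profiles}}.
#' @export
read_unit_profiles <- function(path) {
  if (!file.exists(path)) stop("cannot read unit profile file: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  units <- do.call(rbind, lapply(names(doc), function(uid) {
    p <- doc[[uid]]
    data.frame(unit_id = uid, beds = as.integer(p$beds),
               fte_physicians_per_bed = as.numeric(p$fte_physicians_per_bed),
               independent_org = as.logical(p$independent_org),
               currency = as.character(p$currency),
               ppp_factor = as.numeric(p$ppp_factor),
               stringsAsFactors = FALSE)
  }))
  costs <- do.call(rbind, lapply(names(doc), function(uid) {
    cc <- doc[[uid]]$annual_direct_costs
    data.frame(unit_id = uid, year = as.integer(names(cc)),
               amount = as.numeric(unlist(cc)), stringsAsFactors = FALSE)
  }))
  unit_profiles(units, costs)
}

#' Construct a unit-profile object
#'
#' @param units Data frame with one row per ICU: \code{unit_id},
#'   \code{beds}, \code{fte_physicians_per_bed}, \code{independent_org},
#'   \code{currency} (\code{"EUR"} or \code{"CHF"}), \code{ppp_factor}.
#' @param costs Data frame of annual direct costs in native currency:
#'   \code{unit_id}, \code{year}, \code{amount}.
#' @return An object of class \code{unit_profiles}.
#' @export
unit_profiles <- function(units, costs) {
  stopifnot(all(c("unit_id", "beds", "fte_physicians_per_bed",
                  "independent_org", "currency", "ppp_factor") %in%
                  names(units)),
            all(c("unit_id", "year", "amount") %in% names(costs)))
  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id in profiles")
  if (!all(units$currency %in% c("EUR", "CHF"))) {
    stop("currency must be EUR or CHF")
  }
  if (any(units$beds <= 0) || any(units$fte_physicians_per_bed <= 0) ||
      any(units$ppp_factor <= 0)) {
    stop("beds, fte_physicians_per_bed and ppp_factor must be positive")
  }
  if (!all(costs$unit_id %in% units$unit_id)) {
    stop("cost entry for unknown unit")
  }
  if (any(costs$amount < 0)) stop("annual costs must be non-negative")
  structure(list(units = units[order(units$unit_id), , drop = FALSE],
                 costs = costs[order(costs$unit_id, costs$year), ,
                               drop = FALSE]),
            class = "unit_profiles")
}

#' @export
print.unit_profiles <- function(x, ...) {
  cat("Unit profiles:", nrow(x$units), "ICU(s),",
      length(unique(x$costs$year)), "cost year(s)\n")
  print(x$units, row.names = FALSE)
  invisible(x)
}

#' Check that profiles cover every unit-year in an admission table
#'
#' @param profiles A \code{unit_profiles} object.
#' @param adm Admissions data frame.
#' @return Invisibly \code{TRUE}; errors if any unit-year present in
#'   \code{adm} lacks an annual cost entry.
#' @export
check_profile_coverage <- function(profiles, adm) {
  uy <- unique(adm[c("unit_id", "year")])
  key <- paste(profiles$costs$unit_id, profiles$costs$year)
  miss <- !(paste(uy$unit_id, uy$year) %in% key)
  if (any(miss)) {
    stop("no annual cost entry for unit-year(s): ",
         paste(paste(uy$unit_id[miss], uy$year[miss]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Apply the study exclusion cascade
#'
#' Reduces a raw admission table to the analysis cohort: emergency,
#' non-transfer first admissions with a known hospital discharge status and
#' non-missing TISS, sex and GCS. Exclusion reasons are tested in a fixed
#' order (transfer, non-emergency, unknown discharge status, readmission,
#' missing TISS, missing sex, missing GCS, organ donor) and the first
#' matching reason is logged per excluded admission.
#'
#' Admissions flagged as potential organ donors are handled according to
#' \code{donor_policy}:
#' \describe{
#'   \item{\code{"exclude"}}{donors removed entirely (the primary analysis);}
#'   \item{\code{"resources_only"}}{donors retained and flagged, so that
#'     downstream stages count their resource use (length of stay, TISS,
#'     cost share) but never count them as survivors nor include them in
#'     mortality tallies;}
#'   \item{\code{"include"}}{donors retained as ordinary admissions.}
#' }
#'
#' @param adm Validated admissions data frame.
#' @param donor_policy One of \code{"exclude"}, \code{"resources_only"},
#'   \code{"include"}.
#' @return A list with \code{cohort} (the retained admissions, with the
#'   donor policy recorded in attribute \code{donor_policy}) and
#'   \code{log} (data frame \code{admission_id}, \code{reason}).
#' @export
apply_exclusions <- function(adm,
                             donor_policy = c("exclude", "resources_only",
                                              "include")) {
  donor_policy <- match.arg(donor_policy)
  reason <- rep(NA_character_, nrow(adm))
  mark <- function(cond, r) {
    hit <- is.na(reason) & cond
    reason[hit] <<- r
  }
  mark(adm$icu_transfer_in, "TRANSFER")
  mark(adm$admission_type != "EMERGENCY", "NON_EMERGENCY")
  mark(is.na(adm$died_in_hospital), "UNKNOWN_DISCHARGE")
  mark(adm$readmission, "READMISSION")
  mark(is.na(adm$tiss_total), "MISSING_TISS")
  mark(is.na(adm$sex), "MISSING_SEX")
  mark(is.na(adm$gcs), "MISSING_GCS")
  if (donor_policy == "exclude") mark(adm$organ_donor, "ORGAN_DONOR")

  keep <- is.na(reason)
  cohort <- adm[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  attr(cohort, "donor_policy") <- donor_policy
  log <- data.frame(admission_id = adm$admission_id[!keep],
                    reason = factor(reason[!keep], levels = EXCLUSION_REASONS),
                    stringsAsFactors = FALSE)
  list(cohort = cohort, log = log)
}

#' Select a diagnostic subgroup of a cohort
#'
#' @param cohort Admissions data frame (typically the output of
#'   \code{\link{apply_exclusions}}).
#' @param group A subgroup label: one of the five diagnosis groups,
#'   \code{"NEURO_ALL"} (union of the four neurosurgical groups),
#'   \code{"NON_NEURO"} (the \code{OTHER} group) or \code{"ALL"}.
#' @return The subset of \code{cohort} in the subgroup, attributes
#'   preserved.
#' @export
subgroup_filter <- function(cohort, group) {
  if (!(group %in% SUBGROUP_LABELS)) stop("unknown subgroup label: ", group)
  keep <- switch(group,
                 ALL = rep(TRUE, nrow(cohort)),
                 NEURO_ALL = cohort$diagnosis_group %in% NEURO_GROUPS,
                 NON_NEURO = cohort$diagnosis_group == "OTHER",
                 cohort$diagnosis_group == group)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "donor_policy") <- attr(cohort, "donor_policy")
  out
}
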