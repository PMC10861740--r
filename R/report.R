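# Report formatting, table export and run manifests.

#' Report-style rounding of a percentage
#'
#' Percentages are reported to one decimal place below 10% and to the
#' nearest integer at 10% and above; euro amounts to the nearest integer.
#'
#' @param pct Numeric percentage values (already on the 0-100 scale).
#' @return Numeric vector rounded per the reporting rule.
#' @examples
#' fmt_pct(c(9.315, 12.558))  # 9.3, 13
#' @export
fmt_pct <- function(pct) {
  ifelse(abs(pct) < 10, round(pct, 1), round(pct))
}

#' Percentage of a numerator/denominator pair, report-rounded
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @return \code{fmt_pct(100 * num / den)}.
#' @examples
#' report_percent(574, 6162)   # 9.3
#' report_percent(2514, 6162)  # 41
#' @export
report_percent <- function(num, den) {
  if (any(den <= 0)) stop("denominator must be positive")
  fmt_pct(100 * num / den)
}

#' Exclusion-flow accounting
#'
#' Per-reason counts of the exclusion cascade, in cascade order, plus the
#' retained cohort size — the accounting needed to draw a study flow
#' chart.
#'
#' @param log Exclusion log from \code{\link{apply_exclusions}}.
#' @param n_input Number of admissions entering the cascade.
#' @return Data frame with \code{step}, \code{n}.
#' @export
exclusion_flow <- function(log, n_input) {
  counts <- table(log$reason)
  data.frame(step = c("input", names(counts), "cohort"),
             n = c(n_input, as.integer(counts), n_input - nrow(log)),
             stringsAsFactors = FALSE)
}

#' Export benchmark results as tidy CSV and JSON
#'
#' Writes \code{benchmark.csv} (one row per unit x subgroup x measure x
#' donor policy with all observed/expected fields) and a JSON mirror
#' \code{benchmark.json}.
#'
#' @param benchmark An \code{\link{icu_benchmark}}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "icu_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "benchmark.csv")
  utils::write.csv(benchmark$results, csv, row.names = FALSE, na = "NA")
  js <- file.path(dir, "benchmark.json")
  jsonlite::write_json(benchmark$results, js, dataframe = "rows",
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(csv, js))
}

#' Export association estimates as CSV
#'
#' @param assoc A \code{srur_association} table.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_association <- function(assoc, path) {
  utils::write.csv(as.data.frame(assoc), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Build a run manifest
#'
#' Records what a pipeline run consisted of: a stable hash of the
#' configuration, the seed(s), donor policies and subgroups run, package
#' version, timestamp, and every output file written. Identical
#' configurations yield identical hashes.
#'
#' @param config Any R object describing the run configuration.
#' @param seed Seed(s) used.
#' @param donor_policies,subgroups What was run.
#' @param outputs Character vector of output file paths.
#' @return A list of class \code{run_manifest}.
#' @export
run_manifest <- function(config, seed, donor_policies, subgroups, outputs) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  hash <- unname(tools::md5sum(tmp))
  structure(list(config_hash = hash, seed = seed,
                 donor_policies = donor_policies, subgroups = subgroups,
                 package_version = as.character(utils::packageVersion("icubench")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 outputs = as.character(outputs)),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A \code{run_manifest}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
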