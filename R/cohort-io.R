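# Cohort directories of delimited text: one CSV per table, UTF-8, header row.
# physiology.csv is long format (patient_id, signal, minute 0-239, value) with
# missing values written as empty fields.

#' Write a cohort to a directory of CSV files
#'
#' @param cohort an `icu_cohort`.
#' @param dir output directory (created if needed).
#' @param clinicians optional `clinician_predictions` to write alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, clinicians = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file)
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE,
              na = "")
  wr(cohort$admission, "admission.csv")
  wr(cohort$medications, "medications.csv")
  wr(cohort$labs, "labs.csv")
  wr(cohort$fluids, "fluids.csv")
  wr(cohort$outcomes, "outcomes.csv")
  id <- cohort$admission$patient_id
  phys <- do.call(rbind, lapply(names(cohort$signals), function(s) {
    m <- cohort$signals[[s]]
    data.frame(patient_id = rep(id, each = ncol(m)), signal = s,
               minute = rep(0:(ncol(m) - 1), length(id)),
               value = as.vector(t(m)), stringsAsFactors = FALSE)
  }))
  wr(phys, "physiology.csv")
  if (!is.null(clinicians)) wr(clinicians, "clinicians.csv")
  meta <- list(label = cohort$label,
               config = unclass(cohort$config))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' @param dir a directory written by [write_cohort()].
#' @return an `icu_cohort` (without the latent truth table, which is not part
#'   of the on-disk interchange format).
#' @export
read_cohort <- function(dir) {
  rd <- function(file) read.csv(file.path(dir, file), stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
  admission <- rd("admission.csv")
  phys <- rd("physiology.csv")
  id <- admission$patient_id
  signals <- lapply(split(phys, phys$signal), function(d) {
    m <- matrix(NA_real_, length(id), max(d$minute) + 1, dimnames = list(id, NULL))
    m[cbind(match(d$patient_id, id), d$minute + 1)] <- d$value
    m
  })
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  cfg <- meta$config
  config <- generator_config(
    n_patients = cfg$n_patients, seed = cfg$seed,
    missing_rate = cfg$missing_rate, artifact_rate = cfg$artifact_rate,
    prevalence_day2 = cfg$prevalence_day2,
    los_dispersion = cfg$los_dispersion, severity_slope = cfg$severity_slope,
    effect_sizes = unlist(cfg$effect_sizes), residual_sd = cfg$residual_sd,
    mortality_rate = cfg$mortality_rate, label = cfg$label)
  cl <- file.path(dir, "clinicians.csv")
  structure(list(admission = admission, medications = rd("medications.csv"),
                 labs = rd("labs.csv"),
                 signals = signals[SIGNAL_NAMES],
                 fluids = rd("fluids.csv"), outcomes = rd("outcomes.csv"),
                 latent = NULL, label = meta$label, config = config),
            class = "icu_cohort")
}
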