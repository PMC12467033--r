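#' @importFrom utils read.csv
NULL

# column schemas per table kind; names are the required headers
.table_schemas <- list(
  kinetics = c("inhibitor_ug_per_ml", "substrate_mmol_per_l",
               "velocity_dod_per_min"),
  titration = c("temperature_k", "quencher_mol_per_l", "intensity"),
  dose_response = c("concentration_ug_per_ml", "inhibition_percent"),
  vant_hoff = c("temperature_k", "ka_l_per_mol"),
  ftir = c("wavenumber_cm_1", "absorbance"),
  reversibility = c("inhibitor_ug_per_ml", "enzyme_u_per_l",
                    "velocity_dod_per_min")
)

check_numeric_cols <- function(df, cols) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(num <- as.numeric(as.character(v)))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(as.character(v))))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
      df[[col]] <- num
    }
    if (any(!is.finite(df[[col]])))
      stop(sprintf("missing or non-finite value in column '%s' at row %d",
                   col, which(!is.finite(df[[col]]))[1]))
  }
  df
}

#' Load an assay table from CSV
#'
#' Reads a CSV with a fixed, documented header for one of the supported
#' assay kinds and returns validated, typed records.  Row order is
#' preserved; all error messages use 1-based data-row indices.
#'
#' Supported schemas and their required columns:
#' \describe{
#'   \item{`kinetics`}{`inhibitor_ug_per_ml`, `substrate_mmol_per_l`,
#'     `velocity_dod_per_min` — returns a list of [kinetic_series()]
#'     objects, one per inhibitor concentration.}
#'   \item{`titration`}{`temperature_k`, `quencher_mol_per_l`, `intensity`
#'     (optional `a_ex`, `a_em`) — returns a list of [quench_titration()]
#'     objects, one per temperature.}
#'   \item{`dose_response`}{`concentration_ug_per_ml`, `inhibition_percent`
#'     (optional `sd_percent`) — returns a [dose_response_series()].}
#'   \item{`vant_hoff`}{`temperature_k`, `ka_l_per_mol` — returns a
#'     data frame.}
#'   \item{`ftir`}{`wavenumber_cm_1`, `absorbance` — returns an
#'     [ftir_spectrum()].}
#'   \item{`reversibility`}{`inhibitor_ug_per_ml`, `enzyme_u_per_l`,
#'     `velocity_dod_per_min` — returns a list of [reversibility_series()].}
#' }
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @param schema One of the schema labels above.
#' @return Typed records as described above.
#' @export
load_table <- function(path, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty table: %s", path))
  need <- .table_schemas[[schema]]
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing, collapse = ", ")))
  opt <- intersect(c("a_ex", "a_em", "sd_percent"), names(df))
  df <- check_numeric_cols(df, c(need, opt))
  switch(schema,
    kinetics = {
      split_f <- factor(df$inhibitor_ug_per_ml,
                        levels = unique(df$inhibitor_ug_per_ml))
      lapply(split(df, split_f), function(d)
        kinetic_series(inhibitor_conc = d$inhibitor_ug_per_ml[1],
                       substrate = d$substrate_mmol_per_l,
                       velocity = d$velocity_dod_per_min))
    },
    titration = {
      split_f <- factor(df$temperature_k, levels = unique(df$temperature_k))
      lapply(split(df, split_f), function(d)
        quench_titration(temperature = d$temperature_k[1],
                         Q = d$quencher_mol_per_l,
                         Fobs = d$intensity,
                         Aex = if ("a_ex" %in% names(d)) d$a_ex else NULL,
                         Aem = if ("a_em" %in% names(d)) d$a_em else NULL))
    },
    dose_response = dose_response_series(
      concentration = df$concentration_ug_per_ml,
      inhibition = df$inhibition_percent,
      replicate_sd = if ("sd_percent" %in% names(df)) df$sd_percent else NULL),
    vant_hoff = {
      if (any(df$ka_l_per_mol <= 0))
        stop(sprintf("non-positive Ka at row %d",
                     which(df$ka_l_per_mol <= 0)[1]))
      data.frame(temperature_k = df$temperature_k,
                 ka_l_per_mol = df$ka_l_per_mol)
    },
    ftir = ftir_spectrum(df$wavenumber_cm_1, df$absorbance),
    reversibility = {
      split_f <- factor(df$inhibitor_ug_per_ml,
                        levels = unique(df$inhibitor_ug_per_ml))
      lapply(split(df, split_f), function(d)
        reversibility_series(inhibitor_conc = d$inhibitor_ug_per_ml[1],
                             enzyme_activity = d$enzyme_u_per_l,
                             velocity = d$velocity_dod_per_min))
    })
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else x
}

#' Write a machine-readable analysis report
#'
#' Serializes any collection of stage results (fits, classifications,
#' configuration) to JSON.  Output is deterministic: identical inputs yield
#' byte-identical files.
#'
#' @param results A (possibly nested) list of results; classed fit objects
#'   are flattened to plain lists.
#' @param path Output file path.
#' @param config Optional [analysis_config()] echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  payload <- list(results = strip_classes(results))
  if (!is.null(config)) payload$config <- strip_classes(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Published apparent kinetic constants
#'
#' Apparent Michaelis constants and maximum velocities for six porphyrin
#' inhibitors against alpha-amylase and alpha-glucosidase at a series of
#' inhibitor concentrations, as published.  These feed the secondary-plot
#' estimators [estimate_ki()] / [estimate_kis()] and
#' [classify_inhibition()].
#'
#' @param enzyme Optional filter, `"alpha_amylase"` or `"alpha_glucosidase"`.
#' @param compound Optional compound-name filter.
#' @return Data frame with columns `enzyme`, `compound`,
#'   `inhibitor_ug_per_ml`, `km_app_mmol_per_l`, `vmax_app_dod_per_min`.
#' @export
#' @examples
#' head(kinetic_constants("alpha_amylase", "TAPP"))
kinetic_constants <- function(enzyme = NULL, compound = NULL) {
  df <- read.csv(system.file("extdata", "kinetic_constants.csv",
                             package = "enzbind"), stringsAsFactors = FALSE)
  if (!is.null(enzyme)) df <- df[df$enzyme == enzyme, ]
  if (!is.null(compound)) df <- df[df$compound == compound, ]
  row.names(df) <- NULL
  df
}

#' Published quenching and binding constants
#'
#' Stern-Volmer constants, binding-site numbers and binding constants at
#' three temperatures for six porphyrin inhibitors against alpha-amylase
#' and alpha-glucosidase, as published.  These feed [classify_mechanism()]
#' and [vant_hoff_fit()].
#'
#' @inheritParams kinetic_constants
#' @return Data frame with columns `enzyme`, `compound`, `temperature_k`,
#'   `ksv_1e4_l_per_mol`, `n_sites`, `ka_1e5_l_per_mol`.
#' @export
#' @examples
#' quench_binding_constants("alpha_glucosidase", "THPP")
quench_binding_constants <- function(enzyme = NULL, compound = NULL) {
  df <- read.csv(system.file("extdata", "quench_binding_constants.csv",
                             package = "enzbind"), stringsAsFactors = FALSE)
  if (!is.null(enzyme)) df <- df[df$enzyme == enzyme, ]
  if (!is.null(compound)) df <- df[df$compound == compound, ]
  row.names(df) <- NULL
  df
}
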