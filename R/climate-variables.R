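#' The 20 annual climate variables used throughout the package
#'
#' Returns the canonical variable set of the ClimateNA annual summaries:
#' abbreviation, description, unit, and the plausible range used by the
#' synthetic-landscape generator when rescaling simulated fields. MAT and MAP
#' ranges correspond to the climatic envelope of lodgepole pine across British
#' Columbia and Alberta (-7.3 to 10.3 degrees C; 225 to 8769 mm); the remaining
#' ranges are realistic values for the same region.
#'
#' @return A tibble with columns `variable`, `description`, `unit`, `lo`, `hi`
#'   and `group` (`temperature` or `moisture`, used for the default
#'   inter-variable correlation structure) in canonical order.
#' @export
#' @examples
#' climate_variables()
climate_variables <- function() {
  tibble::tribble(
    ~variable, ~description,                                          ~unit,        ~lo,    ~hi,   ~group,        ~sign,
    "MAT",     "mean annual temperature",                             "degC",      -7.3,   10.3,  "temperature",  1,
    "MWMT",    "mean warmest month temperature",                      "degC",       5,     22,    "temperature",  1,
    "MCMT",    "mean coldest month temperature",                      "degC",     -26,      3,    "temperature",  1,
    "TD",      "continentality (MWMT - MCMT)",                        "degC",       4,     35,    "temperature", -1,
    "MAP",     "mean annual precipitation",                           "mm",       225,   8769,    "moisture",     1,
    "MSP",     "mean summer (May-Sept) precipitation",                "mm",       100,   1500,    "moisture",     1,
    "AHM",     "annual heat-moisture index",                          "index",      1,     60,    "moisture",    -1,
    "SHM",     "summer heat-moisture index",                          "index",     10,    150,    "moisture",    -1,
    "DD_0",    "degree-days below 0 degC",                            "degree-days", 0,  3500,    "temperature", -1,
    "DD5",     "degree-days above 5 degC",                            "degree-days", 150, 2500,   "temperature",  1,
    "NFFD",    "number of frost-free days",                           "days",      50,    320,    "temperature",  1,
    "FFP",     "frost-free period",                                   "days",      20,    220,    "temperature",  1,
    "bFFP",    "day of year frost-free period begins",                "day",      100,    200,    "temperature", -1,
    "eFFP",    "day of year frost-free period ends",                  "day",      210,    300,    "temperature",  1,
    "PAS",     "precipitation as snow",                               "mm",        20,   1500,    "moisture",     1,
    "EMT",     "extreme minimum temperature over 30 yr",              "degC",     -55,     -8,    "temperature",  1,
    "EXT",     "extreme maximum temperature over 30 yr",              "degC",      20,     42,    "temperature",  1,
    "Eref",    "Hargreaves reference evaporation",                    "mm",       300,    900,    "moisture",    -1,
    "CMD",     "Hargreaves climatic moisture deficit",                "mm",         0,    700,    "moisture",    -1,
    "RH",      "mean annual relative humidity",                       "%",         50,     80,    "moisture",     1
  )
}

# canonical names in canonical order
climate_variable_names <- function() climate_variables()$variable

# Accepted header aliases for ingestion (case-insensitive; punctuation-variant
# spellings of the degree-day variables).
climate_name_aliases <- function() {
  c(
    "DD<0" = "DD_0", "DD.0" = "DD_0", "DD0" = "DD_0", "DD_0_" = "DD_0",
    "DD>5" = "DD5", "DD_5" = "DD5", "DD.5" = "DD5",
    "EREF" = "Eref", "BFFP" = "bFFP", "EFFP" = "eFFP"
  )
}

# Normalize a vector of column names onto the canonical variable spelling.
normalize_climate_names <- function(nms) {
  canon <- climate_variable_names()
  ali <- climate_name_aliases()
  out <- nms
  for (i in seq_along(nms)) {
    hit <- match(toupper(nms[i]), toupper(canon))
    if (!is.na(hit)) {
      out[i] <- canon[hit]
    } else if (toupper(nms[i]) %in% toupper(names(ali))) {
      out[i] <- ali[[which(toupper(names(ali)) == toupper(nms[i]))[1]]]
    }
  }
  out
}

# Assert that a data frame carries all 20 finite climate columns.
check_climate_columns <- function(df, where = "climate table") {
  canon <- climate_variable_names()
  missing <- setdiff(canon, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s absent from %s", paste(missing, collapse = ", "), where),
         call. = FALSE)
  }
  for (v in canon) {
    if (!is.numeric(df[[v]]) || anyNA(df[[v]]) || any(!is.finite(df[[v]]))) {
      stop(sprintf("climate variable %s has missing or non-finite values", v),
           call. = FALSE)
    }
  }
  invisible(df)
}
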