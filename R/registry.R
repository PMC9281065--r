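#' The default 33-variable feature registry
#'
#' The registry defines the physiological variables a risk score consumes:
#' variable id, category (`vital`, `lab`, `blood_gas`, `ventilation`),
#' units, plausibility range `[lo, hi]` outside which a charted value is
#' treated as an artefact, a staleness limit (how many hours a last
#' observation may be carried forward), and an imputation fallback rule
#' (`none`, `nibp_to_ibp` for filling invasive pressures from their
#' noninvasive counterpart, `fio2_room_air` for defaulting the inspired
#' oxygen fraction to room air). `ref_value`/`ref_sd` are the reference
#' location and scale used by the synthetic cohort generator.
#'
#' The default registry ships as an editable CSV
#' (`system.file("extdata", "feature_registry.csv", package = "hemodyn")`)
#' so a site can substitute its own variable list and bounds.
#'
#' @param path Path to a registry CSV. Defaults to the bundled registry.
#' @return A tibble of class `hd_registry` with one row per variable.
#' @examples
#' reg <- default_registry()
#' nrow(reg)  # 33
#' @export
default_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_registry.csv", package = "hemodyn")
  read_registry(path)
}

#' @rdname default_registry
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  reg <- as_tibble(reg)
  validate_registry(reg)
  class(reg) <- c("hd_registry", class(reg))
  reg
}

validate_registry <- function(reg) {
  needed <- c("variable", "category", "units", "lo", "hi", "staleness_h", "fallback")
  missing_cols <- setdiff(needed, names(reg))
  check_field(length(missing_cols) == 0, "registry",
              paste("missing columns:", paste(missing_cols, collapse = ", ")))
  check_field(!anyDuplicated(reg$variable), "variable", "duplicated variable ids")
  check_field(all(reg$lo < reg$hi), "lo/hi", "plausibility range must have lo < hi")
  check_field(all(reg$staleness_h > 0), "staleness_h", "must be positive")
  check_field(all(reg$category %in% c("vital", "lab", "blood_gas", "ventilation")),
              "category", "unknown category")
  check_field(all(reg$fallback %in% c("none", "nibp_to_ibp", "fio2_room_air")),
              "fallback", "unknown fallback rule")
  invisible(reg)
}

#' Vasoactive agent name dictionary
#'
#' Maps brand and generic inotrope/vasopressor names (case-insensitively) to
#' canonical agent ids, e.g. `"Levophed"` to `norepinephrine` and
#' `"Neosynephrine"` to `phenylephrine`. The dictionary is a data file and
#' can be replaced per site.
#'
#' @param path Path to a two-column CSV (`raw_name`, `canonical`). Defaults
#'   to the bundled dictionary.
#' @return A tibble with columns `raw_name`, `canonical`.
#' @export
agent_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "agent_dictionary.csv", package = "hemodyn")
  dict <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_field(all(c("raw_name", "canonical") %in% names(dict)),
              "agent_dictionary", "needs raw_name and canonical columns")
  dict$raw_name <- tolower(dict$raw_name)
  as_tibble(dict)
}
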