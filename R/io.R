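# Plain-text I/O: micro records, profiles, panels, weights and configs.

#' Read / write micro records
#'
#' CSV with the documented header: `id`, `adl_1`..`adl_10`, `dep_1`..
#' `dep_10`, `act_1`..`act_8`, `disabled`, `n_chronic`, `x1`..`x12`, plus
#' optional ground-truth columns `truth_y1`..`truth_y4`, `truth_y` written
#' by the generator.
#'
#' @param path File path.
#' @return `read_micro_csv()` returns a `micro_records` data frame.
#' @export
read_micro_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$disabled <- as.logical(d$disabled)
  class(d) <- c("micro_records", "data.frame")
  validate_micro(d)
}

#' @rdname read_micro_csv
#' @param records A `micro_records` data frame.
#' @export
write_micro_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read / write HA profiles
#'
#' CSV columns: `id`, `y1_physical`, `y2_adl`, `y3_mental`, `y4_social`,
#' `y_ha`.
#'
#' @param path File path.
#' @export
read_profiles_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("y1_physical", "y2_adl", "y3_mental", "y4_social", "y_ha"))
    d[[col]] <- as.logical(d[[col]])
  class(d) <- c("ha_profiles", "data.frame")
  d
}

#' @rdname read_profiles_csv
#' @param profiles An `ha_profiles` data frame.
#' @export
write_profiles_csv <- function(profiles, path) {
  write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a regional panel
#'
#' CSV columns: `region`, `year`, `mean_schooling_years`,
#' `urbanization_rate`, `households`, `population`,
#' `old_age_dependency_ratio`.
#'
#' @param path File path.
#' @export
read_panel_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "mean_schooling_years", "urbanization_rate",
            "households", "population", "old_age_dependency_ratio")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_input(paste("panel is missing columns:", paste(miss, collapse = ", ")))
  class(d) <- c("regional_panel", "data.frame")
  d
}

#' @rdname read_panel_csv
#' @param panel A `regional_panel` data frame.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read / write F-W weights as JSON
#'
#' @param path File path.
#' @export
read_weights_json <- function(path) {
  w <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  wn <- fw_weight_names()
  if (!all(wn %in% names(w)))
    stop_input(paste("weights file must name:", paste(wn, collapse = ", ")))
  structure(setNames(as.numeric(w[wn]), wn),
            class = c("fw_weights", "numeric"), beta = NULL, signed = FALSE)
}

#' @rdname read_weights_json
#' @param weights An `fw_weights` object.
#' @export
write_weights_json <- function(weights, path) {
  jsonlite::write_json(as.list(setNames(as.numeric(weights), names(weights))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Read a run/generator config from JSON (or YAML when the yaml package is
# available).
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("YAML configs need the `yaml` package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Packaged default economic-zone mapping
#'
#' An editable region-to-zone partition of China's 30 yearbook provinces
#' into eight economic zones. The Beijing-Tianjin-Hebei, Yangtze River Delta
#' and Pearl River Delta cores follow the published usage; the remaining
#' memberships are package defaults and can be replaced by pointing
#' [aggregate_zones()] at any two-column CSV.
#'
#' @return Data frame with columns `region`, `zone`.
#' @export
default_zone_map <- function() {
  read.csv(system.file("extdata", "economic_zones.csv", package = "fwaging"),
           stringsAsFactors = FALSE)
}
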