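#' Substance/dose categories and the default station layout
#'
#' A six-station home cage offers two water stations and one station each of
#' ethanol 5%, ethanol 10%, fentanyl 5 ug/ml and fentanyl 20 ug/ml. Each
#' station maps to one of five substance/dose categories ("chambers"); water
#' is duplicated so both long walls carry it.
#'
#' @return `sip_chambers()` returns a tibble with one row per substance/dose
#'   category: `chamber` (short key), `substance` (water/ethanol/fentanyl),
#'   `dose_label`, and `high_dose` (logical, `NA` for water).
#'   `default_station_map()` returns the six-station tibble with columns
#'   `station`, `substance`, `dose_label`, `chamber`.
#' @examples
#' sip_chambers()
#' default_station_map()
#' @export
sip_chambers <- function() {
  tibble::tibble(
    chamber    = c("water", "etoh_5", "etoh_10", "fent_5", "fent_20"),
    substance  = c("water", "ethanol", "ethanol", "fentanyl", "fentanyl"),
    dose_label = c("none", "5%", "10%", "5ug", "20ug"),
    high_dose  = c(NA, FALSE, TRUE, FALSE, TRUE)
  )
}

#' @rdname sip_chambers
#' @export
default_station_map <- function() {
  tibble::tibble(
    station    = paste0("S", 1:6),
    substance  = c("water", "ethanol", "ethanol", "water", "fentanyl", "fentanyl"),
    dose_label = c("none", "5%", "10%", "none", "5ug", "20ug")
  ) |>
    dplyr::left_join(sip_chambers(), by = c("substance", "dose_label")) |>
    dplyr::select("station", "substance", "dose_label", "chamber")
}

# validate a station map: unique stations, known categories
validate_station_map <- function(stations) {
  stopifnot(is.data.frame(stations))
  req <- c("station", "substance", "dose_label")
  missing <- setdiff(req, names(stations))
  if (length(missing) > 0) {
    stop("station map is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(stations$station)) {
    stop("station map has duplicated station ids", call. = FALSE)
  }
  out <- dplyr::left_join(
    tibble::as_tibble(stations)[req],
    sip_chambers()[c("substance", "dose_label", "chamber")],
    by = c("substance", "dose_label")
  )
  if (anyNA(out$chamber)) {
    bad <- out$station[is.na(out$chamber)]
    stop("unknown substance/dose at station(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

# behavior battery column names (open field box + elevated zero maze)
behavior_params <- function() {
  c("OFB_distance", "OFB_speed", "OFB_CT", "OFB_CE", "OFB_CL", "OFB_CD",
    "EZM_distance", "EZM_speed", "EZM_OAT", "EZM_OAE", "EZM_OAL", "EZM_OAD")
}
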