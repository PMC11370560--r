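#' Two-bottle-choice preference indices
#'
#' `substance_preference()` computes, per animal, the classic volume-ratio
#' preference of a drug over water, `V_drug / (V_drug + V_water)`, with
#' both doses of the drug summed and both water stations summed.
#' `dose_preference()` computes the within-drug dose preference
#' `V_high / (V_high + V_low)` (high = ethanol 10% or fentanyl 20 ug/ml).
#' 0.5 is indifference. When the denominator is zero the index is
#' undefined (`NA`, `defined = FALSE`); undefined animals are excluded
#' from group statistics rather than imputed at indifference.
#'
#' Both indices are invariant to rescaling all volumes (body-weight
#' normalization cancels).
#'
#' @param intake An [aggregate_intake()] table at `"total"` or `"day"`
#'   granularity.
#' @param substance `"ethanol"` or `"fentanyl"`.
#' @param scope `"total"` for one index per animal over the whole
#'   observation, or `"day"` for one per animal per day (requires a
#'   day-granularity table).
#' @return Tibble `tag`, `kind`, `scope` (`"total"` or the day number),
#'   `value`, `defined`.
#' @examples
#' fx <- simulate_sip(sip_config(n_males = 4, n_females = 4, n_days = 2))
#' events <- assign_drinks(fx$vdm, collapse_visits(fx$rfid),
#'                         fx$animals, fx$stations)
#' intake <- aggregate_intake(events, fx$animals, "total")
#' substance_preference(intake, "ethanol")
#' @export
substance_preference <- function(intake, substance = c("ethanol", "fentanyl"),
                                 scope = c("total", "day")) {
  substance <- match.arg(substance)
  scope <- match.arg(scope)
  num <- function(df) df$substance == substance
  den <- function(df) df$substance %in% c(substance, "water")
  preference_index(intake, scope, num, den,
                   kind = paste0(substance, "/water"))
}

#' @rdname substance_preference
#' @export
dose_preference <- function(intake, substance = c("ethanol", "fentanyl"),
                            scope = c("total", "day")) {
  substance <- match.arg(substance)
  scope <- match.arg(scope)
  doses <- sip_chambers()
  doses <- doses[doses$substance == substance, ]
  if (nrow(doses) != 2) {
    stop(substance, " does not offer exactly two doses", call. = FALSE)
  }
  high <- doses$chamber[which(doses$high_dose)]
  num <- function(df) df$chamber == high
  den <- function(df) df$substance == substance
  preference_index(intake, scope, num, den,
                   kind = paste0(substance, "-dose"))
}

preference_index <- function(intake, scope, num, den, kind) {
  if (scope == "day" && !"day" %in% names(intake)) {
    stop("day-scope preference needs a day-granularity intake table",
         call. = FALSE)
  }
  keys <- c("tag", if (scope == "day") "day")
  intake |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      v_num = sum(.data$volume_ul[num(dplyr::pick(dplyr::everything()))]),
      v_den = sum(.data$volume_ul[den(dplyr::pick(dplyr::everything()))]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      kind = kind,
      scope = if (scope == "day") as.character(.data$day) else "total",
      value = ifelse(.data$v_den > 0, .data$v_num / .data$v_den, NA_real_),
      defined = .data$v_den > 0
    ) |>
    dplyr::select(dplyr::all_of(c("tag", if (scope == "day") "day",
                                  "kind", "scope", "value", "defined")))
}
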