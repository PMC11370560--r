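#' Zeitgeber time of an experiment timestamp
#'
#' The experiment clock starts at lights-on, so ZT0 of day 1 is `t = 0`;
#' ZT 0-12 is the light phase and ZT 12-24 the dark phase of a 12:12
#' cycle. Bins are half-open: an event exactly at a boundary belongs to
#' the later bin.
#'
#' @param t_sec Numeric vector of timestamps, seconds since experiment
#'   start; must be nonnegative.
#' @return Tibble `day` (1-based), `zt` (integer hour 0-23), `phase`
#'   (`"light"`/`"dark"`).
#' @examples
#' zt_of(c(0, 13 * 3600, 25 * 3600))
#' @export
zt_of <- function(t_sec) {
  if (any(t_sec < 0)) stop("timestamps must be nonnegative", call. = FALSE)
  day <- as.integer(floor(t_sec / 86400)) + 1L
  zt <- as.integer(floor((t_sec %% 86400) / 3600))
  tibble::tibble(
    day = day,
    zt = zt,
    phase = ifelse(zt < 12, "light", "dark")
  )
}

intake_granularities <- c("total", "day", "phase", "day_zt")

#' Aggregate attributed drink events into an intake table
#'
#' Sums consumed volume per animal and substance/dose chamber at the
#' requested granularity and computes body-weight normalized intake in
#' ml/kg (`volume_ul / body_weight_g`). Every animal x chamber x bin cell
#' is present (zero-filled), so day-by-ZT tables are dense heat-map
#' matrices. Unassigned events (`tag` `NA`) are excluded and counted in
#' the `n_excluded` attribute.
#'
#' @param events Drink events from [assign_drinks()].
#' @param roster Roster tibble with `tag` and `body_weight_g`.
#' @param granularity One of `"total"`, `"day"`, `"phase"`, `"day_zt"`.
#' @param n_days Number of observation days for zero-filling; defaults to
#'   the last day seen in `events` (1 if empty).
#' @return Tibble with `tag, substance, dose_label, chamber`, the bin
#'   columns implied by `granularity` (`day`, `phase`, `zt`), `volume_ul`
#'   and `intake_ml_kg`.
#' @export
aggregate_intake <- function(events, roster,
                             granularity = c("total", "day", "phase", "day_zt"),
                             n_days = NULL) {
  granularity <- match.arg(granularity)
  bad <- setdiff(unique(events$tag[!is.na(events$tag)]), roster$tag)
  if (length(bad) > 0) {
    stop("events carry tag(s) absent from roster: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_excluded <- sum(is.na(events$tag))
  ev <- events[!is.na(events$tag), , drop = FALSE]
  if (is.null(n_days)) {
    n_days <- if (nrow(ev) > 0) max(zt_of(ev$t_sec)$day) else 1L
  }
  ev <- dplyr::bind_cols(ev, zt_of(ev$t_sec))

  bins <- switch(granularity,
    total = list(),
    day = list(day = seq_len(n_days)),
    phase = list(phase = c("light", "dark")),
    day_zt = list(day = seq_len(n_days), zt = 0:23)
  )
  frame <- tidyr::expand_grid(
    tag = roster$tag,
    chamber = sip_chambers()$chamber,
    !!!bins
  )
  keys <- c("tag", "chamber", names(bins))
  agg <- ev |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(volume_ul = sum(.data$volume_ul), .groups = "drop")
  out <- frame |>
    dplyr::left_join(agg, by = keys) |>
    dplyr::mutate(volume_ul = dplyr::coalesce(.data$volume_ul, 0)) |>
    dplyr::left_join(sip_chambers()[c("chamber", "substance", "dose_label")],
                     by = "chamber") |>
    dplyr::left_join(roster[c("tag", "body_weight_g")], by = "tag") |>
    dplyr::mutate(intake_ml_kg = .data$volume_ul / .data$body_weight_g)
  if (granularity == "day_zt") {
    out$phase <- ifelse(out$zt < 12, "light", "dark")
  }
  out <- out |>
    dplyr::select(dplyr::all_of(c(
      "tag", "substance", "dose_label", "chamber", names(bins),
      if (granularity == "day_zt") "phase", "volume_ul", "intake_ml_kg"
    )))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "granularity") <- granularity
  attr(out, "n_days") <- n_days
  out
}

#' Time spent in the drinking chambers
#'
#' Sums visit-bout durations per animal at the requested granularity.
#' Bouts spanning a bin boundary are split at the boundary, so summed
#' seconds are conserved exactly at every granularity; a visit is counted
#' in the bin containing its start.
#'
#' @param bouts Visit bouts from [collapse_visits()], sorted by `t_start`.
#' @inheritParams aggregate_intake
#' @return Tibble `tag`, bin columns, `seconds`, `n_visits`.
#' @export
chamber_occupancy <- function(bouts,
                              granularity = c("total", "day", "phase", "day_zt"),
                              n_days = NULL) {
  granularity <- match.arg(granularity)
  if (is.null(n_days)) {
    n_days <- if (nrow(bouts) > 0) max(zt_of(bouts$t_end)$day) else 1L
  }
  if (nrow(bouts) == 0) {
    pieces <- tibble::tibble(tag = character(), t_start = double(),
                             hour = integer(), seconds = double(),
                             is_first = logical())
  } else {
    h1 <- floor(bouts$t_start / 3600)
    h2 <- floor(bouts$t_end / 3600)
    nbin <- as.integer(h2 - h1 + 1)
    hour <- as.integer(rep(h1, nbin) + sequence(nbin) - 1)
    t_start <- rep(bouts$t_start, nbin)
    t_end <- rep(bouts$t_end, nbin)
    pieces <- tibble::tibble(
      tag = rep(bouts$tag, nbin),
      hour = hour,
      seconds = pmin(t_end, (hour + 1) * 3600) - pmax(t_start, hour * 3600),
      is_first = sequence(nbin) == 1L
    )
  }
  pieces$day <- pieces$hour %/% 24L + 1L
  pieces$zt <- pieces$hour %% 24L
  pieces$phase <- ifelse(pieces$zt < 12, "light", "dark")

  bins <- switch(granularity,
    total = list(),
    day = list(day = seq_len(n_days)),
    phase = list(phase = c("light", "dark")),
    day_zt = list(day = seq_len(n_days), zt = 0:23)
  )
  keys <- c("tag", names(bins))
  frame <- tidyr::expand_grid(tag = unique(bouts$tag), !!!bins)
  agg <- pieces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(seconds = sum(.data$seconds),
                     n_visits = sum(.data$is_first), .groups = "drop")
  frame |>
    dplyr::left_join(agg, by = keys) |>
    dplyr::mutate(
      seconds = dplyr::coalesce(.data$seconds, 0),
      n_visits = dplyr::coalesce(.data$n_visits, 0L)
    )
}

#' Group-mean day-by-ZT heat-map matrix
#'
#' Averages a dense day-by-ZT intake (or occupancy) table over the animals
#' of each group, yielding one `n_days x 24` matrix per substance chamber
#' per group in long format.
#'
#' @param table A `day_zt`-granularity table from [aggregate_intake()] (or
#'   [chamber_occupancy()]; then no `chamber` column is produced).
#' @param groups Tibble `tag, group` mapping each animal to a group (sex
#'   or phenotype cluster).
#' @param value Name of the value column to average (default
#'   `"intake_ml_kg"`).
#' @return Long tibble `group, chamber?, day, zt, value` (group means,
#'   zero-filled).
#' @export
heatmap_matrix <- function(table, groups, value = "intake_ml_kg") {
  stopifnot(all(c("day", "zt") %in% names(table)),
            all(c("tag", "group") %in% names(groups)),
            value %in% names(table))
  missing <- setdiff(unique(table$tag), groups$tag)
  if (length(missing) > 0) {
    stop("no group for tag(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keys <- intersect(c("group", "chamber", "day", "zt"),
                    c("group", "day", "zt", names(table)))
  table |>
    dplyr::inner_join(groups[c("tag", "group")], by = "tag") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(value = mean(.data[[value]]), .groups = "drop")
}
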