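#' Read the raw acquisition streams and configuration tables
#'
#' The acquisition system produces two CSV streams on a common clock:
#' `rfid.csv` (`t_sec,antenna,tag`), the antenna reads collected nominally
#' at 100 Hz while a tagged animal is at a drinking station, and `vdm.csv`
#' (`t_sec,station,volume_ul`), the 1 Hz volumetric drinking-monitor rows.
#' `read_roster()` parses `animals.csv` (`tag,sex,body_weight_g,cage`) and
#' `read_station_map()` parses `stations.csv` (`station,substance,dose_label`).
#' All readers require a header, use `.` decimals, and return streams
#' stably sorted by time.
#'
#' @param path Path to a CSV file.
#' @return A tibble; see the schemas above.
#' @export
read_rfid_stream <- function(path) {
  df <- read_checked_csv(path, cols = list(
    t_sec = "numeric", antenna = "character", tag = "character"
  ))
  if (any(df$t_sec < 0)) {
    stop("rfid stream has negative timestamps", call. = FALSE)
  }
  df[order(df$t_sec), ]
}

#' @rdname read_rfid_stream
#' @export
read_vdm_stream <- function(path) {
  df <- read_checked_csv(path, cols = list(
    t_sec = "numeric", station = "character", volume_ul = "numeric"
  ))
  if (any(df$t_sec < 0)) {
    stop("vdm stream has negative timestamps", call. = FALSE)
  }
  if (any(df$volume_ul < 0)) {
    bad <- which(df$volume_ul < 0)[1]
    stop("vdm stream has negative volume at data row ", bad, call. = FALSE)
  }
  df[order(df$t_sec), ]
}

#' @rdname read_rfid_stream
#' @export
read_roster <- function(path) {
  df <- read_checked_csv(path, cols = list(
    tag = "character", sex = "character",
    body_weight_g = "numeric", cage = "character"
  ))
  if (!all(df$sex %in% c("M", "F"))) {
    stop("roster sex must be 'M' or 'F'", call. = FALSE)
  }
  if (any(df$body_weight_g <= 0)) {
    stop("roster body weights must be positive", call. = FALSE)
  }
  df
}

#' @rdname read_rfid_stream
#' @export
read_station_map <- function(path) {
  df <- read_checked_csv(path, cols = list(
    station = "character", substance = "character", dose_label = "character"
  ))
  validate_station_map(df)
}

# strict CSV reader: exact column set, typed parse errors with row numbers
read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(names(cols), names(df))
  extra <- setdiff(names(df), names(cols))
  if (length(missing) > 0 || length(extra) > 0) {
    stop(sprintf(
      "%s: expected columns {%s}; missing {%s}; unexpected {%s}",
      basename(path), paste(names(cols), collapse = ","),
      paste(missing, collapse = ","), paste(extra, collapse = ",")
    ), call. = FALSE)
  }
  df <- df[names(cols)]
  for (nm in names(cols)) {
    if (cols[[nm]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[nm]]))
      if (anyNA(v) && !all(is.na(df[[nm]]) == is.na(v))) {
        bad <- which(is.na(v) & !is.na(df[[nm]]))[1]
        stop(sprintf("%s: cannot parse '%s' as a number in column %s, data row %d",
                     basename(path), df[[nm]][bad], nm, bad), call. = FALSE)
      }
      if (anyNA(v)) {
        stop(sprintf("%s: missing value in column %s", basename(path), nm),
             call. = FALSE)
      }
      df[[nm]] <- v
    }
  }
  tibble::as_tibble(df)
}

#' Collapse RFID reads into visit bouts
#'
#' A visit bout is a maximal run of reads of one tag at one antenna in
#' which successive reads are no more than `max_gap` seconds apart. Bout
#' start/end are the first/last observed read times (closed interval: both
#' endpoints are observed detections).
#'
#' @param reads Tibble `t_sec, antenna, tag`, sorted by `t_sec`.
#' @param max_gap Maximum within-bout gap between successive reads of the
#'   same tag at the same antenna, seconds. Default 1.0 bridges detection
#'   dropout at the nominal 100 Hz read rate.
#' @return Tibble `tag, station, t_start, t_end, n_reads`, sorted by
#'   `t_start`.
#' @examples
#' reads <- tibble::tibble(
#'   t_sec = seq(0, 0.5, by = 0.01), antenna = "S1", tag = "M001"
#' )
#' collapse_visits(reads)
#' @export
collapse_visits <- function(reads, max_gap = 1.0) {
  stopifnot(max_gap > 0)
  req <- c("t_sec", "antenna", "tag")
  stopifnot(all(req %in% names(reads)))
  if (is.unsorted(reads$t_sec)) {
    stop("reads must be sorted by t_sec", call. = FALSE)
  }
  if (nrow(reads) == 0) {
    return(tibble::tibble(tag = character(), station = character(),
                          t_start = double(), t_end = double(),
                          n_reads = integer()))
  }
  o <- order(reads$tag, reads$antenna, reads$t_sec, method = "radix")
  t <- reads$t_sec[o]; ant <- reads$antenna[o]; tag <- reads$tag[o]
  n <- length(t)
  new_bout <- c(TRUE, tag[-1] != tag[-n] | ant[-1] != ant[-n] |
                  (t[-1] - t[-n]) > max_gap)
  id <- cumsum(new_bout)
  starts <- which(new_bout)
  ends <- c(starts[-1] - 1L, n)
  out <- tibble::tibble(
    tag = tag[starts],
    station = ant[starts],
    t_start = t[starts],
    t_end = t[ends],
    n_reads = ends - starts + 1L
  )
  out[order(out$t_start), ]
}

#' Attribute drinking-monitor rows to animals via visit bouts
#'
#' Each drink row at station `s`, time `t` is attributed to the animal
#' whose bout at `s` contains `t` (closed interval; if several bouts
#' contain `t` the one with the earliest start wins). Failing containment,
#' the bout at `s` whose nearest boundary is within `tolerance` seconds
#' wins (ties again to the earlier bout start). Otherwise the row is
#' unassigned (`tag = NA`). Substance and dose are joined from the station
#' map. The summed volume of assigned plus unassigned events always equals
#' the summed input volume.
#'
#' @param drinks Tibble `t_sec, station, volume_ul`, time-sorted.
#' @param bouts Visit bouts from [collapse_visits()].
#' @param roster Roster tibble (used to validate tags).
#' @param stations Station map tibble.
#' @param tolerance Nearest-boundary tolerance, seconds (default 2).
#' @return Tibble of drink events: `tag` (`NA` when unassigned), `station`,
#'   `substance`, `dose_label`, `chamber`, `t_sec`, `volume_ul`, sorted by
#'   time, with attribute `n_unassigned`.
#' @export
assign_drinks <- function(drinks, bouts, roster, stations, tolerance = 2.0) {
  smap <- validate_station_map(stations)
  unknown <- setdiff(unique(drinks$station), smap$station)
  if (length(unknown) > 0) {
    stop("drink rows at unknown station(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_tag <- setdiff(unique(bouts$tag), roster$tag)
  if (length(bad_tag) > 0) {
    stop("bouts carry tag(s) absent from roster: ",
         paste(bad_tag, collapse = ", "), call. = FALSE)
  }
  drinks <- drinks[order(drinks$t_sec), ]
  drinks$tag <- NA_character_
  for (s in unique(drinks$station)) {
    di <- which(drinks$station == s)
    b <- bouts[bouts$station == s, , drop = FALSE]
    if (nrow(b) == 0) next
    b <- b[order(b$t_start), , drop = FALSE]
    drinks$tag[di] <- match_bouts(drinks$t_sec[di], b, tolerance)
  }
  out <- drinks |>
    dplyr::left_join(smap, by = "station") |>
    dplyr::select("tag", "station", "substance", "dose_label", "chamber",
                  "t_sec", "volume_ul")
  attr(out, "n_unassigned") <- sum(is.na(out$tag))
  out
}

# interval attribution at one station; bouts sorted by t_start
match_bouts <- function(t, b, tolerance) {
  starts <- b$t_start; ends <- b$t_end; tags <- b$tag
  cme <- cummax(ends)                      # running max of bout ends
  idx <- findInterval(t, starts)           # last bout starting at or before t
  out <- rep(NA_character_, length(t))
  for (i in seq_along(t)) {
    ti <- t[i]; j <- idx[i]
    hit <- NA_integer_
    if (j >= 1 && cme[j] >= ti) {
      # some bout starting <= ti also ends >= ti; earliest start wins
      lo <- j
      while (lo > 1 && cme[lo - 1] >= ti) lo <- lo - 1
      for (k in lo:j) {
        if (ends[k] >= ti) { hit <- k; break }
      }
    }
    if (is.na(hit)) {
      # nearest boundary within tolerance; ties to the earlier bout start
      d_prev <- Inf; k_prev <- NA_integer_
      if (j >= 1) {
        k_prev <- which.max(ends[seq_len(j)])
        d_prev <- ti - ends[k_prev]
      }
      d_next <- Inf; k_next <- NA_integer_
      if (j < length(starts)) {
        k_next <- j + 1L
        d_next <- starts[k_next] - ti
      }
      if (min(d_prev, d_next) <= tolerance) {
        hit <- if (d_prev <= d_next) k_prev else k_next
      }
    }
    if (!is.na(hit)) out[i] <- tags[hit]
  }
  out
}
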