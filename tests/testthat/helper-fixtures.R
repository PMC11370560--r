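# shared small fixtures, built once per test run

tiny_cfg <- function(...) {
  sip_config(n_males = 4, n_females = 4, n_days = 2, seed = 101, ...)
}

.shared <- new.env()

shared_fixture <- function() {
  if (is.null(.shared$fx)) .shared$fx <- simulate_sip(tiny_cfg())
  .shared$fx
}

shared_events <- function() {
  if (is.null(.shared$events)) {
    fx <- shared_fixture()
    bouts <- collapse_visits(fx$rfid)
    .shared$bouts <- bouts
    .shared$events <- assign_drinks(fx$vdm, bouts, fx$animals, fx$stations)
  }
  .shared$events
}

shared_bouts <- function() {
  shared_events()
  .shared$bouts
}

# hand-built drink events at arbitrary times (already "attributed")
make_events <- function(tag, t_sec, chamber, volume_ul = 10) {
  ch <- sip_chambers()
  i <- match(chamber, ch$chamber)
  stopifnot(!anyNA(i))
  smap <- default_station_map()
  tibble::tibble(
    tag = tag,
    station = smap$station[match(chamber, smap$chamber)],
    substance = ch$substance[i],
    dose_label = ch$dose_label[i],
    chamber = chamber,
    t_sec = t_sec,
    volume_ul = volume_ul
  )
}

# uniform random attributed events over n_days for the window oracle
random_events <- function(n, n_days = 2, n_tags = 5, seed = 1) {
  withr::with_seed(seed, {
    ch <- sip_chambers()$chamber
    make_events(
      tag = sample(sprintf("A%02d", seq_len(n_tags)), n, replace = TRUE),
      t_sec = stats::runif(n, 0, n_days * 86400),
      chamber = sample(ch, n, replace = TRUE),
      volume_ul = stats::rgamma(n, 2, scale = 20)
    )
  })
}

# brute-force window classifier: nested loops, no binning arithmetic shared
# with the implementation
brute_force_windows <- function(events, mode, window_min = 60) {
  cat_of <- if (mode == "collapsed") events$substance else events$chamber
  out <- list()
  for (tg in sort(unique(events$tag))) {
    sel <- events$tag == tg & events$volume_ul > 0
    if (!any(sel)) next
    tmax <- max(events$t_sec[sel])
    w_len <- window_min * 60
    k <- 0
    while (k * w_len <= tmax) {
      in_w <- sel & events$t_sec >= k * w_len & events$t_sec < (k + 1) * w_len
      if (any(in_w)) {
        cats <- unique(cat_of[in_w])
        ord <- match(cats, if (mode == "collapsed") {
          c("water", "ethanol", "fentanyl")
        } else sip_chambers()$chamber)
        out[[length(out) + 1]] <- tibble::tibble(
          tag = tg,
          day = floor(k * w_len / 86400) + 1,
          window = floor((k * w_len) %% 86400 / w_len),
          combo = paste(cats[order(ord)], collapse = "+"),
          size = length(cats)
        )
      }
      k <- k + 1
    }
  }
  dplyr::bind_rows(out)
}
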