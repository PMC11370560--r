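#' Generate a synthetic cohort roster and station map
#'
#' Draws a roster of single-sex cages of `cage_size` animals with truncated
#' normal body weights, plus the default six-station map (two water
#' stations, ethanol 5%/10%, fentanyl 5/20 ug/ml).
#'
#' @param cfg A [sip_config()].
#' @return List with `animals` (tibble `tag, sex, body_weight_g, cage`) and
#'   `stations` (see [default_station_map()]).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sip_config"))
  for (s in c("M", "F")) {
    n <- if (s == "M") cfg$n_males else cfg$n_females
    if (n %% cfg$cage_size != 0) {
      stop(sprintf(
        "number of %s animals (%d) is not divisible by cage_size (%d)",
        if (s == "M") "male" else "female", n, cfg$cage_size
      ), call. = FALSE)
    }
  }
  n <- cfg$n_males + cfg$n_females
  withr::with_seed(cfg$seed, {
    sex <- rep(c("M", "F"), c(cfg$n_males, cfg$n_females))
    tag <- sprintf("%s%03d", sex, c(seq_len(cfg$n_males),
                                    seq_len(cfg$n_females)))
    bw <- stats::rnorm(n, cfg$weight_mean, cfg$weight_sd)
    while (any(bw <= 0)) { # truncation at zero by resampling
      bad <- bw <= 0
      bw[bad] <- stats::rnorm(sum(bad), cfg$weight_mean, cfg$weight_sd)
    }
    cage <- sprintf("C%02d", if (n > 0) {
      rep(seq_len(n / cfg$cage_size), each = cfg$cage_size)
    } else integer(0))
    animals <- tibble::tibble(
      tag = tag, sex = sex, body_weight_g = bw, cage = cage
    )
  })
  list(animals = animals, stations = default_station_map())
}

#' Generate the 12-parameter behavior table with latent phenotype truth
#'
#' Each animal is assigned a latent phenotype by the mixing proportions and
#' its 12 OFB/EZM parameters are drawn from a multivariate normal around
#' that phenotype's mean row; all parameters are nonnegative quantities and
#' are clipped at zero.
#'
#' @param cfg A [sip_config()].
#' @param animals Roster tibble from [generate_cohort()].
#' @return List with `behavior` (tibble `tag` + the 12 [behavior_params()]
#'   columns) and `truth` (tibble `tag, phenotype`).
#' @export
generate_behavior_table <- function(cfg, animals) {
  stopifnot(inherits(cfg, "sip_config"))
  check_psd(cfg$phenotype_cov)
  n <- nrow(animals)
  withr::with_seed(cfg$seed + 1L, {
    phenotype <- sample.int(3, n, replace = TRUE, prob = cfg$phenotype_mix)
    noise <- if (n > 0) {
      MASS::mvrnorm(n, mu = rep(0, 12), Sigma = cfg$phenotype_cov)
    } else {
      matrix(0, 0, 12)
    }
  })
  if (n == 1) noise <- matrix(noise, nrow = 1)
  vals <- pmax(cfg$phenotype_means[phenotype, , drop = FALSE] + noise, 0)
  colnames(vals) <- behavior_params()
  list(
    behavior = dplyr::bind_cols(
      tibble::tibble(tag = animals$tag), tibble::as_tibble(vals)
    ),
    truth = tibble::tibble(tag = animals$tag, phenotype = phenotype)
  )
}

#' Simulate the RFID and drinking-monitor acquisition streams
#'
#' Per animal, visit onsets follow a two-rate Poisson process
#' (`base_visit_rate` visits/hour in the light phase, multiplied by
#' `dark_rate_multiplier` in the dark phase). Each visit picks a chamber
#' with probability proportional to the animal's phenotype- and
#' sex-specific choice weights (the fentanyl log-weights drift upward by
#' `escalation_slope` per day), lasts a lognormal duration, and emits
#' antenna reads at the nominal `rfid_hz` thinned by the detection
#' probability (entry and exit always detected). With probability
#' `drink_prob` the visit consumes a gamma-distributed volume recorded as
#' 1 Hz drinking-monitor rows inside the bout.
#'
#' @param cfg A [sip_config()].
#' @param animals,stations Cohort pieces from [generate_cohort()].
#' @param truth Truth tibble from [generate_behavior_table()].
#' @return List with `rfid` (tibble `t_sec, antenna, tag`, time-sorted) and
#'   `vdm` (tibble `t_sec, station, volume_ul`, time-sorted).
#' @export
generate_drinking_streams <- function(cfg, animals, stations, truth) {
  stopifnot(inherits(cfg, "sip_config"), cfg$n_days >= 1)
  end <- cfg$n_days * 86400
  empty <- list(
    rfid = tibble::tibble(t_sec = double(), antenna = character(),
                          tag = character()),
    vdm = tibble::tibble(t_sec = double(), station = character(),
                         volume_ul = double())
  )
  if (nrow(animals) == 0 || cfg$base_visit_rate <= 0) return(empty)

  smap <- validate_station_map(stations)
  stations_by_chamber <- split(smap$station, smap$chamber)

  withr::with_seed(cfg$seed + 2L, {
    visits <- sim_visit_onsets(cfg, animals, truth)
    if (nrow(visits) == 0) return(empty)
    visits <- sim_choose_stations(cfg, visits, stations_by_chamber)
    visits$dur <- pmax(
      pmin(stats::rlnorm(nrow(visits), log(cfg$bout_median_s), cfg$bout_sdlog),
           end - visits$t - 1e-3),
      0.01
    )
    rfid <- sim_emit_rfid(cfg, visits)
    vdm <- sim_emit_vdm(cfg, visits)
  })
  list(rfid = rfid, vdm = vdm)
}

# Poisson visit onsets over the alternating light/dark segments
sim_visit_onsets <- function(cfg, animals, truth) {
  seg <- tidyr::expand_grid(
    idx = seq_len(nrow(animals)),
    day = seq_len(cfg$n_days),
    phase = c("light", "dark")
  )
  seg$start <- (seg$day - 1) * 86400 + ifelse(seg$phase == "dark", 43200, 0)
  rate_s <- cfg$base_visit_rate / 3600
  seg$lambda <- 43200 * rate_s *
    ifelse(seg$phase == "dark", cfg$dark_rate_multiplier, 1)
  n_vis <- stats::rpois(nrow(seg), seg$lambda)
  t <- rep(seg$start, n_vis) + stats::runif(sum(n_vis)) * 43200
  idx <- rep(seg$idx, n_vis)
  truth_ph <- truth$phenotype[match(animals$tag, truth$tag)]
  tibble::tibble(
    tag = animals$tag[idx],
    sex = animals$sex[idx],
    phenotype = truth_ph[idx],
    t = t,
    day = floor(t / 86400) + 1
  )
}

# chamber choice by normalized weights, with per-day fentanyl escalation
sim_choose_stations <- function(cfg, visits, stations_by_chamber) {
  chambers <- sip_chambers()$chamber
  w_tab <- cfg$substance_weights
  visits$chamber <- NA_character_
  grp <- interaction(visits$phenotype, visits$sex, visits$day, drop = TRUE)
  for (g in levels(grp)) {
    sel <- which(grp == g)
    ph <- visits$phenotype[sel[1]]; sx <- visits$sex[sel[1]]
    d <- visits$day[sel[1]]
    sub <- w_tab[w_tab$phenotype == ph & w_tab$sex == sx, ]
    w <- sub$weight[match(chambers, sub$chamber)]
    names(w) <- chambers
    is_fent <- startsWith(chambers, "fent")
    w[is_fent] <- w[is_fent] * exp(cfg$escalation_slope * (d - 1))
    visits$chamber[sel] <- sample(chambers, length(sel),
                                  replace = TRUE, prob = w)
  }
  # station within chamber (water occupies two stations)
  visits$station <- vapply(seq_len(nrow(visits)), function(i) {
    s <- stations_by_chamber[[visits$chamber[i]]]
    if (length(s) == 1) s else s[sample.int(length(s), 1)]
  }, character(1))
  visits
}

sim_emit_rfid <- function(cfg, visits) {
  n_samp <- floor(visits$dur * cfg$rfid_hz) + 1L
  t <- rep(visits$t, n_samp) + (sequence(n_samp) - 1) / cfg$rfid_hz
  pos <- sequence(n_samp)
  is_edge <- pos == 1L | pos == rep(n_samp, n_samp)
  keep <- is_edge | stats::runif(length(t)) < cfg$rfid_detect_prob
  out <- tibble::tibble(
    t_sec = t[keep],
    antenna = rep(visits$station, n_samp)[keep],
    tag = rep(visits$tag, n_samp)[keep]
  )
  out[order(out$t_sec), ]
}

sim_emit_vdm <- function(cfg, visits) {
  drinks <- visits[stats::runif(nrow(visits)) < cfg$drink_prob, , drop = FALSE]
  if (nrow(drinks) == 0) {
    return(tibble::tibble(t_sec = double(), station = character(),
                          volume_ul = double()))
  }
  vol <- stats::rgamma(nrow(drinks), shape = cfg$volume_shape,
                       scale = cfg$volume_scale)
  n_rows <- pmax(1L, as.integer(floor(drinks$dur)))
  t <- rep(drinks$t, n_rows) +
    ifelse(rep(n_rows, n_rows) == 1L & rep(drinks$dur, n_rows) < 1,
           rep(drinks$dur, n_rows) / 2,
           sequence(n_rows) - 0.5)
  out <- tibble::tibble(
    t_sec = t,
    station = rep(drinks$station, n_rows),
    volume_ul = rep(vol / n_rows, n_rows)
  )
  out[order(out$t_sec), ]
}

#' Simulate a complete cohort fixture
#'
#' Runs [generate_cohort()], [generate_behavior_table()] and
#' [generate_drinking_streams()] under seeds derived from `cfg$seed` and
#' bundles the result.
#'
#' @param cfg A [sip_config()].
#' @return A list of class `sip_fixture`: `config`, `animals`, `stations`,
#'   `rfid`, `vdm`, `behavior`, `truth`.
#' @examples
#' fx <- simulate_sip(sip_config(n_males = 4, n_females = 4, n_days = 1))
#' @export
simulate_sip <- function(cfg = sip_config()) {
  cohort <- generate_cohort(cfg)
  beh <- generate_behavior_table(cfg, cohort$animals)
  streams <- generate_drinking_streams(cfg, cohort$animals, cohort$stations,
                                       beh$truth)
  structure(
    list(
      config = cfg,
      animals = cohort$animals,
      stations = cohort$stations,
      rfid = streams$rfid,
      vdm = streams$vdm,
      behavior = beh$behavior,
      truth = beh$truth
    ),
    class = "sip_fixture"
  )
}

#' Write a simulated fixture to a directory of plain-text files
#'
#' Emits `animals.csv`, `stations.csv`, `rfid.csv`, `vdm.csv`,
#' `behavior.csv` and `truth.json` in the dialects the stream readers
#' expect; writing then re-reading round-trips losslessly, and the same
#' seed yields byte-identical files.
#'
#' @param fixture A `sip_fixture` from [simulate_sip()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(fixture, out_dir) {
  stopifnot(inherits(fixture, "sip_fixture"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    animals = file.path(out_dir, "animals.csv"),
    stations = file.path(out_dir, "stations.csv"),
    rfid = file.path(out_dir, "rfid.csv"),
    vdm = file.path(out_dir, "vdm.csv"),
    behavior = file.path(out_dir, "behavior.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  readr::write_csv(fixture$animals, paths[["animals"]])
  readr::write_csv(
    fixture$stations[c("station", "substance", "dose_label")],
    paths[["stations"]]
  )
  readr::write_csv(fixture$rfid, paths[["rfid"]])
  readr::write_csv(fixture$vdm, paths[["vdm"]])
  readr::write_csv(fixture$behavior, paths[["behavior"]])
  jsonlite::write_json(
    list(
      phenotype = stats::setNames(as.list(fixture$truth$phenotype),
                                  fixture$truth$tag),
      substance_weights = fixture$config$substance_weights
    ),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
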