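#' Configuration for the synthetic home-cage drinking simulator
#'
#' Bundles every knob of the synthetic-data generator: cohort composition,
#' the light/dark visit process, the choice model over drinking stations,
#' bout and volume distributions, the RFID/VDM emission model, and the
#' latent behavioral-phenotype model behind the 12-parameter behavior table.
#'
#' Defaults describe a study week of 32 males and 24 females housed
#' four-to-a-cage under a 12:12 light:dark cycle (lights on 06:00) with six
#' drinking stations (2x water, ethanol 5% and 10%, fentanyl 5 and
#' 20 ug/ml). Visit rates, bout durations and the RFID detection
#' probability are calibrated so a simulated cohort-week produces stream
#' sizes of the same magnitude as a real acquisition run (several hundred
#' thousand antenna reads, tens of thousands of 1 Hz drink rows).
#'
#' @param n_males,n_females Number of animals of each sex.
#' @param cage_size Animals per (single-sex) cage; must divide each sex's count.
#' @param n_days Days of continuous access.
#' @param lights_on_hour Clock hour of lights-on; the experiment clock starts
#'   at lights-on, so `t = 0` is zeitgeber time 0 of day 1.
#' @param base_visit_rate Light-phase visit rate, visits/hour per animal.
#' @param dark_rate_multiplier Multiplier on the visit rate during the dark
#'   phase (ZT 12-24).
#' @param substance_weights Tibble `(phenotype, sex, chamber, weight)` of
#'   nonnegative choice weights; see [default_substance_weights()].
#' @param escalation_slope Additive per-day drift on the log fentanyl choice
#'   weight (escalation of fentanyl-directed visits across days).
#' @param bout_median_s,bout_sdlog Lognormal visit-bout duration parameters
#'   (median seconds; sd on the log scale).
#' @param drink_prob Probability a visit includes drinking.
#' @param volume_shape,volume_scale Gamma parameters of per-bout consumed
#'   volume in microliters (mean `shape * scale`).
#' @param rfid_hz Nominal antenna sampling rate during a visit (Hz).
#' @param rfid_detect_prob Probability an individual within-bout sample
#'   registers a tag read; the first and last sample of a bout always
#'   register (entry/exit detections), so bout boundaries are observed.
#' @param weight_mean,weight_sd Body-weight distribution (grams), truncated
#'   at zero.
#' @param phenotype_means 3 x 12 matrix of behavior-parameter means, one row
#'   per latent phenotype, columns in [behavior_params()] order.
#' @param phenotype_cov 12 x 12 symmetric positive semi-definite covariance
#'   shared across phenotypes.
#' @param phenotype_mix Length-3 mixing proportions, summing to 1.
#' @param seed Integer RNG seed; identical configs generate byte-identical
#'   fixtures.
#' @return A list of class `sip_config`.
#' @examples
#' cfg <- sip_config(n_males = 4, n_females = 4, n_days = 1, seed = 42)
#' @export
sip_config <- function(n_males = 32,
                       n_females = 24,
                       cage_size = 4,
                       n_days = 7,
                       lights_on_hour = 6,
                       base_visit_rate = 0.5,
                       dark_rate_multiplier = 3,
                       substance_weights = default_substance_weights(),
                       escalation_slope = 0.15,
                       bout_median_s = 10,
                       bout_sdlog = 0.5,
                       drink_prob = 0.6,
                       volume_shape = 4,
                       volume_scale = 75,
                       rfid_hz = 100,
                       rfid_detect_prob = 0.07,
                       weight_mean = 25,
                       weight_sd = 2,
                       phenotype_means = default_phenotype_means(),
                       phenotype_cov = default_phenotype_cov(),
                       phenotype_mix = c(0.2, 0.1, 0.7),
                       seed = 1L) {
  stopifnot(
    n_males >= 0, n_females >= 0, cage_size >= 1, n_days >= 1,
    base_visit_rate >= 0, dark_rate_multiplier >= 0,
    bout_median_s > 0, bout_sdlog >= 0,
    drink_prob >= 0, drink_prob <= 1,
    volume_shape > 0, volume_scale > 0,
    rfid_hz > 0, rfid_detect_prob >= 0, rfid_detect_prob <= 1,
    weight_mean > 0, weight_sd >= 0
  )
  if (abs(sum(phenotype_mix) - 1) > 1e-9 || any(phenotype_mix < 0)) {
    stop("phenotype_mix must be nonnegative and sum to 1", call. = FALSE)
  }
  phenotype_means <- as.matrix(phenotype_means)
  if (!all(dim(phenotype_means) == c(3, 12))) {
    stop("phenotype_means must be a 3 x 12 matrix", call. = FALSE)
  }
  colnames(phenotype_means) <- behavior_params()
  check_psd(phenotype_cov)
  req <- c("phenotype", "sex", "chamber", "weight")
  if (!all(req %in% names(substance_weights)) ||
      any(substance_weights$weight < 0)) {
    stop("substance_weights needs columns phenotype, sex, chamber, weight, ",
         "with nonnegative weights", call. = FALSE)
  }
  structure(
    list(
      n_males = as.integer(n_males), n_females = as.integer(n_females),
      cage_size = as.integer(cage_size), n_days = as.integer(n_days),
      lights_on_hour = lights_on_hour,
      base_visit_rate = base_visit_rate,
      dark_rate_multiplier = dark_rate_multiplier,
      substance_weights = tibble::as_tibble(substance_weights),
      escalation_slope = escalation_slope,
      bout_median_s = bout_median_s, bout_sdlog = bout_sdlog,
      drink_prob = drink_prob,
      volume_shape = volume_shape, volume_scale = volume_scale,
      rfid_hz = rfid_hz, rfid_detect_prob = rfid_detect_prob,
      weight_mean = weight_mean, weight_sd = weight_sd,
      phenotype_means = phenotype_means,
      phenotype_cov = phenotype_cov,
      phenotype_mix = phenotype_mix,
      seed = as.integer(seed)
    ),
    class = "sip_config"
  )
}

check_psd <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != 12 || ncol(sigma) != 12 ||
      max(abs(sigma - t(sigma))) > 1e-8) {
    stop("phenotype_cov must be a symmetric 12 x 12 matrix", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("phenotype_cov must be positive semi-definite", call. = FALSE)
  }
  invisible(sigma)
}

#' Default choice weights over the five substance/dose chambers
#'
#' The weight of a chamber is the unnormalized probability that a visit is
#' directed at it (water's weight is shared over its two stations). Females
#' carry multiplied ethanol and fentanyl weights, emulating the higher
#' female preference for both drugs over water; the three latent phenotypes
#' carry distinct fentanyl profiles (phenotype 2 strongly prefers the high
#' fentanyl dose).
#'
#' @param female_ethanol_mult,female_fentanyl_mult Multipliers applied to a
#'   female's ethanol / fentanyl weights. Setting both to 1 removes the
#'   planted sex effect (null configuration).
#' @return Tibble with columns `phenotype` (1..3), `sex` (`"M"`/`"F"`),
#'   `chamber`, `weight`.
#' @export
default_substance_weights <- function(female_ethanol_mult = 1.5,
                                      female_fentanyl_mult = 2) {
  base <- c(water = 2, etoh_5 = 0.8, etoh_10 = 0.6, fent_5 = 0.7, fent_20 = 0.5)
  pheno_mult <- list(
    `1` = c(water = 1,   etoh_5 = 1, etoh_10 = 1, fent_5 = 1.5, fent_20 = 1),
    `2` = c(water = 1,   etoh_5 = 1, etoh_10 = 1, fent_5 = 1.5, fent_20 = 2.5),
    `3` = c(water = 1.2, etoh_5 = 1, etoh_10 = 1, fent_5 = 1,   fent_20 = 1)
  )
  grid <- tidyr::expand_grid(
    phenotype = 1:3, sex = c("M", "F"), chamber = names(base)
  )
  grid$weight <- purrr::pmap_dbl(grid, function(phenotype, sex, chamber) {
    w <- base[[chamber]] * pheno_mult[[as.character(phenotype)]][[chamber]]
    if (sex == "F") {
      if (startsWith(chamber, "etoh")) w <- w * female_ethanol_mult
      if (startsWith(chamber, "fent")) w <- w * female_fentanyl_mult
    }
    w
  })
  grid
}

#' Default latent behavioral-phenotype model
#'
#' Three phenotypes over the 12 open-field (OFB) and elevated-zero-maze
#' (EZM) parameters from a 5-minute session each: a high-anxiety profile
#' (low center/open-arm exploration, long entry latencies), a low-anxiety
#' explorer profile, and an intermediate majority profile. Units: distances
#' m, speeds m/s, times and latencies s, entries counts. The default
#' within-phenotype covariance is diagonal with standard deviations chosen
#' so neighboring phenotype means sit roughly 3 or more SDs apart on the
#' discriminating parameters.
#'
#' @return `default_phenotype_means()`: 3 x 12 matrix; rows are phenotypes,
#'   columns [behavior_params()]. `default_phenotype_cov()`: diagonal
#'   12 x 12 covariance.
#' @export
default_phenotype_means <- function() {
  m <- rbind(
    c(22, 0.073, 12, 6, 90, 2.5, 16, 0.053, 25, 5, 80, 2.5),   # high anxiety
    c(38, 0.127, 55, 22, 10, 9.0, 28, 0.093, 95, 18, 8, 9.0),  # explorer
    c(30, 0.100, 30, 14, 40, 5.5, 22, 0.073, 55, 11, 35, 5.5)  # intermediate
  )
  colnames(m) <- behavior_params()
  rownames(m) <- paste0("phenotype_", 1:3)
  m
}

#' @rdname default_phenotype_means
#' @export
default_phenotype_cov <- function() {
  sds <- c(2.5, 0.008, 8, 3, 18, 1.2, 2.5, 0.008, 12, 2.5, 16, 1.2)
  sigma <- diag(sds^2)
  dimnames(sigma) <- list(behavior_params(), behavior_params())
  sigma
}
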