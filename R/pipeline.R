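#' Run the full home-cage polysubstance analysis battery
#'
#' Orchestrates every stage over a simulated cohort or a directory of
#' acquisition files: stream integration (visit bouts, attributed drink
#' events), intake and occupancy summaries, preference indices,
#' polysubstance window classification with chi-squared comparisons,
#' behavioral phenotype clustering, and the sex- and cluster-conditioned
#' statistical battery (mixed RM ANOVAs, t tests, one-way ANOVAs).
#'
#' @param cfg A [sip_config()] used to simulate the cohort when
#'   `input_dir` is `NULL`; its seed drives the whole run.
#' @param input_dir Optional directory holding `animals.csv`,
#'   `stations.csv`, `rfid.csv`, `vdm.csv`, `behavior.csv` (the
#'   [write_fixture_set()] layout) to analyze instead of simulating.
#' @param window_min Polysubstance window length, minutes.
#' @param max_gap Bout-collapsing gap, seconds (see [collapse_visits()]).
#' @param tolerance Drink-attribution tolerance, seconds.
#' @param k,k_range,B Clustering settings (see [cluster_phenotypes()]).
#' @param out_dir Optional directory; when given, the tabular interfaces
#'   (`intake_long.csv`, `occupancy_long.csv`, `heatmap_long.csv`,
#'   `preference_long.csv`, `poly_windows.csv`, `poly_distributions.csv`,
#'   `clusters.csv`, `stability.csv`) and `report.json` are written there.
#' @return A list of class `sip_report`; see the vignette for the layout.
#' @export
run_sip_pipeline <- function(cfg = sip_config(), input_dir = NULL,
                             window_min = 60, max_gap = 1.0, tolerance = 2.0,
                             k = "auto", k_range = 3:6, B = 100,
                             out_dir = NULL) {
  if (is.null(input_dir)) {
    fx <- simulate_sip(cfg)
  } else {
    need <- file.path(input_dir, c("animals.csv", "stations.csv", "rfid.csv",
                                   "vdm.csv", "behavior.csv"))
    absent <- need[!file.exists(need)]
    if (length(absent) > 0) {
      stop("missing input file(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    fx <- list(
      config = cfg,
      animals = read_roster(need[1]),
      stations = read_station_map(need[2]),
      rfid = read_rfid_stream(need[3]),
      vdm = read_vdm_stream(need[4]),
      behavior = read_checked_csv(need[5], cols = c(
        list(tag = "character"),
        stats::setNames(as.list(rep("numeric", 12)), behavior_params())
      )),
      truth = NULL
    )
  }

  # --- stream integration -------------------------------------------------
  bouts <- collapse_visits(fx$rfid, max_gap = max_gap)
  events <- assign_drinks(fx$vdm, bouts, fx$animals, fx$stations,
                          tolerance = tolerance)
  n_days <- max(cfg$n_days, if (nrow(events) > 0) {
    max(zt_of(events$t_sec)$day)
  } else 1L)
  sex_groups <- tibble::tibble(tag = fx$animals$tag, group = fx$animals$sex)

  # --- intake, occupancy, preference -------------------------------------
  intake <- lapply(
    stats::setNames(nm = c("total", "day", "phase", "day_zt")),
    function(gr) aggregate_intake(events, fx$animals, gr, n_days = n_days)
  )
  occupancy <- lapply(
    stats::setNames(nm = c("total", "day", "phase", "day_zt")),
    function(gr) chamber_occupancy(bouts, gr, n_days = n_days)
  )
  heatmap_sex <- heatmap_matrix(intake$day_zt, sex_groups)
  preference <- dplyr::bind_rows(
    substance_preference(intake$total, "ethanol"),
    substance_preference(intake$total, "fentanyl"),
    dose_preference(intake$total, "ethanol"),
    dose_preference(intake$total, "fentanyl"),
    substance_preference(intake$day, "ethanol", scope = "day"),
    substance_preference(intake$day, "fentanyl", scope = "day"),
    dose_preference(intake$day, "ethanol", scope = "day"),
    dose_preference(intake$day, "fentanyl", scope = "day")
  )

  # --- polysubstance windows ---------------------------------------------
  windows <- list(
    collapsed = classify_windows(events, "collapsed", window_min = window_min),
    dose = classify_windows(events, "dose", window_min = window_min)
  )
  poly <- poly_battery(windows, sex_groups, n_days)

  # --- behavioral phenotyping --------------------------------------------
  clustering <- cluster_phenotypes(
    fx$behavior, k = k, k_range = k_range, B = B, seed = cfg$seed + 100L
  )
  cluster_groups <- tibble::tibble(
    tag = clustering$clusters$tag,
    group = paste0("cluster_", clustering$clusters$cluster)
  )
  cluster_by_sex <- cluster_by_group_table(clustering$clusters |>
                                             dplyr::rename(cluster = "cluster"),
                                           fx$animals)
  heatmap_cluster <- heatmap_matrix(intake$day_zt, cluster_groups)
  poly_cluster <- poly_battery(windows, cluster_groups, n_days)

  # --- statistical battery ------------------------------------------------
  stats_sex <- stats_battery(intake, preference, fx$behavior, fx$animals,
                             sex_groups, n_days)
  stats_cluster <- stats_battery(intake, preference, fx$behavior, fx$animals,
                                 cluster_groups, n_days)

  report <- structure(
    list(
      counts = list(
        n_animals = nrow(fx$animals), n_days = n_days,
        n_rfid = nrow(fx$rfid), n_vdm = nrow(fx$vdm),
        n_bouts = nrow(bouts), n_events = nrow(events),
        n_unassigned = attr(events, "n_unassigned"),
        n_windows_collapsed = nrow(windows$collapsed),
        n_windows_dose = nrow(windows$dose)
      ),
      animals = fx$animals, stations = fx$stations,
      bouts = bouts, events = events,
      intake = intake, occupancy = occupancy,
      heatmaps = list(sex = heatmap_sex, cluster = heatmap_cluster),
      preference = preference,
      windows = windows,
      poly = list(sex = poly, cluster = poly_cluster),
      clustering = clustering, cluster_by_sex = cluster_by_sex,
      stats = list(sex = stats_sex, cluster = stats_cluster),
      truth = fx$truth, seed = cfg$seed
    ),
    class = "sip_report"
  )
  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

# per-grouping polysubstance distributions and chi-squared comparisons
poly_battery <- function(windows, groups, n_days) {
  out <- list()
  for (mode in names(windows)) {
    w <- windows[[mode]]
    dist_all <- combination_distribution(w, groups)
    per_day <- lapply(seq_len(n_days), function(d) {
      combination_distribution(w, groups, days = d)
    })
    tests <- list()
    for (ring in c("outer", "inner")) {
      tests[[paste0("all_days_", ring)]] <-
        try_test(function() compare_distributions(dist_all, ring))
      for (d in seq_len(n_days)) {
        tests[[paste0("day", d, "_", ring)]] <-
          try_test(function() compare_distributions(per_day[[d]], ring))
      }
      # first vs last day within each group
      for (g in unique(groups$group)) {
        gt <- groups$tag[groups$group == g]
        wg <- w[w$tag %in% gt, , drop = FALSE]
        d1 <- combination_distribution(wg, days = 1) |>
          dplyr::mutate(group = "day_1")
        d7 <- combination_distribution(wg, days = n_days) |>
          dplyr::mutate(group = paste0("day_", n_days))
        tests[[paste0(g, "_day1_vs_day", n_days, "_", ring)]] <-
          try_test(function() compare_distributions(list(d1, d7), ring))
      }
    }
    out[[mode]] <- list(distribution = dist_all, per_day = per_day,
                        tests = tests)
  }
  out
}

try_test <- function(f) {
  tryCatch(f(), error = function(e) {
    tibble::tibble(method = "skipped", statistic = NA_real_, df1 = NA_real_,
                   df2 = NA_real_, p_value = NA_real_,
                   note = conditionMessage(e))
  })
}

# sex- or cluster-conditioned statistical battery over intake, preference
# and behavior tables
stats_battery <- function(intake, preference, behavior, roster, groups,
                          n_days) {
  join_grp <- function(df) dplyr::inner_join(df, groups, by = "tag")
  out <- list()

  # total intake: group x substance chamber mixed RM ANOVA
  tot <- join_grp(intake$total)
  out$intake_by_chamber <- try_test(function() mixed_rm_anova(
    tot, subject = "tag", group = "group", within = "chamber",
    value = "intake_ml_kg"
  ))
  # split by light/dark phase
  ph <- join_grp(intake$phase)
  for (p in c("dark", "light")) {
    out[[paste0("intake_by_chamber_", p)]] <- try_test(function() {
      mixed_rm_anova(ph[ph$phase == p, ], subject = "tag", group = "group",
                     within = "chamber", value = "intake_ml_kg")
    })
  }
  # per chamber: group x day mixed RM ANOVA (Table 1 / Table 5 analogue)
  day <- join_grp(intake$day)
  out$intake_by_day <- lapply(
    stats::setNames(nm = sip_chambers()$chamber),
    function(ch) try_test(function() {
      mixed_rm_anova(day[day$chamber == ch, ], subject = "tag",
                     group = "group", within = "day", value = "intake_ml_kg")
    })
  )

  # total preferences: t test (2 groups) or one-way ANOVA (3+)
  pref_tot <- join_grp(preference[preference$scope == "total", ])
  out$preference_total <- lapply(
    stats::setNames(nm = unique(pref_tot$kind)),
    function(kd) try_test(function() {
      d <- pref_tot[pref_tot$kind == kd & pref_tot$defined, ]
      gs <- sort(unique(d$group))
      if (length(gs) == 2) {
        t_test(d$value[d$group == gs[1]], d$value[d$group == gs[2]])
      } else {
        oneway_anova(d$value, d$group)
      }
    })
  )
  # preferences across days: group x day mixed RM ANOVA on subjects with
  # every day defined (undefined days would unbalance the design)
  pref_day <- join_grp(preference[preference$scope != "total", ])
  out$preference_by_day <- lapply(
    stats::setNames(nm = unique(pref_day$kind)),
    function(kd) try_test(function() {
      d <- pref_day[pref_day$kind == kd, ]
      complete <- d |>
        dplyr::group_by(.data$tag) |>
        dplyr::filter(sum(.data$defined) == n_days) |>
        dplyr::ungroup()
      mixed_rm_anova(complete, subject = "tag", group = "group",
                     within = "day", value = "value")
    })
  )

  # behavior parameters: t test (2 groups) / one-way ANOVA (Table 2/4)
  beh <- join_grp(behavior)
  out$behavior <- lapply(
    stats::setNames(nm = behavior_params()),
    function(par) try_test(function() {
      gs <- sort(unique(beh$group))
      if (length(gs) == 2) {
        t_test(beh[[par]][beh$group == gs[1]], beh[[par]][beh$group == gs[2]])
      } else {
        oneway_anova(beh[[par]], beh$group)
      }
    })
  )
  out
}

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) readr::write_csv(df, file.path(out_dir, f))
  w(report$intake$day_zt, "intake_long.csv")
  w(report$occupancy$day_zt, "occupancy_long.csv")
  w(dplyr::bind_rows(sex = report$heatmaps$sex,
                     cluster = report$heatmaps$cluster, .id = "grouping"),
    "heatmap_long.csv")
  w(report$preference, "preference_long.csv")
  w(dplyr::bind_rows(report$windows), "poly_windows.csv")
  w(dplyr::bind_rows(
    sex_collapsed = report$poly$sex$collapsed$distribution,
    sex_dose = report$poly$sex$dose$distribution,
    cluster_collapsed = report$poly$cluster$collapsed$distribution,
    cluster_dose = report$poly$cluster$dose$distribution,
    .id = "analysis"
  ), "poly_distributions.csv")
  w(report$clustering$clusters, "clusters.csv")
  if (!is.null(report$clustering$stability)) {
    w(report$clustering$stability, "stability.csv")
  }
  export_report(report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Export the analysis report as a single JSON document
#'
#' Serializes the run's counts, test results, preference and
#' polysubstance summaries, cluster assignment and stability table into
#' one JSON file. Raw event-level tables are omitted (they have their own
#' CSV interfaces).
#'
#' @param report A `sip_report` from [run_sip_pipeline()].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  required <- c("counts", "preference", "poly", "clustering", "stats")
  missing <- setdiff(required, names(report))
  if (length(missing) > 0) {
    stop("incomplete report bundle; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  strip <- function(x) {
    if (is.data.frame(x)) {
      as.data.frame(lapply(x, function(col) {
        attributes(col) <- NULL
        col
      }))
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  doc <- list(
    counts = report$counts,
    seed = report$seed,
    cluster_by_sex = list(
      table = as.data.frame.matrix(report$cluster_by_sex$table),
      test = strip(report$cluster_by_sex$test)
    ),
    stability = strip(report$clustering$stability),
    k = report$clustering$k,
    clusters = strip(report$clustering$clusters),
    preference = strip(report$preference),
    poly_tests = strip(list(
      sex = lapply(report$poly$sex, function(m) m$tests),
      cluster = lapply(report$poly$cluster, function(m) m$tests)
    )),
    stats = strip(report$stats)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
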