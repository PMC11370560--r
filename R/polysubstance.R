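#' Enumerate the polysubstance combination universe
#'
#' In collapsed mode the categories are the three substance types (water,
#' ethanol, fentanyl), giving `2^3 - 1 = 7` possible non-empty
#' combinations; in dose-resolved mode the five substance/dose chambers
#' give `2^5 - 1 = 31`.
#'
#' @param mode `"collapsed"` or `"dose"`.
#' @return Tibble `combo` (canonical `+`-joined label), `size`.
#' @examples
#' nrow(combo_universe("collapsed")) # 7
#' @export
combo_universe <- function(mode = c("collapsed", "dose")) {
  mode <- match.arg(mode)
  cats <- poly_categories(mode)
  sets <- unlist(
    lapply(seq_along(cats), function(k) {
      combn(cats, k, FUN = paste, collapse = "+", simplify = FALSE)
    })
  )
  tibble::tibble(
    combo = sets,
    size = lengths(strsplit(sets, "+", fixed = TRUE))
  )
}

poly_categories <- function(mode) {
  switch(mode,
    collapsed = c("water", "ethanol", "fentanyl"),
    dose = sip_chambers()$chamber,
    stop("unknown mode: ", mode, call. = FALSE)
  )
}

#' Classify 60-minute polysubstance windows
#'
#' Partitions the experiment into fixed, non-overlapping windows aligned
#' to lights-on (half-open, so an event exactly on a boundary falls in
#' the later window) and, per animal and window, records the set of
#' substance categories with positive consumed volume. A window with two
#' or more categories is a polysubstance window. Windows with no intake
#' produce no record.
#'
#' @param events Attributed drink events from [assign_drinks()];
#'   unassigned rows are ignored.
#' @param mode `"collapsed"` (water/ethanol/fentanyl) or `"dose"` (the
#'   five substance/dose chambers).
#' @param window_min Window length in minutes (default 60).
#' @return Tibble `tag, day, window` (0-based index within day), `mode`,
#'   `combo`, `size`, sorted by tag/day/window.
#' @export
classify_windows <- function(events, mode = c("collapsed", "dose"),
                             window_min = 60) {
  mode <- match.arg(mode)
  stopifnot(window_min > 0)
  ev <- events[!is.na(events$tag) & events$volume_ul > 0, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(tibble::tibble(tag = character(), day = integer(),
                          window = integer(), mode = character(),
                          combo = character(), size = integer()))
  }
  cats <- poly_categories(mode)
  cat_of <- if (mode == "collapsed") ev$substance else ev$chamber
  ev |>
    dplyr::mutate(
      day = as.integer(floor(.data$t_sec / 86400)) + 1L,
      window = as.integer(floor((.data$t_sec %% 86400) / (window_min * 60))),
      category = factor(cat_of, levels = cats)
    ) |>
    dplyr::group_by(.data$tag, .data$day, .data$window) |>
    dplyr::summarise(
      combo = paste(levels(.data$category)[sort(unique(as.integer(.data$category)))],
                    collapse = "+"),
      size = dplyr::n_distinct(.data$category),
      .groups = "drop"
    ) |>
    dplyr::mutate(mode = mode, .before = "combo") |>
    dplyr::arrange(.data$tag, .data$day, .data$window)
}

#' Tally windows into a combination distribution
#'
#' Counts windows by combination (the "inner ring" of the nested pie
#' encoding) for one or more groups of animals; counts by set size (the
#' "outer ring") are the sums of the inner tallies over combinations of
#' equal size. Every combination of the mode's universe is retained with
#' a zero count so distributions from different groups are conformable.
#'
#' @param windows Output of [classify_windows()] (a single mode).
#' @param groups Optional tibble `tag, group`; `NULL` pools all animals
#'   into group `"all"`.
#' @param days Optional vector of day numbers to restrict to.
#' @return Tibble `group, combo, size, n` covering the full combination
#'   universe per group.
#' @export
combination_distribution <- function(windows, groups = NULL, days = NULL) {
  mode <- unique(windows$mode)
  if (length(mode) > 1) {
    stop("windows mix classification modes", call. = FALSE)
  }
  if (nrow(windows) == 0) mode <- "collapsed"
  if (!is.null(days)) windows <- windows[windows$day %in% days, , drop = FALSE]
  if (is.null(groups)) {
    groups <- tibble::tibble(tag = unique(windows$tag), group = "all")
    group_levels <- "all"
  } else {
    missing <- setdiff(unique(windows$tag), groups$tag)
    if (length(missing) > 0) {
      stop("no group for tag(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    group_levels <- sort(unique(groups$group))
  }
  universe <- combo_universe(mode)
  counts <- windows |>
    dplyr::inner_join(groups[c("tag", "group")], by = "tag") |>
    dplyr::count(.data$group, .data$combo)
  tidyr::expand_grid(group = group_levels, universe) |>
    dplyr::left_join(counts, by = c("group", "combo")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Chi-squared comparison of combination distributions
#'
#' Compares two or more groups' window distributions on either the outer
#' ring (number of substance types per window) or the inner ring (the
#' specific substance combination), via a Pearson chi-squared test on the
#' groups x categories contingency table. Categories with a zero total
#' across all groups are dropped before testing.
#'
#' @param dist A distribution tibble from [combination_distribution()]
#'   containing at least two groups, or several such tibbles passed as a
#'   list (their `group` labels must differ).
#' @param ring `"outer"` (by size) or `"inner"` (by combination).
#' @return A one-row test tibble from [chi_square_test()], with the
#'   contingency table in the `table` attribute.
#' @export
compare_distributions <- function(dist, ring = c("outer", "inner")) {
  ring <- match.arg(ring)
  if (is.list(dist) && !is.data.frame(dist)) dist <- dplyr::bind_rows(dist)
  if (dplyr::n_distinct(dist$group) < 2) {
    stop("need at least two groups to compare", call. = FALSE)
  }
  key <- if (ring == "outer") "size" else "combo"
  wide <- dist |>
    dplyr::group_by(.data$group, .data[[key]]) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(key), values_from = "n")
  tab <- as.matrix(wide[-1])
  rownames(tab) <- wide$group
  chi_square_test(tab)
}
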