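#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed RM ANOVA into its effects table
#'
#' @param x A [mixed_rm_anova()] result.
#' @param ... Unused.
#' @return Tibble `effect, statistic, df1, df2, p_value`.
#' @method tidy sip_mixed_anova
#' @export
tidy.sip_mixed_anova <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "cells") <- NULL
  out
}

#' @rdname tidy.sip_mixed_anova
#' @method glance sip_mixed_anova
#' @export
glance.sip_mixed_anova <- function(x, ...) {
  cells <- attr(x, "cells")
  tibble::tibble(
    n_groups = dplyr::n_distinct(cells$group),
    n_within = dplyr::n_distinct(cells$within),
    n_subjects = sum(cells$n[!duplicated(cells$group)]),
    ms_subject = attr(x, "ms_subject"),
    ms_resid = attr(x, "ms_resid")
  )
}

#' Tidy methods for the phenotype clustering
#'
#' `tidy()` returns the per-animal cluster assignment; `glance()` the
#' one-row model summary (components kept, variance explained, chosen k,
#' inertia).
#'
#' @param x A `sip_clustering` from [cluster_phenotypes()].
#' @param ... Unused.
#' @method tidy sip_clustering
#' @export
tidy.sip_clustering <- function(x, ...) x$clusters

#' @rdname tidy.sip_clustering
#' @method glance sip_clustering
#' @export
glance.sip_clustering <- function(x, ...) {
  tibble::tibble(
    n = length(x$fit$labels),
    k = x$k,
    n_components = x$n_components,
    variance_explained = sum(x$pca$ratios[seq_len(x$n_components)]),
    inertia = x$fit$inertia
  )
}

#' @export
print.sip_clustering <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Behavioral phenotype clustering: n = %d, %d PCs (%.1f%% variance), k = %d\n",
    g$n, g$n_components, 100 * g$variance_explained, g$k
  ))
  print(table(cluster = x$clusters$cluster))
  invisible(x)
}

#' @export
print.sip_report <- function(x, ...) {
  c <- x$counts
  cat("Home-cage polysubstance analysis report\n")
  cat(sprintf(
    "  %d animals, %d days; %d RFID reads -> %d bouts; %d VDM rows -> %d events (%d unassigned)\n",
    c$n_animals, c$n_days, c$n_rfid, c$n_bouts, c$n_vdm, c$n_events,
    c$n_unassigned
  ))
  cat(sprintf("  %d collapsed-mode windows, %d dose-mode windows; k = %d clusters\n",
              c$n_windows_collapsed, c$n_windows_dose, x$clustering$k))
  invisible(x)
}
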