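test_result <- function(method, statistic, df1, df2, p_value) {
  tibble::tibble(
    method = method, statistic = statistic,
    df1 = df1, df2 = df2, p_value = p_value
  )
}

#' Two-tailed Student's t test (pooled variance)
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return One-row tibble `method, statistic, df1, df2 (NA), p_value`,
#'   with per-group mean +/- SEM in the `groups` attribute.
#' @export
t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  out <- test_result("Student t", unname(tt$statistic),
                     unname(tt$parameter), NA_real_, tt$p.value)
  attr(out, "groups") <- group_summary(c(x, y),
                                       rep(c("x", "y"), c(length(x), length(y))))
  out
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with df `(g - 1, N - g)`. A completely
#' constant response yields `F = 0`, `p = 1` (not an error).
#'
#' @param values Numeric response vector.
#' @param groups Group label vector of the same length.
#' @return One-row tibble `method, statistic, df1, df2, p_value` with
#'   per-group mean +/- SEM in the `groups` attribute.
#' @export
oneway_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  df1 <- nlevels(g) - 1
  df2 <- length(values) - nlevels(g)
  if (df2 < 1) stop("no residual degrees of freedom", call. = FALSE)
  gm <- tapply(values, g, mean)
  ss_b <- sum(tabulate(g) * (gm - mean(values))^2)
  ss_w <- sum((values - gm[g])^2)
  f <- if (ss_b == 0) 0 else (ss_b / df1) / (ss_w / df2)
  p <- if (ss_b == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
  out <- test_result("one-way ANOVA", f, df1, df2, p)
  attr(out, "groups") <- group_summary(values, groups)
  out
}

#' Mixed-design (two-way repeated measures) ANOVA
#'
#' Classical univariate partition for one between-subject factor (e.g.
#' sex or phenotype cluster) crossed with one within-subject factor (e.g.
#' substance chamber or day), every subject measured once at every within
#' level. Sums of squares split into the between-subjects stratum (group;
#' subjects within group) and the within-subjects stratum (within factor;
#' interaction; residual), giving the df pairs `(g-1, N-g)` for the group
#' effect and `(a-1, (a-1)(N-g))` and `((a-1)(g-1), (a-1)(N-g))` for the
#' within and interaction effects. No sphericity correction is applied
#' (printed df are the uncorrected integers).
#'
#' @param data Long tibble with columns `subject`, `group`, `within`,
#'   `value` (or names given by the other arguments).
#' @param subject,group,within,value Column names.
#' @return Object of class `sip_mixed_anova`: a 3-row effects tibble
#'   (`effect, statistic, df1, df2, p_value`) with the error-term mean
#'   squares, cell means and group sizes stored as attributes for post
#'   hoc testing.
#' @export
mixed_rm_anova <- function(data, subject = "subject", group = "group",
                           within = "within", value = "value") {
  df <- tibble::tibble(
    subject = factor(data[[subject]]),
    group = factor(data[[group]]),
    within = factor(data[[within]]),
    value = as.numeric(data[[value]])
  )
  # balance validation: one observation per subject x within level
  counts <- table(df$subject, df$within)
  if (any(counts != 1)) {
    bad <- rownames(counts)[apply(counts != 1, 1, any)]
    stop("unbalanced design: subject(s) without exactly one observation ",
         "per within level: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  gmap <- unique(df[c("subject", "group")])
  if (anyDuplicated(gmap$subject)) {
    bad <- gmap$subject[duplicated(gmap$subject)]
    stop("subject(s) appear in more than one group: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  n_subj <- nlevels(df$subject)
  a <- nlevels(df$within)
  g <- nlevels(df$group)
  if (g < 2 || a < 2) {
    stop("need at least 2 groups and 2 within levels", call. = FALSE)
  }

  fit <- stats::aov(value ~ group * within + Error(subject), data = df)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within_tab <- as.data.frame(s[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within_tab))

  pick <- function(tab, rn, term) {
    i <- match(term, rn)
    c(df = tab$Df[i], ss = tab$`Sum Sq`[i], ms = tab$`Mean Sq`[i])
  }
  eff_group <- pick(between, rn_b, "group")
  err_subj <- pick(between, rn_b, "Residuals")
  eff_within <- pick(within_tab, rn_w, "within")
  eff_inter <- pick(within_tab, rn_w, "group:within")
  err_resid <- pick(within_tab, rn_w, "Residuals")

  ss_total <- sum((df$value - mean(df$value))^2)
  f_of <- function(eff, err) {
    # constant response or an exactly-zero effect: F = 0, not 0/0
    if (ss_total == 0 || eff[["ss"]] <= 1e-12 * ss_total) {
      return(c(f = 0, p = 1))
    }
    f <- eff[["ms"]] / err[["ms"]]
    c(f = f, p = stats::pf(f, eff[["df"]], err[["df"]], lower.tail = FALSE))
  }
  fg <- f_of(eff_group, err_subj)
  fw <- f_of(eff_within, err_resid)
  fi <- f_of(eff_inter, err_resid)

  out <- tibble::tibble(
    effect = c("group", "within", "interaction"),
    statistic = c(fg[["f"]], fw[["f"]], fi[["f"]]),
    df1 = c(eff_group[["df"]], eff_within[["df"]], eff_inter[["df"]]),
    df2 = c(err_subj[["df"]], err_resid[["df"]], err_resid[["df"]]),
    p_value = c(fg[["p"]], fw[["p"]], fi[["p"]])
  )
  cells <- df |>
    dplyr::group_by(.data$group, .data$within) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
    )
  structure(out, class = c("sip_mixed_anova", class(out)),
            cells = cells,
            ms_subject = err_subj[["ms"]], df_subject = err_subj[["df"]],
            ms_resid = err_resid[["ms"]], df_resid = err_resid[["df"]],
            n_per_group = table(gmap$group), a = a)
}

#' Bonferroni-adjusted post hoc comparisons after a mixed ANOVA
#'
#' Pairwise cell-mean comparisons with `p_adj = min(1, m * p)` where `m`
#' is the family size. Between-group comparisons at each within level use
#' the subjects-within-groups error mean square with its `N - g` df;
#' within-level comparisons inside each group use the residual mean
#' square with its `(a - 1)(N - g)` df.
#'
#' @param fit A [mixed_rm_anova()] result.
#' @param type `"between"` (groups compared at each within level) or
#'   `"within"` (within levels compared inside each group).
#' @return Tibble `within`/`group`, the two compared levels, `estimate`,
#'   `statistic`, `df`, `p_value`, `p_adj`.
#' @export
posthoc_bonferroni <- function(fit, type = c("between", "within")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "sip_mixed_anova"))
  cells <- attr(fit, "cells")
  if (type == "between") {
    ms <- attr(fit, "ms_subject"); dfe <- attr(fit, "df_subject")
    strata <- split(cells, cells$within)
    lvl_col <- "group"; stratum_col <- "within"
  } else {
    ms <- attr(fit, "ms_resid"); dfe <- attr(fit, "df_resid")
    strata <- split(cells, cells$group)
    lvl_col <- "within"; stratum_col <- "group"
  }
  rows <- purrr::map_dfr(strata, function(s) {
    pairs <- utils::combn(as.character(s[[lvl_col]]), 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      s1 <- s[s[[lvl_col]] == p[1], ]; s2 <- s[s[[lvl_col]] == p[2], ]
      est <- s1$mean - s2$mean
      se <- sqrt(ms * (1 / s1$n + 1 / s2$n))
      t <- est / se
      tibble::tibble(
        !!stratum_col := as.character(s1[[stratum_col]]),
        level_1 = p[1], level_2 = p[2],
        estimate = est, statistic = t, df = dfe,
        p_value = 2 * stats::pt(abs(t), dfe, lower.tail = FALSE)
      )
    })
  })
  if (nrow(rows) == 0) stop("empty contrast family", call. = FALSE)
  rows$p_adj <- pmin(1, rows$p_value * nrow(rows))
  rows
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the input order (monotone in ranks and
#'   never smaller than the input).
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Pearson chi-squared test of a contingency table
#'
#' Expected counts from the row/column margins, no continuity correction,
#' upper-tail p, `df = (r - 1)(c - 1)`. Rows and columns whose totals are
#' zero are dropped first; a table with fewer than two informative rows
#' or columns is degenerate and raises an error.
#'
#' @param tab Matrix (or table) of nonnegative counts.
#' @return One-row tibble `method, statistic, df1, df2 (NA), p_value`
#'   with the kept table in the `table` attribute.
#' @examples
#' chi_square_test(rbind(c(7, 4), c(1, 5), c(24, 15)))
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate table: fewer than 2 rows or columns with positive totals",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- test_result("chi-squared", unname(ct$statistic),
                     unname(ct$parameter), NA_real_, ct$p.value)
  attr(out, "table") <- tab
  out
}

#' Group means with standard errors
#'
#' Mean +/- SEM per group, the reporting convention of the analysis
#' battery. `NA` values are dropped pairwise.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return Tibble `group, n, mean, sem`.
#' @export
group_summary <- function(values, groups) {
  keep <- !is.na(values)
  tibble::tibble(group = groups[keep], value = values[keep]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
    )
}
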