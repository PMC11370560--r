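#' Standardize a behavior table
#'
#' Z-scores each of the 12 OFB/EZM parameters (population SD, divisor
#' `n`), storing the transform so it can be reapplied or inverted. The 12
#' parameters carry incommensurate units (m, m/s, s, counts), so PCA is
#' always run on the standardized matrix (equivalently, on the
#' correlation matrix).
#'
#' @param behavior Tibble with a `tag` column and the 12
#'   [behavior_params()] columns, or a bare numeric matrix.
#' @return List of class `sip_standardize`: `z` (matrix, rownames = tags),
#'   `center`, `scale`.
#' @export
standardize <- function(behavior) {
  x <- as_behavior_matrix(behavior)
  if (nrow(x) < 2) stop("need at least 2 animals", call. = FALSE)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  if (any(scale == 0)) {
    stop("zero-variance parameter(s): ",
         paste(colnames(x)[scale == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(z = z, center = center, scale = scale),
            class = "sip_standardize")
}

as_behavior_matrix <- function(behavior) {
  if (is.matrix(behavior)) return(behavior)
  stopifnot(is.data.frame(behavior))
  cols <- setdiff(names(behavior), "tag")
  x <- as.matrix(behavior[cols])
  if (anyNA(x)) stop("behavior table has missing values", call. = FALSE)
  rownames(x) <- if ("tag" %in% names(behavior)) behavior$tag else NULL
  x
}

#' Principal component analysis of the standardized behavior matrix
#'
#' Eigendecomposition of the covariance of the z-scored parameters,
#' components sorted by explained variance. Sign convention: the
#' largest-magnitude loading of each component is positive, making
#' loadings reproducible across platforms.
#'
#' @param z Standardized matrix (from [standardize()]`$z`) or a
#'   `sip_standardize` object.
#' @return List of class `sip_pca`: `loadings` (columns = components),
#'   `ratios` (explained-variance ratios, descending, summing to 1),
#'   `scores` (`z %*% loadings`).
#' @export
pca_reduce <- function(z) {
  if (inherits(z, "sip_standardize")) z <- z$z
  if (nrow(z) < 2) stop("need at least 2 animals", call. = FALSE)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(loadings = loadings, ratios = ratios, scores = z %*% loadings),
    class = "sip_pca"
  )
}

#' Number of leading components exceeding a variance threshold
#'
#' The smallest `m` whose cumulative explained-variance ratio is strictly
#' greater than `threshold` (default 0.75, i.e. the first components
#' explaining over 75% of variance).
#'
#' @param ratios Descending explained-variance ratios summing to 1.
#' @param threshold Cumulative-variance threshold in `[0, 1)`.
#' @return Integer `m`.
#' @export
select_components <- function(ratios, threshold = 0.75) {
  if (length(ratios) == 0) stop("empty ratio vector", call. = FALSE)
  m <- which(cumsum(ratios) > threshold)[1]
  if (is.na(m)) length(ratios) else as.integer(m)
}

#' Fit k-means in principal-component space
#'
#' Multi-start k-means (`n_init` random initializations, best inertia
#' kept) on the reduced score matrix.
#'
#' @param scores Numeric matrix, one row per animal.
#' @param k Number of clusters (`k <= n`).
#' @param n_init Number of random initializations.
#' @param seed Optional seed making the fit reproducible.
#' @return List of class `sip_kmeans`: `k`, `centroids`, `labels`
#'   (0-based integer vector, named by rownames), `inertia`
#'   (within-cluster sum of squares), `n_init`, `seed`.
#' @export
kmeans_fit <- function(scores, k, n_init = 10, seed = NULL) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) {
    stop("k (", k, ") exceeds number of animals (", nrow(scores), ")",
         call. = FALSE)
  }
  stopifnot(k >= 1, n_init >= 1)
  fit_once <- function() {
    stats::kmeans(scores, centers = k, nstart = n_init, iter.max = 100)
  }
  km <- if (is.null(seed)) fit_once() else withr::with_seed(seed, fit_once())
  labels <- as.integer(km$cluster) - 1L
  names(labels) <- rownames(scores)
  structure(
    list(k = as.integer(k), centroids = km$centers, labels = labels,
         inertia = km$tot.withinss, n_init = n_init, seed = seed),
    class = "sip_kmeans"
  )
}

#' Agreement between two labelings
#'
#' Computes, from the label contingency table, the five clustering
#' agreement scores used to judge bootstrap stability: homogeneity,
#' completeness and their harmonic mean (V-measure), the adjusted Rand
#' index (permutation-model pair counting), and adjusted mutual
#' information (expected MI under the hypergeometric model; arithmetic
#' mean normalizer). Homogeneity treats `labels` as the candidate
#' clustering and `reference` as the classes: it is 1 when every
#' candidate cluster contains members of a single reference class.
#'
#' @param labels,reference Equal-length label vectors (any atomic type).
#' @return Named numeric vector `homogeneity, completeness, v_measure,
#'   ari, ami`.
#' @examples
#' agreement_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1)) # ARI = -0.5
#' @export
agreement_metrics <- function(labels, reference) {
  if (length(labels) != length(reference)) {
    stop("labelings differ in length", call. = FALSE)
  }
  if (length(labels) < 2) stop("need at least 2 items", call. = FALSE)
  tab <- table(labels, reference)
  n <- sum(tab)
  a <- rowSums(tab) # candidate cluster sizes
  b <- colSums(tab) # reference class sizes

  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_a <- ent(a / n)
  h_b <- ent(b / n)
  p_joint <- tab / n
  h_joint <- ent(as.vector(p_joint))
  mi <- h_a + h_b - h_joint
  h_b_given_a <- h_joint - h_a # H(reference | labels)
  h_a_given_b <- h_joint - h_b

  homogeneity <- if (h_b == 0) 1 else 1 - h_b_given_a / h_b
  completeness <- if (h_a == 0) 1 else 1 - h_a_given_b / h_a
  v <- if (homogeneity + completeness == 0) 0 else {
    2 * homogeneity * completeness / (homogeneity + completeness)
  }

  # adjusted Rand: pair counting against the permutation model
  comb2 <- function(x) x * (x - 1) / 2
  index <- sum(comb2(tab))
  exp_index <- sum(comb2(a)) * sum(comb2(b)) / comb2(n)
  max_index <- (sum(comb2(a)) + sum(comb2(b))) / 2
  ari <- if (max_index == exp_index) 1 else {
    (index - exp_index) / (max_index - exp_index)
  }

  ami <- if (max(h_a, h_b) == 0) 1 else {
    emi <- expected_mutual_information(a, b, n)
    denom <- (h_a + h_b) / 2 - emi
    if (abs(denom) < 1e-12) 0 else (mi - emi) / denom
  }

  c(homogeneity = homogeneity, completeness = completeness,
    v_measure = v, ari = ari, ami = ami)
}

# E[MI] over the hypergeometric model of random labelings with fixed margins
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Bootstrap cluster-stability table
#'
#' For each candidate `k`, fits a seeded reference k-means on the full
#' score matrix, then `B` replicate fits on bootstrap row-resamples with
#' fresh random initializations; each replicate's labels are compared to
#' the reference labels on the rows the resample shares with the full
#' data, via [agreement_metrics()]. The table reports each metric's mean
#' over replicates; the recommended `k` maximizes mean adjusted Rand
#' (ties to the smaller `k`).
#'
#' @param scores Reduced score matrix (animals x components).
#' @param k_range Candidate cluster counts (default 3:6).
#' @param B Bootstrap replicates (default 100).
#' @param n_init Random initializations per fit.
#' @param seed Seed for the whole procedure.
#' @return Tibble `k, homogeneity, completeness, v_measure, ari, ami`
#'   with attribute `recommended_k`.
#' @export
stability_table <- function(scores, k_range = 3:6, B = 100, n_init = 10,
                            seed = 1L) {
  stopifnot(B >= 2)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  rows <- withr::with_seed(seed, {
    lapply(k_range, function(k) {
      ref <- kmeans_fit(scores, k, n_init = n_init)
      reps <- replicate(B, {
        idx <- sample.int(n, n, replace = TRUE)
        fit <- kmeans_fit(scores[idx, , drop = FALSE], k, n_init = n_init)
        shared <- !duplicated(idx)
        agreement_metrics(fit$labels[shared], ref$labels[idx[shared]])
      })
      c(k = k, rowMeans(reps))
    })
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  best <- which(out$ari == max(out$ari))[1]
  attr(out, "recommended_k") <- as.integer(out$k[best])
  out
}

#' Cluster-by-group contingency table with chi-squared test
#'
#' Cross-tabulates cluster assignment against a roster grouping (sex by
#' default) and tests the distribution with a Pearson chi-squared test.
#'
#' @param labels Named 0-based label vector (names = tags) or tibble
#'   `tag, cluster`.
#' @param roster Roster tibble containing `tag` and the grouping column.
#' @param group Grouping column name (default `"sex"`).
#' @return List with `table` (clusters x groups matrix) and `test` (a
#'   [chi_square_test()] result).
#' @export
cluster_by_group_table <- function(labels, roster, group = "sex") {
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(tag = names(labels), cluster = as.integer(labels))
  }
  missing <- setdiff(labels$tag, roster$tag)
  if (length(missing) > 0) {
    stop("labels carry tag(s) absent from roster: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::inner_join(labels, roster, by = "tag")
  tab <- as.matrix(table(df$cluster, df[[group]]))
  list(table = tab, test = chi_square_test(tab))
}

#' Behavioral phenotyping: standardize, reduce, cluster
#'
#' The full phenotyping pipeline over a 12-parameter OFB/EZM behavior
#' table: z-score, PCA, keep the leading components explaining over
#' `variance_threshold` of the variance, evaluate bootstrap cluster
#' stability over `k_range` (unless `k` is fixed), and fit the final
#' k-means.
#'
#' @param behavior Behavior tibble (`tag` + 12 parameter columns).
#' @param k `"auto"` (choose by maximum mean bootstrap adjusted Rand) or
#'   a fixed integer.
#' @param variance_threshold Cumulative explained-variance cutoff for
#'   component selection (default 0.75).
#' @param k_range,B,n_init See [stability_table()].
#' @param seed Seed for stability bootstrap and final fit.
#' @return Object of class `sip_clustering`: `standardize`, `pca`,
#'   `n_components`, `stability` (`NULL` when `k` fixed), `k`, `fit`,
#'   `clusters` (tibble `tag, cluster`).
#' @export
cluster_phenotypes <- function(behavior, k = "auto", variance_threshold = 0.75,
                               k_range = 3:6, B = 100, n_init = 10,
                               seed = 1L) {
  std <- standardize(behavior)
  pca <- pca_reduce(std)
  m <- select_components(pca$ratios, variance_threshold)
  scores <- pca$scores[, seq_len(m), drop = FALSE]
  stability <- NULL
  if (identical(k, "auto")) {
    stability <- stability_table(scores, k_range = k_range, B = B,
                                 n_init = n_init, seed = seed)
    k <- attr(stability, "recommended_k")
  }
  fit <- kmeans_fit(scores, k, n_init = n_init, seed = seed + 1L)
  structure(
    list(
      standardize = std, pca = pca, n_components = m,
      stability = stability, k = as.integer(k), fit = fit,
      clusters = tibble::tibble(tag = names(fit$labels),
                                cluster = unname(fit$labels))
    ),
    class = "sip_clustering"
  )
}
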