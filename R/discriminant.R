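#' Group statistics for one diagnostic group
#'
#' Per-group means and standard deviations of the five diagnostic
#' indicators, the cluster centres and spreads of the discriminant
#' model.
#'
#' @param group group label (e.g. `"conditional_norm"`).
#' @param mean named numeric over `x1`..`x5`.
#' @param sd named numeric over `x1`..`x5`, all >= 0.
#' @param n optional sample count.
#' @return Object of class `group_stats`.
#' @export
group_stats <- function(group, mean, sd, n = NA_integer_) {
  feats <- paste0("x", 1:5)
  mean <- unlist(mean)[feats]; sd <- unlist(sd)[feats]
  if (anyNA(mean) || anyNA(sd))
    stop("group '", group, "': all five indicators x1..x5 need mean and sd")
  if (any(sd < 0)) stop("negative standard deviation in group '", group, "'")
  names(mean) <- names(sd) <- feats
  structure(list(group = as.character(group), mean = mean, sd = sd,
                 n = as.integer(n)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group_stats: %s (n = %s)\n", x$group, format(x$n)))
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Load diagnostic-group statistics
#'
#' With no argument, loads the bundled reference fixture: cohort means
#' and SDs of the five indicators for the conditional norm and the four
#' sinusitis forms, plus the reported pairwise distances and error
#' probabilities of the original clinical study (attached as attribute
#' `"reported_comparisons"`; kept separate because the reported
#' distances are not exactly recoverable from the reported means/SDs,
#' see the package vignette). A user file with the same JSON schema is
#' accepted.
#'
#' @param source path to a JSON file, or `NULL` for the bundled fixture.
#' @return Named list of [group_stats()] objects with attribute
#'   `"reported_comparisons"` (data frame, possibly empty).
#' @export
load_group_stats <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "sinusitis_group_stats.json",
                          package = "sinudens", mustWork = TRUE)
  raw <- jsonlite::read_json(source, simplifyVector = TRUE)
  if (is.null(raw$groups)) stop("no 'groups' entry in ", source)
  gl <- lapply(seq_len(nrow(raw$groups)), function(i) {
    g <- raw$groups[i, ]
    m <- unlist(g$mean); s <- unlist(g$sd)
    names(m) <- names(s) <- raw$indicators
    group_stats(g$group, m, s, if (!is.null(g$n)) g$n else NA_integer_)
  })
  names(gl) <- vapply(gl, function(g) g$group, character(1))
  rep_cmp <- raw$reported_comparisons
  attr(gl, "reported_comparisons") <-
    if (is.null(rep_cmp)) data.frame() else rep_cmp
  gl
}

#' Standardized difference of one indicator between two groups
#'
#' `delta_i = |m0 - m1| / max(sd0, sd1)` (the larger of the two group
#' spreads normalizes the separation). Degenerate spread
#' (`max sd = 0`): 0 when the means agree, `Inf` (infinite separation,
#' to be excluded from finite sums) when they differ.
#'
#' @param m0,m1 group means.
#' @param sd0,sd1 group standard deviations (>= 0).
#' @return Non-negative standardized difference (possibly `Inf`).
#' @export
standardized_diff <- function(m0, m1, sd0, sd1) {
  s <- pmax(sd0, sd1)
  out <- ifelse(s > 0, abs(m0 - m1) / s, ifelse(m0 == m1, 0, Inf))
  unname(out)
}

#' Multiparameter normalized Euclidean distance between two groups
#'
#' `delta = sqrt(sum_i delta_i^2)` over the requested indicators, with
#' `delta_i` from [standardized_diff()]. Indicators with infinite
#' standardized difference are excluded from the finite sum and listed
#' in the `"flagged_infinite"` attribute.
#'
#' @param stats0,stats1 [group_stats()] objects.
#' @param features character subset of `x1`..`x5` (default all five).
#' @return delta (numeric), with attributes `per_feature` (named
#'   delta_i) and `flagged_infinite`.
#' @export
normalized_distance <- function(stats0, stats1,
                                features = paste0("x", 1:5)) {
  stopifnot(inherits(stats0, "group_stats"), inherits(stats1, "group_stats"))
  if (length(features) == 0L) stop("empty feature set")
  if (!all(features %in% paste0("x", 1:5)))
    stop("features must be a subset of x1..x5")
  di <- standardized_diff(stats0$mean[features], stats1$mean[features],
                          stats0$sd[features], stats1$sd[features])
  names(di) <- features
  inf <- names(di)[is.infinite(di)]
  if (length(inf) == length(di))
    stop("no non-degenerate features left")
  delta <- sqrt(sum(di[is.finite(di)]^2))
  structure(delta, per_feature = di, flagged_infinite = inf)
}

#' Decision-error probability of the two-group discriminant
#'
#' For Gaussian groups separated by normalized distance delta the
#' probability of a wrong decision is `per = 1 - Phi(delta/2)`, with
#' Phi the probability integral `Phi(x) = erf(x/sqrt(2))` (equivalently
#' `per = 2 (1 - pnorm(delta/2))`). The alternative reading of Phi as
#' the standard normal CDF is available via `convention`.
#'
#' @param delta normalized Euclidean distance, >= 0.
#' @param convention `"probability_integral"` (default) or
#'   `"normal_cdf"`.
#' @return Error probability in (0, 1].
#' @export
error_probability <- function(delta,
                              convention = c("probability_integral",
                                             "normal_cdf")) {
  convention <- match.arg(convention)
  if (any(delta < 0)) stop("delta must be >= 0")
  if (convention == "probability_integral")
    2 * (1 - stats::pnorm(delta / 2))
  else
    1 - stats::pnorm(delta / 2)
}

#' Incremental discriminant curves for a two-group comparison
#'
#' Adds indicators one at a time in the stated order and tracks the
#' growth of the normalized distance `delta(j)` and the fall of the
#' error probability `per(j)`; squared distances add over disjoint
#' feature sets, so `delta(j)` is non-decreasing and `per(j)`
#' non-increasing regardless of order, and `delta(5)` is
#' order-invariant.
#'
#' @param stats0,stats1 [group_stats()] objects.
#' @param feature_order permutation of `x1`..`x5` (default the natural
#'   order; the indicators are deliberately not ranked).
#' @param convention passed to [error_probability()].
#' @return Object of class `sinus_discriminant`: `curve` (data frame
#'   `j`, `feature`, `delta_i`, `delta`, `per`), final `delta` and
#'   `per`, the groups compared, and degenerate-feature flags.
#' @export
incremental_curves <- function(stats0, stats1,
                               feature_order = paste0("x", 1:5),
                               convention = "probability_integral") {
  feats <- paste0("x", 1:5)
  if (!identical(sort(feature_order), sort(feats)) &&
      !all(feature_order %in% feats))
    stop("feature_order must be a permutation (or subset) of x1..x5")
  if (anyDuplicated(feature_order)) stop("duplicated features in order")
  nd_all <- normalized_distance(stats0, stats1, feature_order)
  di <- attr(nd_all, "per_feature")
  fin <- is.finite(di)
  cum <- sqrt(cumsum(ifelse(fin, di^2, 0)))
  per <- error_probability(cum, convention)
  curve <- data.frame(j = seq_along(feature_order),
                      feature = feature_order,
                      delta_i = unname(di),
                      delta = unname(cum), per = unname(per))
  structure(list(curve = curve,
                 delta = unname(cum[length(cum)]),
                 per = unname(per[length(per)]),
                 group0 = stats0$group, group1 = stats1$group,
                 flagged_infinite = attr(nd_all, "flagged_infinite"),
                 convention = convention),
            class = "sinus_discriminant")
}

#' @export
print.sinus_discriminant <- function(x, ...) {
  cat(sprintf("sinus_discriminant: %s vs %s\n", x$group0, x$group1))
  cat(sprintf("  delta = %.2f, per = %.2f (%d indicators)\n",
              x$delta, x$per, nrow(x$curve)))
  if (length(x$flagged_infinite))
    cat("  infinite-separation features excluded:",
        paste(x$flagged_infinite, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sinus_discriminant <- function(object, ...) {
  cat(sprintf("Two-group discriminant comparison: %s vs %s\n",
              object$group0, object$group1))
  print(transform(object$curve, delta = round(delta, 2),
                  per = round(per, 2), delta_i = round(delta_i, 2)))
  invisible(object)
}

#' @export
plot.sinus_discriminant <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$curve$j, x$curve$delta, type = "b", xlab = "j",
                 ylab = expression(delta(j)),
                 main = paste(x$group0, "vs", x$group1), ...)
  graphics::plot(x$curve$j, x$curve$per, type = "b", xlab = "j",
                 ylab = "per(j)", main = "decision-error probability", ...)
  invisible(x)
}

#' Nearest-cluster classification of a patient
#'
#' Computes the normalized Euclidean distance from the patient's
#' indicator vector to each group's cluster centre,
#' `sqrt(sum_i ((x_i - m_i)/sd_i)^2)` with that cluster's own spread;
#' the shortest distance gives the most probable diagnosis. An
#' indicator with zero spread in a cluster is skipped when the patient
#' matches the centre exactly and otherwise makes the distance infinite
#' (cluster ranked last). Ties are broken by cluster order and flagged.
#' Distance-derived compliance weights are reported as a softmax over
#' negative squared distances (an explicit extrapolation of the ranking
#' into probabilities).
#'
#' @param x an [extract_indicators()] vector or named numeric with the
#'   requested features.
#' @param clusters named list of [group_stats()] (>= 2), e.g. from
#'   [load_group_stats()].
#' @param features character subset of `x1`..`x5`.
#' @return Object of class `sinus_classification`: `ranking` (data
#'   frame group, distance, weight, rank), `winner`, `tie` flag.
#' @export
classify_patient <- function(x, clusters, features = paste0("x", 1:5)) {
  if (length(clusters) < 2L) stop("need at least two clusters")
  xv <- unclass(x)[features]
  if (anyNA(xv))
    stop("missing indicator values for: ",
         paste(features[is.na(xv)], collapse = ", "))
  dist_to <- function(g) {
    m <- g$mean[features]; s <- g$sd[features]
    terms <- numeric(length(features))
    for (i in seq_along(features)) {
      if (s[i] > 0) terms[i] <- ((xv[i] - m[i]) / s[i])^2
      else if (xv[i] == m[i]) terms[i] <- 0
      else return(Inf)
    }
    sqrt(sum(terms))
  }
  d <- vapply(clusters, dist_to, numeric(1))
  groups <- vapply(clusters, function(g) g$group, character(1))
  ord <- order(d, seq_along(d))
  d2 <- ifelse(is.finite(d), d^2, Inf)
  w <- exp(-(d2 - min(d2)))
  w <- if (all(!is.finite(d))) rep(NA_real_, length(d)) else w / sum(w)
  ranking <- data.frame(group = groups[ord], distance = unname(d[ord]),
                        weight = unname(w[ord]),
                        rank = seq_along(ord))
  tie <- length(d) > 1 && isTRUE(abs(sort(d)[1] - sort(d)[2]) < 1e-9)
  structure(list(ranking = ranking, winner = ranking$group[1], tie = tie,
                 features = features),
            class = "sinus_classification")
}

#' @export
print.sinus_classification <- function(x, ...) {
  cat("sinus_classification: winner =", x$winner,
      if (x$tie) "(tie!)" else "", "\n")
  print(transform(x$ranking, distance = round(distance, 3),
                  weight = round(weight, 3)))
  invisible(x)
}

#' Mahalanobis distance
#'
#' `sqrt((x - m)' Sigma^-1 (x - m))`; with diagonal covariance
#' `diag(sd_i^2)` it reduces to the normalized Euclidean distance used
#' by [classify_patient()], and the full form accounts for correlations
#' between indicators.
#'
#' @param x numeric vector.
#' @param center numeric mean vector.
#' @param covariance symmetric positive-definite matrix.
#' @return Non-negative distance.
#' @export
mahalanobis_distance <- function(x, center, covariance) {
  x <- as.numeric(x); center <- as.numeric(center)
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-10))
    stop("covariance must be symmetric")
  ch <- tryCatch(chol(covariance),
                 error = function(e) stop("covariance must be positive-definite"))
  z <- backsolve(ch, x - center, transpose = TRUE)
  sqrt(sum(z^2))
}
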